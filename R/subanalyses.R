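#' Classify whether a cycle was triggered in accordance with the model
#'
#' A treatment-arm cycle counts as accordant when both proxy criteria
#' hold, or when the trigger-day E2 exceeds the OHSS safety threshold:
#' \enumerate{
#'   \item on the trigger day, the model did not predict an MII increase
#'     from waiting one more day (`mii_plus1 <= mii_today`);
#'   \item on the most recent monitored visit strictly before the trigger
#'     day, the model predicted at least a `gain_threshold` relative MII
#'     increase from waiting one more day
#'     (`mii_plus1 >= (1 + gain_threshold) * mii_today`);
#'   \item (alternative) trigger-day E2 strictly above `e2_threshold`.
#' }
#' A condition whose prediction is unavailable evaluates to `FALSE` and is
#' noted in the flag.
#'
#' @param preds data frame of per-day predictions for one patient:
#'   columns `cycle_day`, `mii_today`, `mii_plus1` (and optionally
#'   `mii_plus2`).
#' @param visits the patient's visit data frame (used for the trigger day
#'   and trigger-day E2).
#' @param gain_threshold minimum relative predicted gain at the prior
#'   visit (default 0.05, i.e. 5 percent).
#' @param e2_threshold trigger-day E2 threshold in pg/mL (default 5000).
#' @return list of class `accordance_flag`: `patient_id`, `accordant`,
#'   `reasons` (subset of `no_gain_on_trigger_day`,
#'   `prior_visit_predicted_gain`, `e2_over_threshold`), `details`.
#' @export
classify_accordance <- function(preds, visits, gain_threshold = 0.05,
                                e2_threshold = 5000) {
  trig <- visits[visits$is_trigger_day, , drop = FALSE]
  if (nrow(trig) != 1) {
    stim_abort("cycle has no (or no unique) trigger day",
               "stim_classification_error")
  }
  t_day <- trig$cycle_day
  e2_trig <- trig$e2
  prior_days <- visits$cycle_day[visits$cycle_day < t_day]
  prior_day <- if (length(prior_days)) max(prior_days) else NA_integer_

  p_at <- function(day) {
    if (is.na(day)) return(NULL)
    r <- preds[preds$cycle_day == day, , drop = FALSE]
    if (nrow(r) == 1) r else NULL
  }
  pt <- p_at(t_day)
  pp <- p_at(prior_day)
  cond1 <- !is.null(pt) && pt$mii_plus1 <= pt$mii_today
  cond2 <- !is.null(pp) && pp$mii_plus1 >= (1 + gain_threshold) * pp$mii_today
  cond_e2 <- e2_trig > e2_threshold

  accordant <- (cond1 && cond2) || cond_e2
  reasons <- c(
    if (cond1) "no_gain_on_trigger_day",
    if (cond2) "prior_visit_predicted_gain",
    if (cond_e2) "e2_over_threshold"
  ) %||% character(0)
  structure(list(
    patient_id = visits$patient_id[1],
    accordant = accordant,
    reasons = if (accordant) reasons else character(0),
    details = list(trigger_day = t_day, prior_day = prior_day,
                   e2_trigger_day = e2_trig,
                   trigger_day_preds = pt, prior_visit_preds = pp,
                   cond1 = cond1, cond2 = cond2, cond_e2 = cond_e2)
  ), class = "accordance_flag")
}

#' Accordance flags for every completed treatment-arm cycle
#'
#' Runs [predict_trigger()] on each monitored visit from `from_day`
#' onwards and applies [classify_accordance()] per treatment-arm patient
#' with an outcome.
#'
#' @param cohort a `stim_cohort`.
#' @param model a `trigger_model`.
#' @param from_day first cycle day with predictions (default 7).
#' @inheritParams classify_accordance
#' @return data frame: `patient_id`, `accordant`, `reasons`
#'   (semicolon-joined), `e2_trigger_day`.
#' @export
accordance_flags <- function(cohort, model, from_day = 7,
                             gain_threshold = 0.05, e2_threshold = 5000) {
  b <- cohort$baselines
  ids <- intersect(b$patient_id[b$arm == "treatment"],
                   cohort$outcomes$patient_id)
  rows <- lapply(ids, function(pid) {
    v <- cohort$visits[cohort$visits$patient_id == pid, , drop = FALSE]
    v <- v[order(v$cycle_day), , drop = FALSE]
    elig <- v[v$cycle_day >= from_day, , drop = FALSE]
    preds <- if (nrow(elig) > 0) {
      do.call(rbind, lapply(seq_len(nrow(elig)), function(i) {
        p <- predict_trigger(model, elig[i, ])
        data.frame(cycle_day = elig$cycle_day[i], mii_today = p$mii_today,
                   mii_plus1 = p$mii_plus1, mii_plus2 = p$mii_plus2)
      }))
    } else {
      data.frame(cycle_day = integer(0), mii_today = numeric(0),
                 mii_plus1 = numeric(0), mii_plus2 = numeric(0))
    }
    fl <- classify_accordance(preds, v, gain_threshold, e2_threshold)
    data.frame(patient_id = pid, accordant = fl$accordant,
               reasons = paste(fl$reasons, collapse = ";"),
               e2_trigger_day = fl$details$e2_trigger_day,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Outcome comparison restricted to accordant patients
#'
#' Subsets the treatment arm to accordant patients, re-matches them to the
#' full control pool with the same methodology as [match_patients()], and
#' re-runs [compare_arms()].
#'
#' @param cohort a `stim_cohort` (baselines must be imputed).
#' @param flags output of [accordance_flags()].
#' @param ... passed to [compare_arms()].
#' @return list: `n_accordant`, `match` (`NULL` when empty), `comparison`
#'   (zero-row when empty).
#' @export
accordance_report <- function(cohort, flags, ...) {
  keep <- flags$patient_id[flags$accordant]
  b <- cohort$baselines
  sub <- b[b$arm == "control" | b$patient_id %in% keep, , drop = FALSE]
  if (length(keep) == 0) {
    empty <- data.frame(physician_id = character(0), n_pairs = integer(0),
                        outcome = character(0), mean_treatment = numeric(0),
                        mean_control = numeric(0), delta = numeric(0),
                        t = numeric(0), p = numeric(0), stringsAsFactors = FALSE)
    return(list(n_accordant = 0L, match = NULL, comparison = empty))
  }
  m <- match_patients(sub)
  list(n_accordant = length(keep), match = m,
       comparison = compare_arms(m, cohort$outcomes, ...))
}

#' Stratify the treatment arm by survey agreement
#'
#' A treatment patient is in the *agree* group when every recorded survey
#' verdict for their cycle is `"confirmed"` or `"changed"`, and in the
#' *disagree* group when any verdict is `"ignored"`.  `"unavailable"`
#' verdicts (predictions missing for data reasons) are excluded from the
#' quantifier; a patient whose verdicts are all unavailable falls in the
#' agree group vacuously and is listed in `vacuous_ids`.  Each group is
#' separately matched to the control pool and compared.
#'
#' @param surveys survey data frame.
#' @param cohort a `stim_cohort` (baselines imputed).
#' @param ... passed to [compare_arms()].
#' @return list: `groups` (patient_id, group), `vacuous_ids`, and per
#'   group `match`/`comparison` under `agree` and `disagree` (`NULL` when
#'   the group is empty).
#' @export
agreement_groups <- function(surveys, cohort, ...) {
  b <- cohort$baselines
  treat_ids <- b$patient_id[b$arm == "treatment"]
  no_resp <- setdiff(treat_ids, surveys$patient_id)
  if (length(no_resp) > 0) {
    stim_abort(paste("treatment patient(s) without survey responses:",
                     paste(utils::head(no_resp, 10), collapse = ", ")),
               "stim_assignment_error")
  }
  assign_one <- function(pid) {
    v <- surveys$verdict[surveys$patient_id == pid]
    v <- v[v != "unavailable"]
    if (length(v) == 0) return("agree_vacuous")
    if (all(v %in% c("confirmed", "changed"))) "agree" else "disagree"
  }
  grp <- vapply(treat_ids, assign_one, character(1))
  groups <- data.frame(patient_id = treat_ids,
                       group = ifelse(grp == "disagree", "disagree", "agree"),
                       stringsAsFactors = FALSE)
  vacuous <- treat_ids[grp == "agree_vacuous"]

  one <- function(ids) {
    if (length(ids) == 0) return(list(match = NULL, comparison = NULL))
    sub <- b[b$arm == "control" | b$patient_id %in% ids, , drop = FALSE]
    m <- match_patients(sub)
    list(match = m, comparison = compare_arms(m, cohort$outcomes, ...))
  }
  list(
    groups = groups,
    vacuous_ids = vacuous,
    agree = one(groups$patient_id[groups$group == "agree"]),
    disagree = one(groups$patient_id[groups$group == "disagree"])
  )
}
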