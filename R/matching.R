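MATCH_OUTCOMES <- c(oocytes = "oocytes_retrieved", mii = "mii_count",
                    total_fsh = "total_fsh_iu", trigger_day = "trigger_day")

#' KNN imputation of missing baseline covariates
#'
#' Each missing field among age, AMH, AFC, BMI is replaced by the mean of
#' that field over the `k_impute` reference patients nearest in the
#' standardized (log-AMH, log-AFC) space of the patient's *observed*
#' features.  Present values are never touched; imputed AFC is rounded to
#' the nearest integer since it is a count.
#'
#' @param patients baseline data frame (may contain `NA` in `amh`, `afc`,
#'   `bmi`).
#' @param reference complete data frame with columns `age`, `amh`, `afc`,
#'   `bmi` (e.g. a [simulate_reference()] table).
#' @param k_impute neighbourhood size (default 10).
#' @return list with `patients` (filled) and `log`, a data frame recording
#'   each imputed (patient_id, field, value).
#' @export
impute_baseline <- function(patients, reference, k_impute = 10) {
  fields <- c("age", "amh", "afc", "bmi")
  if (anyNA(reference[fields])) {
    abort_validation("imputation reference must have no missing values")
  }
  if (k_impute > nrow(reference)) {
    stim_abort("k_impute exceeds the reference size", "stim_size_error")
  }
  log_rows <- list()
  todo <- which(rowSums(is.na(patients[fields])) > 0)
  for (i in todo) {
    obs <- fields[!is.na(patients[i, fields])]
    mis <- fields[is.na(patients[i, fields])]
    if (length(obs) == 0) {
      stim_abort(sprintf("patient %s has all baseline features missing",
                         patients$patient_id[i]), "stim_imputation_error")
    }
    ref_std <- standardize_features(reference, obs)
    q_std <- standardize_features(patients[i, , drop = FALSE], obs,
                                  stats = ref_std$stats)
    nb <- find_neighbors(q_std$matrix[1, ], ref_std$matrix,
                         ids = as.character(seq_len(nrow(reference))),
                         k = k_impute)
    rows <- as.integer(nb)
    for (f in mis) {
      val <- mean(reference[[f]][rows])
      if (f == "afc") val <- round(val)
      patients[[f]][i] <- val
      log_rows[[length(log_rows) + 1]] <- data.frame(
        patient_id = patients$patient_id[i], field = f, value = val,
        stringsAsFactors = FALSE
      )
    }
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(patient_id = character(0), field = character(0),
               value = numeric(0), stringsAsFactors = FALSE)
  list(patients = patients, log = log)
}

smd <- function(x_t, x_c) {
  s <- sqrt((stats::var(x_t) + stats::var(x_c)) / 2)
  if (!is.finite(s) || s == 0) return(0)
  (mean(x_t) - mean(x_c)) / s
}

match_covariates <- function(baselines, features) {
  std <- standardize_features(baselines, features)
  Z <- std$matrix
  rownames(Z) <- baselines$patient_id
  Z
}

#' Match treatment patients to historical controls
#'
#' Per-physician 1-to-1 nearest-neighbour matching with replacement: for
#' each treatment patient, the control patient of the *same physician*
#' with the smallest Euclidean distance in standardized (age, log AMH,
#' log AFC) space is selected; a control may be reused.  Standardization
#' statistics are computed across all patients (both arms pooled).  BMI is
#' not part of the matching distance but is reported in the balance
#' diagnostics.
#'
#' @param baselines baseline data frame with no missing matching features
#'   (impute first).
#' @param features matching covariates (log transform applied to
#'   `amh`/`afc` inside the standardization).
#' @param balance_features covariates reported in the SMD diagnostics.
#' @return object of class `match_result`: `pairs` (treatment_id,
#'   control_id, physician_id, distance), `smd` (per covariate, pre- and
#'   post-matching standardized mean differences), `features`.
#' @export
match_patients <- function(baselines,
                           features = c("age", "amh", "afc"),
                           balance_features = c("age", "amh", "afc", "bmi")) {
  b <- baselines
  Z <- match_covariates(b, features)
  treat <- which(b$arm == "treatment")
  ctrl <- which(b$arm == "control")
  if (length(treat) == 0 || length(ctrl) == 0) {
    stim_abort("both arms must be non-empty", "stim_matching_error")
  }
  pairs <- vector("list", length(treat))
  for (j in seq_along(treat)) {
    i <- treat[j]
    cand <- ctrl[b$physician_id[ctrl] == b$physician_id[i]]
    if (length(cand) == 0) {
      stim_abort(sprintf("physician %s has treatment patients but no controls",
                         b$physician_id[i]), "stim_matching_error")
    }
    d2 <- rowSums(sweep(Z[cand, , drop = FALSE], 2, Z[i, ])^2)
    best <- cand[order(d2, b$patient_id[cand], method = "radix")][1]
    pairs[[j]] <- data.frame(
      treatment_id = b$patient_id[i], control_id = b$patient_id[best],
      physician_id = b$physician_id[i],
      distance = sqrt(min(d2)), stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, pairs)

  # balance: SMD on the analysis scale (log for amh/afc), pre vs post
  Zb <- match_covariates(b, balance_features)
  t_rows <- match(pairs$treatment_id, b$patient_id)
  c_rows <- match(pairs$control_id, b$patient_id)
  smd_tab <- data.frame(
    covariate = balance_features,
    smd_pre = vapply(balance_features, function(f)
      smd(Zb[b$arm == "treatment", f], Zb[b$arm == "control", f]), numeric(1)),
    smd_post = vapply(balance_features, function(f)
      smd(Zb[t_rows, f], Zb[c_rows, f]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(pairs = pairs, smd = smd_tab, features = features),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs (%d distinct controls) on {%s}\n",
              nrow(x$pairs), length(unique(x$pairs$control_id)),
              paste(x$features, collapse = ", ")))
  print(x$smd)
  invisible(x)
}

# t-test that degrades gracefully on zero-variance input
safe_t_test <- function(x, y, paired = FALSE) {
  delta <- mean(x) - mean(y)
  res <- tryCatch(
    stats::t.test(x, y, paired = paired, var.equal = FALSE),
    error = function(e) NULL
  )
  if (is.null(res)) {
    if (abs(delta) < 1e-12) return(list(t = 0, p = 1))
    return(list(t = sign(delta) * Inf, p = 0))
  }
  list(t = unname(res$statistic), p = res$p.value)
}

#' Compare outcomes between matched arms
#'
#' Per-physician and pooled means of oocytes retrieved, MII, total FSH and
#' trigger day for the treatment patients and their matched controls
#' (controls counted once per pair, so repeated controls are frequency
#' weighted), with treatment-minus-control deltas and two-sided t-tests.
#' The default test is Welch's unequal-variance t-test on the two groups
#' treated as independent samples; `paired = TRUE` switches to a paired
#' test on the within-pair differences.
#'
#' With heavy control reuse the pair-level samples contain duplicated
#' control values, which understates the control-arm variance and makes
#' the pair-weighted tests anti-conservative; `weighting = "unique"`
#' instead averages and tests each distinct matched control once, which
#' restores type-I calibration at the cost of weighting controls away
#' from the matched-cohort arithmetic.
#'
#' @param matched a [match_patients()] result.
#' @param outcomes outcome data frame covering every matched patient.
#' @param paired use a paired t-test instead of Welch (only with
#'   `weighting = "pairs"`).
#' @param weighting `"pairs"` (controls counted once per pair, in both
#'   means and tests) or `"unique"` (each distinct control counted once
#'   in the control mean and in the test sample).
#' @return data frame of class `arm_comparison` with columns
#'   `physician_id` (`"All"` = pooled), `n_pairs`, `outcome`,
#'   `mean_treatment`, `mean_control`, `delta`, `t`, `p`.
#' @export
compare_arms <- function(matched, outcomes, paired = FALSE,
                         weighting = c("pairs", "unique")) {
  weighting <- match.arg(weighting)
  pairs <- matched$pairs
  need <- unique(c(pairs$treatment_id, pairs$control_id))
  absent <- setdiff(need, outcomes$patient_id)
  if (length(absent) > 0) {
    abort_validation(paste("missing outcomes for patient(s):",
                           paste(utils::head(absent, 10), collapse = ", ")))
  }
  groups <- c(All = NA, stats::setNames(unique(pairs$physician_id),
                                        unique(pairs$physician_id)))
  rows <- list()
  for (g in names(groups)) {
    p <- if (g == "All") pairs else pairs[pairs$physician_id == g, , drop = FALSE]
    ti <- match(p$treatment_id, outcomes$patient_id)
    ci <- match(p$control_id, outcomes$patient_id)
    for (oc in names(MATCH_OUTCOMES)) {
      col <- MATCH_OUTCOMES[[oc]]
      x <- outcomes[[col]][ti]
      y <- outcomes[[col]][ci]
      if (weighting == "unique") {
        y <- outcomes[[col]][match(unique(p$control_id), outcomes$patient_id)]
      }
      mc <- mean(y)
      tt <- safe_t_test(x, y, paired = paired && weighting == "pairs")
      rows[[length(rows) + 1]] <- data.frame(
        physician_id = g, n_pairs = nrow(p), outcome = oc,
        mean_treatment = mean(x), mean_control = mc,
        delta = mean(x) - mc, t = tt$t, p = tt$p,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("arm_comparison", class(out))
  out
}

#' Baseline characteristics table for matched arms
#'
#' Per-physician and pooled means of age, AMH, AFC and BMI (raw scale) for
#' the treatment patients and their matched controls, plus post-matching
#' standardized mean differences on the analysis scale.
#'
#' @param matched a [match_patients()] result.
#' @param baselines the baseline data frame the match was built from.
#' @return data frame with columns `physician_id`, `covariate`,
#'   `mean_treatment`, `mean_control`, `smd_post`.
#' @export
baseline_table <- function(matched, baselines) {
  pairs <- matched$pairs
  covs <- c("age", "amh", "afc", "bmi")
  Zb <- match_covariates(baselines, covs)
  groups <- c(All = NA, stats::setNames(unique(pairs$physician_id),
                                        unique(pairs$physician_id)))
  rows <- list()
  for (g in names(groups)) {
    p <- if (g == "All") pairs else pairs[pairs$physician_id == g, , drop = FALSE]
    ti <- match(p$treatment_id, baselines$patient_id)
    ci <- match(p$control_id, baselines$patient_id)
    for (cv in covs) {
      rows[[length(rows) + 1]] <- data.frame(
        physician_id = g, covariate = cv, n_pairs = nrow(p),
        mean_treatment = mean(baselines[[cv]][ti]),
        mean_control = mean(baselines[[cv]][ci]),
        smd_post = smd(Zb[ti, cv], Zb[ci, cv]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
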