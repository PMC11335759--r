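TRIGGER_FEATURES <- c("bin_lt11", "bin_11_13", "bin_14_15",
                      "bin_16_17", "bin_18_19", "bin_gt19", "e2")
TRIGGER_SUBMODELS <- c("mii_0", "mii_1", "mii_2", "e2_1", "e2_2")
TRIGGER_MODEL_VERSION <- "stim-trigger-1"

trigger_feature_row <- function(diameters, e2) {
  counts <- bin_follicles(diameters)
  stats::setNames(c(as.numeric(counts), e2), TRIGGER_FEATURES)
}

#' Build per-horizon training rows for the trigger tool
#'
#' For every completed cycle (one with a trigger day and an outcome) and
#' every monitoring visit at day `t` with `T - t` in `{0, 1, 2}` (trigger
#' day `T`), one MII training row pairs the visit's follicle-bin counts and
#' E2 with the cycle's observed MII count.  The single observed MII is the
#' target at all three horizons -- the only outcome a cycle produces -- so
#' labels are shared across horizons.  E2-forecast rows pair features at
#' day `t` with observed E2 at `t + 1` and `t + 2` whenever those visits
#' exist.  Cycles without a trigger day are skipped with a warning.
#'
#' @param cohort a `stim_cohort` with outcomes.
#' @return data frame with columns `patient_id`, `cycle_day`, `model` (one
#'   of `mii_0`, `mii_1`, `mii_2`, `e2_1`, `e2_2`), the seven features, and
#'   `target`.
#' @export
build_training_rows <- function(cohort) {
  v <- cohort$visits
  o <- cohort$outcomes
  fol <- parse_follicles(v$follicles)
  feat <- t(vapply(seq_len(nrow(v)),
                   function(i) trigger_feature_row(fol[[i]], v$e2[i]),
                   numeric(7)))
  trig_day <- o$trigger_day[match(v$patient_id, o$patient_id)]
  mii <- o$mii_count[match(v$patient_id, o$patient_id)]

  skipped <- unique(v$patient_id[is.na(trig_day)])
  if (length(skipped) > 0) {
    warning(sprintf("skipping %d cycle(s) without a trigger day: %s",
                    length(skipped),
                    paste(utils::head(skipped, 5), collapse = ", ")),
            call. = FALSE)
  }

  out <- list()
  horizon <- trig_day - v$cycle_day
  for (h in 0:2) {
    i <- which(!is.na(horizon) & horizon == h)
    if (length(i) == 0) next
    out[[paste0("mii_", h)]] <- data.frame(
      patient_id = v$patient_id[i], cycle_day = v$cycle_day[i],
      model = paste0("mii_", h), feat[i, , drop = FALSE],
      target = mii[i], stringsAsFactors = FALSE
    )
  }
  key <- paste(v$patient_id, v$cycle_day)
  for (h in 1:2) {
    nxt <- match(paste(v$patient_id, v$cycle_day + h), key)
    i <- which(!is.na(nxt) & !is.na(trig_day))
    if (length(i) == 0) next
    out[[paste0("e2_", h)]] <- data.frame(
      patient_id = v$patient_id[i], cycle_day = v$cycle_day[i],
      model = paste0("e2_", h), feat[i, , drop = FALSE],
      target = v$e2[nxt[i]], stringsAsFactors = FALSE
    )
  }
  rows <- do.call(rbind, out)
  rownames(rows) <- NULL
  rows
}

ols_or_ridge <- function(X, y, ridge_penalty) {
  Xa <- cbind(intercept = 1, X)
  if (ridge_penalty == 0) {
    fit <- stats::lm.fit(Xa, y)
    beta <- fit$coefficients
    if (anyNA(beta) || fit$rank < ncol(Xa)) {
      stim_abort(
        "design matrix is rank deficient at ridge_penalty = 0; set ridge_penalty > 0",
        "stim_rank_error"
      )
    }
  } else {
    P <- diag(c(0, rep(ridge_penalty, ncol(X))))  # intercept unpenalized
    beta <- drop(solve(crossprod(Xa) + P, crossprod(Xa, y)))
  }
  if (any(!is.finite(beta))) stim_abort("non-finite coefficients", "stim_rank_error")
  list(intercept = unname(beta[1]),
       coefficients = stats::setNames(unname(beta[-1]), colnames(X)))
}

#' Train the trigger-timing model
#'
#' Fits one ordinary-least-squares regression per prediction target: MII
#' if triggering today / tomorrow / in two days, and E2 tomorrow / in two
#' days, each over the seven features (six follicle-diameter bin counts
#' and current E2).  An optional ridge penalty handles collinear bins.
#'
#' @param rows output of [build_training_rows()].
#' @param ridge_penalty non-negative L2 penalty (intercept unpenalized).
#' @param min_rows minimum rows required per sub-model.
#' @return an object of class `trigger_model`: version, feature order, and
#'   per-sub-model intercept + 7 coefficients and training size.
#' @export
train_trigger_model <- function(rows, ridge_penalty = 0, min_rows = 30) {
  models <- list()
  for (m in TRIGGER_SUBMODELS) {
    r <- rows[rows$model == m, , drop = FALSE]
    if (nrow(r) < min_rows) {
      stim_abort(sprintf("sub-model '%s' has %d rows; need >= %d",
                         m, nrow(r), min_rows), "stim_support_error")
    }
    fit <- ols_or_ridge(as.matrix(r[TRIGGER_FEATURES]), r$target, ridge_penalty)
    fit$n <- nrow(r)
    models[[m]] <- fit
  }
  structure(list(version = TRIGGER_MODEL_VERSION,
                 features = TRIGGER_FEATURES,
                 models = models),
            class = "trigger_model")
}

#' @export
print.trigger_model <- function(x, ...) {
  cat(sprintf("<trigger_model> %s; %d sub-models over %d features\n",
              x$version, length(x$models), length(x$features)))
  invisible(x)
}

#' Project an MII prediction triple onto the biologically feasible set
#'
#' The model never reports a decline in predicted MII tomorrow followed by
#' an increase in two days: once predicted yield declines, later horizons
#' cannot exceed it.  If `mii_plus1 < mii_today`, `mii_plus2` is capped at
#' `mii_plus1`; the other two values are never altered, and feasible
#' triples pass through unchanged.  The projection is idempotent.
#'
#' @param mii_today,mii_plus1,mii_plus2 raw (non-negative) predictions.
#' @return list with `mii_today`, `mii_plus1`, `mii_plus2`, and `changed`.
#' @examples
#' project_feasible(8, 7, 9)   # caps the last value at 7
#' project_feasible(6, 7.4, 8.1)  # feasible, unchanged
#' @export
project_feasible <- function(mii_today, mii_plus1, mii_plus2) {
  capped <- if (mii_plus1 < mii_today) min(mii_plus2, mii_plus1) else mii_plus2
  list(mii_today = mii_today, mii_plus1 = mii_plus1, mii_plus2 = capped,
       changed = capped != mii_plus2)
}

#' Predict MII yield and E2 for trigger-timing decisions
#'
#' Applies the per-horizon linear models to the visit's most recent
#' follicle measurements and E2, clips raw predictions at zero, and
#' projects the MII triple onto the feasible set ([project_feasible()]).
#'
#' @param model a `trigger_model`.
#' @param visit one-row visit data frame (columns `follicles`, `e2`), or a
#'   list with `follicles` (numeric diameters) and `e2`.
#' @return list of class `trigger_prediction`: `mii_today`, `mii_plus1`,
#'   `mii_plus2`, `e2_plus1`, `e2_plus2`, `constraint_applied`.
#' @export
predict_trigger <- function(model, visit) {
  stopifnot(inherits(model, "trigger_model"))
  diam <- if (is.character(visit$follicles)) {
    parse_follicles(visit$follicles)[[1]]
  } else {
    as.numeric(visit$follicles)
  }
  e2 <- visit$e2
  if (length(e2) != 1 || is.na(e2)) abort_input("visit E2 is required")
  if (length(diam) == 0) abort_input("visit has no follicle measurements")
  x <- trigger_feature_row(diam, e2)
  raw <- vapply(model$models, function(m) {
    unname(m$intercept + sum(m$coefficients[model$features] * x))
  }, numeric(1))
  raw <- pmax(raw, 0)
  proj <- project_feasible(raw[["mii_0"]], raw[["mii_1"]], raw[["mii_2"]])
  structure(list(
    mii_today = proj$mii_today,
    mii_plus1 = proj$mii_plus1,
    mii_plus2 = proj$mii_plus2,
    e2_plus1 = raw[["e2_1"]],
    e2_plus2 = raw[["e2_2"]],
    constraint_applied = proj$changed
  ), class = "trigger_prediction")
}

#' @export
print.trigger_prediction <- function(x, ...) {
  cat(sprintf(
    "<trigger_prediction> MII %.1f today / %.1f tomorrow / %.1f in two days%s; E2 %.0f / %.0f pg/mL\n",
    x$mii_today, x$mii_plus1, x$mii_plus2,
    if (x$constraint_applied) " (feasibility constraint applied)" else "",
    x$e2_plus1, x$e2_plus2
  ))
  invisible(x)
}

#' Serialize and load a trigger model
#'
#' The model file is versioned JSON carrying the feature order and each
#' sub-model's intercept and coefficients at full double precision, so a
#' load-after-save reproduces predictions exactly.  Loading fails on a
#' version or feature-order mismatch.
#'
#' @param model a `trigger_model`.
#' @param path file path.
#' @export
serialize_model <- function(model, path) {
  stopifnot(inherits(model, "trigger_model"))
  payload <- list(
    version = model$version,
    features = model$features,
    models = lapply(model$models, function(m) {
      list(intercept = m$intercept,
           coefficients = as.list(m$coefficients),
           n = m$n)
    })
  )
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname serialize_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$version, TRIGGER_MODEL_VERSION)) {
    stim_abort(sprintf("model version '%s' not supported (expected '%s')",
                       payload$version %||% "<none>", TRIGGER_MODEL_VERSION),
               "stim_load_error")
  }
  feats <- unlist(payload$features)
  if (!identical(feats, TRIGGER_FEATURES)) {
    stim_abort("model file feature order does not match the expected 7 features",
               "stim_load_error")
  }
  models <- lapply(payload$models, function(m) {
    co <- unlist(m$coefficients)
    if (!identical(sort(names(co)), sort(TRIGGER_FEATURES))) {
      stim_abort("sub-model coefficients do not cover the 7 features",
                 "stim_load_error")
    }
    list(intercept = as.numeric(m$intercept),
         coefficients = co[TRIGGER_FEATURES],
         n = m$n %||% NA_integer_)
  })
  if (!all(TRIGGER_SUBMODELS %in% names(models))) {
    stim_abort("model file is missing sub-models", "stim_load_error")
  }
  structure(list(version = TRIGGER_MODEL_VERSION,
                 features = TRIGGER_FEATURES,
                 models = models[TRIGGER_SUBMODELS]),
            class = "trigger_model")
}
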