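#' Standardize baseline features for similarity search
#'
#' AMH and AFC are log-transformed (log(x + 0.01), so zero reserve markers
#' remain finite) and every selected feature is z-scored: subtract the mean
#' and divide by the population (divide-by-n) standard deviation.  When
#' `stats` is supplied the stored means/sds are reused, which is how query
#' patients are projected into the space of a reference cohort.
#'
#' @param patients data frame containing the selected feature columns, with
#'   no missing values (impute first; see [impute_baseline()]).
#' @param features character vector drawn from `age`, `amh`, `afc`, `bmi`.
#' @param stats optional data frame (`feature`, `mean`, `sd`) from a
#'   previous call.
#' @param log_features features log-transformed before z-scoring.
#' @return list with `matrix` (n x p standardized features) and `stats`.
#' @export
standardize_features <- function(patients,
                                 features = c("age", "amh", "afc", "bmi"),
                                 stats = NULL,
                                 log_features = c("amh", "afc")) {
  missing_cols <- setdiff(features, names(patients))
  if (length(missing_cols) > 0) {
    abort_schema(paste("missing feature column(s):", paste(missing_cols, collapse = ", ")))
  }
  raw <- lapply(features, function(f) {
    x <- patients[[f]]
    if (anyNA(x)) abort_validation(sprintf("feature '%s' has missing values", f))
    if (f %in% log_features) {
      if (any(x < 0)) abort_validation(sprintf("feature '%s' negative under log transform", f))
      x <- log(x + 0.01)
    }
    x
  })
  X <- do.call(cbind, raw)
  colnames(X) <- features
  if (is.null(stats)) {
    mu <- colMeans(X)
    sd <- apply(X, 2, pop_sd)
    if (any(sd == 0)) {
      stim_abort(sprintf("zero-variance feature(s): %s",
                         paste(features[sd == 0], collapse = ", ")),
                 "stim_degenerate_error")
    }
    stats <- data.frame(feature = features, mean = mu, sd = sd,
                        row.names = NULL, stringsAsFactors = FALSE)
  } else {
    if (!all(features %in% stats$feature)) {
      abort_input("stats do not cover the requested features")
    }
    stats <- stats[match(features, stats$feature), , drop = FALSE]
  }
  Z <- sweep(sweep(X, 2, stats$mean), 2, stats$sd, "/")
  list(matrix = Z, stats = stats)
}

#' Find the k nearest reference patients
#'
#' Euclidean distance in the standardized feature space; ties are broken by
#' lexicographic patient id so the ordering is deterministic under any
#' permutation of the reference rows.
#'
#' @param query numeric vector (one standardized patient).
#' @param features standardized reference matrix (rows = patients).
#' @param ids reference patient ids (defaults to `rownames(features)`).
#' @param k number of neighbours.
#' @return character vector of `k` ids, nearest first.
#' @export
find_neighbors <- function(query, features, ids = rownames(features), k = 100) {
  features <- as.matrix(features)
  if (is.null(ids)) abort_input("reference ids are required")
  if (nrow(features) < k) {
    stim_abort(sprintf("reference has %d patients but k = %d", nrow(features), k),
               "stim_size_error")
  }
  d2 <- rowSums(sweep(features, 2, as.numeric(query))^2)
  ord <- order(d2, ids, method = "radix")
  ids[ord][seq_len(k)]
}

#' Fit a patient-specific dose-response curve
#'
#' Least-squares polynomial fit (degree 2 by default: the lowest degree
#' admitting an interior maximum) of neighbour MII counts on their starting
#' FSH doses, evaluated on a 12.5-IU grid spanning the neighbours' observed
#' dose range; extrapolation beyond that range is refused by construction.
#' Pointwise bands are the 2.5th/97.5th percentiles (for `band_level =
#' 0.95`) of curves refit on bootstrap resamples of the neighbour set, then
#' widened where necessary to contain the point fit.  With noiseless
#' neighbours the bands collapse onto the curve.
#'
#' @param dose,mii neighbour starting doses (IU) and MII counts.
#' @param neighbor_ids optional ids stored in the result.
#' @param degree polynomial degree.
#' @param band_level band coverage level.
#' @param bootstrap_reps bootstrap resamples for the bands.
#' @param seed integer seed for the bootstrap.
#' @param grid_step dose grid spacing (IU).
#' @return an object of class `dose_response_curve`: list with `dose_grid`,
#'   `predicted_mii`, `band_low`, `band_high`, `neighbor_ids`,
#'   `recommended_dose` (the grid argmax, unsnapped; see
#'   [recommend_dose()]), `coefficients`, `degree`.
#' @export
fit_dose_response <- function(dose, mii, neighbor_ids = NULL, degree = 2,
                              band_level = 0.95, bootstrap_reps = 500,
                              seed = 1, grid_step = 12.5) {
  if (length(dose) != length(mii)) abort_input("dose and mii lengths differ")
  n_distinct <- length(unique(dose))
  if (n_distinct < max(3, degree + 1)) {
    stim_abort(sprintf("need at least %d distinct dose values, got %d",
                       max(3, degree + 1), n_distinct),
               "stim_support_error")
  }
  grid <- unique(c(seq(min(dose), max(dose), by = grid_step), max(dose)))
  fit_predict <- function(d, y) {
    co <- stats::coef(stats::lm(y ~ stats::poly(d, degree, raw = TRUE)))
    co[is.na(co)] <- 0
    as.numeric(outer(grid, 0:degree, `^`) %*% co)
  }
  pred <- fit_predict(dose, mii)

  set.seed(substream_seed(seed, 1))
  alpha <- (1 - band_level) / 2
  boot <- matrix(NA_real_, nrow = bootstrap_reps, ncol = length(grid))
  n <- length(dose)
  for (b in seq_len(bootstrap_reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    tries <- 0
    while (length(unique(dose[idx])) < degree + 1 && tries < 50) {
      idx <- sample.int(n, n, replace = TRUE)
      tries <- tries + 1
    }
    boot[b, ] <- fit_predict(dose[idx], mii[idx])
  }
  band_low <- pmin(apply(boot, 2, stats::quantile, probs = alpha), pred)
  band_high <- pmax(apply(boot, 2, stats::quantile, probs = 1 - alpha), pred)

  structure(list(
    dose_grid = grid,
    predicted_mii = pred,
    band_low = band_low,
    band_high = band_high,
    neighbor_ids = neighbor_ids,
    recommended_dose = grid[which.max(pred)],
    coefficients = stats::coef(stats::lm(mii ~ stats::poly(dose, degree, raw = TRUE))),
    degree = degree
  ), class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf(
    "<dose_response_curve> degree %d on [%g, %g] IU; predicted MII max %.2f at %g IU\n",
    x$degree, min(x$dose_grid), max(x$dose_grid),
    max(x$predicted_mii), x$recommended_dose
  ))
  invisible(x)
}

#' Recommend a starting dose from a fitted curve
#'
#' The grid argmax of the predicted curve (ties toward the lower dose),
#' snapped to clinically usable increments: multiples of `dose_step`,
#' default 37.5 IU (half a 75-IU vial), with exact halves rounded down.
#'
#' @param curve a [fit_dose_response()] result.
#' @param dose_step dosing increment in IU.
#' @return recommended starting dose (IU).
#' @export
recommend_dose <- function(curve, dose_step = 37.5) {
  stopifnot(inherits(curve, "dose_response_curve"))
  snap_to_step(curve$dose_grid[which.max(curve$predicted_mii)], dose_step)
}

#' Build a dose-response curve for one patient against a reference cohort
#'
#' End-to-end starting-dose tool: standardizes the reference cohort's
#' baseline features (age, log AMH, log AFC, BMI), projects the query
#' patient with the stored statistics, retrieves the `k` most similar
#' reference patients, and fits the dose-response curve to their (dose,
#' MII) pairs.
#'
#' @param reference a reference data frame with columns `patient_id`,
#'   `age`, `amh`, `afc`, `bmi`, `starting_dose_iu`, `mii_count` and no
#'   missing values (e.g. [simulate_reference()]).
#' @param patient one-row data frame with the baseline features.
#' @param k number of neighbours (default 100).
#' @param features similarity features.
#' @inheritParams fit_dose_response
#' @return a `dose_response_curve`.
#' @export
starting_dose_curve <- function(reference, patient, k = 100,
                                features = c("age", "amh", "afc", "bmi"),
                                degree = 2, band_level = 0.95,
                                bootstrap_reps = 500, seed = 1,
                                grid_step = 12.5) {
  need <- c("patient_id", features, "starting_dose_iu", "mii_count")
  missing_cols <- setdiff(need, names(reference))
  if (length(missing_cols) > 0) {
    abort_schema(paste("reference is missing column(s):",
                       paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(reference[need])) abort_validation("reference cohort has missing values")
  ref_std <- standardize_features(reference, features)
  q_std <- standardize_features(patient, features, stats = ref_std$stats)
  nb <- find_neighbors(q_std$matrix[1, ], ref_std$matrix,
                       ids = reference$patient_id, k = k)
  rows <- match(nb, reference$patient_id)
  fit_dose_response(reference$starting_dose_iu[rows], reference$mii_count[rows],
                    neighbor_ids = nb, degree = degree, band_level = band_level,
                    bootstrap_reps = bootstrap_reps, seed = seed,
                    grid_step = grid_step)
}
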