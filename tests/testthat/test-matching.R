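ref_table <- function(n = 200, seed = 1) {
  set.seed(seed)
  data.frame(age = rnorm(n, 36, 4), amh = rlnorm(n, log(2.2), 0.6),
             afc = pmax(1, round(rlnorm(n, log(15.5), 0.45))),
             bmi = rnorm(n, 25, 3.5))
}

test_that("imputation fills only missing fields from nearest-neighbour means", {
  ref <- ref_table()
  pts <- data.frame(patient_id = c("A", "B"), age = c(34, 39),
                    amh = c(2.0, NA), afc = c(NA, 12), bmi = c(24, 28),
                    stringsAsFactors = FALSE)
  res <- impute_baseline(pts, ref, k_impute = 10)
  expect_false(anyNA(res$patients[c("age", "amh", "afc", "bmi")]))
  # present values untouched
  expect_equal(res$patients$amh[1], 2.0)
  expect_equal(res$patients$afc[2], 12)
  expect_setequal(paste(res$log$patient_id, res$log$field), c("A afc", "B amh"))

  # brute-force oracle for patient A's afc
  obs <- c("age", "amh", "bmi")
  rs <- standardize_features(ref, obs)
  qs <- standardize_features(pts[1, ], obs, stats = rs$stats)
  d <- sqrt(rowSums(sweep(rs$matrix, 2, qs$matrix[1, ])^2))
  nn <- order(d)[1:10]
  expect_equal(res$patients$afc[1], round(mean(ref$afc[nn])))
})

test_that("imputation edge cases: complete rows unchanged, exhaustive k gives the field mean", {
  ref <- ref_table(50, seed = 2)
  pts <- data.frame(patient_id = "C", age = 36, amh = 2.5, afc = 16, bmi = 25,
                    stringsAsFactors = FALSE)
  res <- impute_baseline(pts, ref, k_impute = 10)
  expect_equal(res$patients, pts)
  expect_equal(nrow(res$log), 0)

  pts$amh <- NA
  res2 <- impute_baseline(pts, ref, k_impute = 50)
  expect_equal(res2$patients$amh, mean(ref$amh))

  all_miss <- data.frame(patient_id = "D", age = NA, amh = NA, afc = NA,
                         bmi = NA, stringsAsFactors = FALSE)
  expect_error(impute_baseline(all_miss, ref), class = "stim_imputation_error")
})

make_arms <- function(n_t = 30, n_c = 60, seed = 3, shift = 0,
                      physicians = c("MD1", "MD2")) {
  set.seed(seed)
  n <- n_t + n_c
  arm <- rep(c("treatment", "control"), c(n_t, n_c))
  data.frame(
    patient_id = sprintf("M%03d", seq_len(n)),
    physician_id = sample(physicians, n, replace = TRUE),
    arm = arm,
    age = rnorm(n, 36, 4) + shift * 4 * (arm == "treatment"),
    amh = rlnorm(n, log(2.2) + shift * 0.6 * (arm == "treatment"), 0.6),
    afc = pmax(1, round(rlnorm(n, log(15.5), 0.45))),
    bmi = rnorm(n, 25, 3.5),
    stringsAsFactors = FALSE
  )
}

test_that("an exact-copy control arm matches at distance zero", {
  b <- make_arms(n_t = 20, n_c = 0)
  copies <- b; copies$arm <- "control"
  copies$patient_id <- sub("^M", "C", copies$patient_id)
  m <- match_patients(rbind(b, copies))
  expect_equal(m$pairs$control_id, sub("^M", "C", m$pairs$treatment_id))
  expect_equal(m$pairs$distance, rep(0, 20))
  expect_equal(m$smd$smd_post, rep(0, 4), tolerance = 1e-12)
})

test_that("matching agrees with a brute-force nearest-control scan", {
  b <- make_arms(n_t = 50, n_c = 80, seed = 5)
  m <- match_patients(b)
  std <- standardize_features(b, c("age", "amh", "afc"))
  Z <- std$matrix
  for (j in seq_len(nrow(m$pairs))) {
    i <- match(m$pairs$treatment_id[j], b$patient_id)
    cand <- which(b$arm == "control" & b$physician_id == b$physician_id[i])
    d <- sqrt(rowSums(sweep(Z[cand, , drop = FALSE], 2, Z[i, ])^2))
    best <- cand[order(d, b$patient_id[cand])][1]
    expect_identical(m$pairs$control_id[j], b$patient_id[best])
  }
})

test_that("matching never crosses physicians and handles a single shared control", {
  b <- make_arms(n_t = 40, n_c = 40, seed = 7)
  m <- match_patients(b)
  pid <- function(id) b$physician_id[match(id, b$patient_id)]
  expect_equal(pid(m$pairs$treatment_id), pid(m$pairs$control_id))

  one <- make_arms(n_t = 10, n_c = 0, seed = 8, physicians = "MD1")
  lone <- data.frame(patient_id = "C001", physician_id = "MD1",
                     arm = "control", age = 36, amh = 2.2, afc = 16,
                     bmi = 25, stringsAsFactors = FALSE)
  m1 <- match_patients(rbind(one, lone))
  expect_equal(unique(m1$pairs$control_id), "C001")

  orphan <- make_arms(n_t = 5, n_c = 5, seed = 9, physicians = "MD1")
  orphan$physician_id[orphan$arm == "treatment"][1] <- "MD9"
  expect_error(match_patients(orphan), class = "stim_matching_error",
               regexp = "MD9")
})

test_that("identical matched outcomes give zero deltas with p = 1", {
  b <- make_arms(n_t = 15, n_c = 0, seed = 11)
  copies <- b; copies$arm <- "control"
  copies$patient_id <- sub("^M", "C", copies$patient_id)
  m <- match_patients(rbind(b, copies))
  o_t <- data.frame(patient_id = b$patient_id, oocytes_retrieved = 14,
                    mii_count = 11, total_fsh_iu = 3000, trigger_day = 10)
  o_c <- o_t; o_c$patient_id <- sub("^M", "C", o_c$patient_id)
  cmp <- compare_arms(m, rbind(o_t, o_c))
  expect_equal(cmp$delta, rep(0, nrow(cmp)))
  expect_equal(cmp$t, rep(0, nrow(cmp)))
  expect_equal(cmp$p, rep(1, nrow(cmp)))

  missing <- rbind(o_t[-1, ], o_c)
  expect_error(compare_arms(m, missing), class = "stim_validation_error",
               regexp = b$patient_id[1])
})

test_that("arm-comparison deltas are antisymmetric under swapping pair roles", {
  coh <- simulate_cohort(sim_config(n_per_arm_per_physician = 20,
                                    n_physicians = 2, seed = 13,
                                    miss_amh = 0, miss_afc = 0))$cohort
  m <- match_patients(coh$baselines)
  cmp <- compare_arms(m, coh$outcomes)
  swapped <- m
  swapped$pairs <- data.frame(treatment_id = m$pairs$control_id,
                              control_id = m$pairs$treatment_id,
                              physician_id = m$pairs$physician_id,
                              distance = m$pairs$distance,
                              stringsAsFactors = FALSE)
  cmp2 <- compare_arms(swapped, coh$outcomes)
  expect_equal(cmp2$delta, -cmp$delta)
  expect_equal(cmp2$t, -cmp$t)
  expect_equal(cmp2$p, cmp$p)
})

test_that("a simulated treatment effect is recovered by the matched comparison", {
  deltas <- vapply(1:8, function(s) {
    coh <- simulate_cohort(sim_config(n_per_arm_per_physician = 40,
                                      n_physicians = 2, seed = 300 + s,
                                      treatment_effect = 2,
                                      miss_amh = 0, miss_afc = 0))$cohort
    cmp <- compare_arms(match_patients(coh$baselines), coh$outcomes)
    cmp$delta[cmp$physician_id == "All" & cmp$outcome == "mii"]
  }, numeric(1))
  expect_gt(mean(deltas), 1.3)
  expect_lt(mean(deltas), 2.7)
})

test_that("matching improves covariate balance under a baseline shift", {
  b <- make_arms(n_t = 40, n_c = 120, seed = 17, shift = 0.4)
  m <- match_patients(b)
  expect_true(all(abs(m$smd$smd_post[m$smd$covariate %in% c("age", "amh", "afc")]) <
                    abs(m$smd$smd_pre[m$smd$covariate %in% c("age", "amh", "afc")])))
})

test_that("the baseline table reports matched-arm means per physician", {
  b <- make_arms(n_t = 20, n_c = 40, seed = 19)
  m <- match_patients(b)
  tab <- baseline_table(m, b)
  all_age <- tab[tab$physician_id == "All" & tab$covariate == "age", ]
  ti <- match(m$pairs$treatment_id, b$patient_id)
  expect_equal(all_age$mean_treatment, mean(b$age[ti]))
  expect_setequal(unique(tab$covariate), c("age", "amh", "afc", "bmi"))

  single <- rbind(
    data.frame(patient_id = "T1", physician_id = "MD1", arm = "treatment",
               age = 30, amh = 1.5, afc = 10, bmi = 22),
    data.frame(patient_id = "C1", physician_id = "MD1", arm = "control",
               age = 40, amh = 3.5, afc = 20, bmi = 28)
  )
  ms <- match_patients(single)
  ts <- baseline_table(ms, single)
  expect_equal(ts$mean_treatment[ts$covariate == "age"], c(30, 30))
  expect_equal(ts$mean_control[ts$covariate == "bmi"], c(28, 28))
})
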