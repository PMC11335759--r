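pred_frame <- function(days, today, plus1) {
  data.frame(cycle_day = days, mii_today = today, mii_plus1 = plus1,
             mii_plus2 = plus1)
}

acc_visits <- function(trigger_day = 10, e2_trigger = 3000,
                       days = c(trigger_day - 1, trigger_day)) {
  data.frame(
    patient_id = "P1", cycle_day = days, follicles = "16;18;20",
    e2 = ifelse(days == trigger_day, e2_trigger, 2000),
    fsh_pure = 150, fsh_combo = 75, lh = 75,
    is_trigger_day = days == trigger_day,
    trigger_type = ifelse(days == trigger_day, "hcg", "none"),
    stringsAsFactors = FALSE
  )
}

test_that("the accordance rule classifies each hand-worked branch correctly", {
  # both criteria hold: no predicted gain on trigger day (9.8 <= 10.0),
  # >= 5% predicted gain the visit before (8.6 >= 8.4)
  f1 <- classify_accordance(pred_frame(c(9, 10), c(8.0, 10.0), c(8.6, 9.8)),
                            acc_visits())
  expect_true(f1$accordant)
  expect_setequal(f1$reasons, c("no_gain_on_trigger_day",
                                "prior_visit_predicted_gain"))

  # E2 over threshold alone qualifies even with predictions absent
  f2 <- classify_accordance(pred_frame(integer(0), numeric(0), numeric(0)),
                            acc_visits(e2_trigger = 5200))
  expect_true(f2$accordant)
  expect_equal(f2$reasons, "e2_over_threshold")

  # both conditions fail: predicted gain on trigger day, prior gain under 5%
  f3 <- classify_accordance(pred_frame(c(9, 10), c(8.0, 10.0), c(8.1, 11.0)),
                            acc_visits(e2_trigger = 2000))
  expect_false(f3$accordant)
  expect_equal(f3$reasons, character(0))

  # condition 1 alone is not sufficient
  f4 <- classify_accordance(pred_frame(c(9, 10), c(8.0, 10.0), c(8.1, 9.5)),
                            acc_visits())
  expect_false(f4$accordant)

  # condition 2 alone is not sufficient
  f5 <- classify_accordance(pred_frame(c(9, 10), c(8.0, 10.0), c(8.6, 10.5)),
                            acc_visits())
  expect_false(f5$accordant)

  # boundary: exactly 5% prior gain counts, exactly-equal trigger-day
  # prediction counts as "no increase", E2 exactly at threshold does not
  f6 <- classify_accordance(pred_frame(c(9, 10), c(8.0, 10.0), c(8.4, 10.0)),
                            acc_visits(e2_trigger = 5000))
  expect_true(f6$accordant)
  f7 <- classify_accordance(pred_frame(c(9, 10), c(8.0, 10.0), c(8.39, 10.0)),
                            acc_visits(e2_trigger = 5000))
  expect_false(f7$accordant)

  expect_error(
    classify_accordance(pred_frame(10, 10, 9),
                        within(acc_visits(), is_trigger_day <- FALSE)),
    class = "stim_classification_error"
  )
})

test_that("missing predictions make the corresponding condition false", {
  # prediction only on the trigger day: cond2 unknowable -> not accordant
  f <- classify_accordance(pred_frame(10, 10.0, 9.5), acc_visits())
  expect_false(f$accordant)
  # prediction only on the prior visit: cond1 unknowable -> not accordant
  f2 <- classify_accordance(pred_frame(9, 8.0, 8.6), acc_visits())
  expect_false(f2$accordant)
})

test_that("the rule is monotone in its thresholds", {
  set.seed(23)
  cases <- lapply(1:200, function(i) {
    tday <- sample(8:12, 1)
    list(preds = pred_frame(c(tday - 1, tday),
                            runif(2, 5, 12), runif(2, 5, 13)),
         visits = acc_visits(trigger_day = tday,
                             e2_trigger = runif(1, 1000, 7000)))
  })
  flag_set <- function(gain, e2thr) {
    vapply(cases, function(cs)
      classify_accordance(cs$preds, cs$visits, gain_threshold = gain,
                          e2_threshold = e2thr)$accordant, logical(1))
  }
  base <- flag_set(0.05, 5000)
  expect_true(all(base >= flag_set(0.05, 6000)))      # raising E2 shrinks
  expect_true(all(flag_set(0.02, 5000) >= base))      # lowering gain grows
  # order invariance: flags are a pure per-patient function
  perm <- sample(length(cases))
  expect_equal(flag_set(0.05, 5000)[perm],
               vapply(cases[perm], function(cs)
                 classify_accordance(cs$preds, cs$visits)$accordant, logical(1)))
})

sim_with_surveys <- function(seed = 31, agree_dose = 0.6, agree_trig = 0.6,
                             n = 20) {
  coh <- simulate_cohort(sim_config(n_per_arm_per_physician = n,
                                    n_physicians = 2, seed = seed,
                                    miss_amh = 0, miss_afc = 0))$cohort
  coh$surveys <- simulate_survey(coh, agree_dose, agree_trig, seed = seed + 1)
  coh
}

test_that("accordance reporting subsets, re-matches, and degrades to empty", {
  coh <- sim_with_surveys(seed = 33)
  model <- train_trigger_model(build_training_rows(coh))
  flags <- accordance_flags(coh, model)
  expect_setequal(flags$patient_id,
                  coh$baselines$patient_id[coh$baselines$arm == "treatment"])

  all_on <- flags; all_on$accordant <- TRUE
  rep_all <- accordance_report(coh, all_on)
  full <- compare_arms(match_patients(coh$baselines), coh$outcomes)
  expect_equal(rep_all$comparison, full)

  none <- flags; none$accordant <- FALSE
  rep_none <- accordance_report(coh, none)
  expect_equal(rep_none$n_accordant, 0L)
  expect_equal(nrow(rep_none$comparison), 0L)
})

test_that("agree/disagree grouping applies the all-quantifier over verdicts", {
  coh <- sim_with_surveys(seed = 35)
  treat <- coh$baselines$patient_id[coh$baselines$arm == "treatment"]
  sv <- coh$surveys
  res <- agreement_groups(sv, coh)

  # independent recount of the quantifier
  oracle <- vapply(treat, function(pid) {
    v <- sv$verdict[sv$patient_id == pid & sv$verdict != "unavailable"]
    if (length(v) == 0 || all(v %in% c("confirmed", "changed"))) "agree" else "disagree"
  }, character(1))
  expect_equal(res$groups$group, unname(oracle[res$groups$patient_id]))
  # the two groups partition the treatment arm
  expect_setequal(res$groups$patient_id, treat)

  # hand-picked verdict patterns
  sv2 <- data.frame(patient_id = c("X", "X", "X", "Y", "Y"),
                    tool = "trigger", cycle_day = 7:11,
                    verdict = c("confirmed", "changed", "confirmed",
                                "confirmed", "ignored"),
                    stringsAsFactors = FALSE)
  b2 <- data.frame(patient_id = c("X", "Y", "Z"), physician_id = "MD1",
                   arm = c("treatment", "treatment", "control"),
                   age = c(34, 38, 36), amh = c(2, 3, 2.4),
                   afc = c(14, 18, 16), bmi = c(24, 26, 25),
                   stringsAsFactors = FALSE)
  coh2 <- list(baselines = b2,
               outcomes = data.frame(patient_id = c("X", "Y", "Z"),
                                     oocytes_retrieved = c(10, 12, 11),
                                     mii_count = c(8, 9, 9),
                                     total_fsh_iu = c(3000, 2800, 2900),
                                     trigger_day = c(10, 10, 10)))
  res2 <- agreement_groups(sv2, coh2)
  expect_equal(res2$groups$group[res2$groups$patient_id == "X"], "agree")
  expect_equal(res2$groups$group[res2$groups$patient_id == "Y"], "disagree")

  sv3 <- sv2[sv2$patient_id == "X", ]
  expect_error(agreement_groups(sv3, coh2), class = "stim_assignment_error",
               regexp = "Y")
})

test_that("unavailable-only patients are agree-by-vacuity and reported", {
  b <- data.frame(patient_id = c("U", "V", "W"), physician_id = "MD1",
                  arm = c("treatment", "treatment", "control"),
                  age = c(34, 38, 36), amh = c(2, 3, 2.4),
                  afc = c(14, 18, 16), bmi = c(24, 26, 25),
                  stringsAsFactors = FALSE)
  o <- data.frame(patient_id = c("U", "V", "W"),
                  oocytes_retrieved = c(10, 12, 11), mii_count = c(8, 9, 9),
                  total_fsh_iu = c(3000, 2800, 2900), trigger_day = c(10, 10, 10))
  sv <- data.frame(patient_id = c("U", "V"), tool = "starting_dose",
                   cycle_day = NA, verdict = c("unavailable", "confirmed"),
                   stringsAsFactors = FALSE)
  res <- agreement_groups(sv, list(baselines = b, outcomes = o))
  expect_equal(res$vacuous_ids, "U")
  expect_true(all(res$groups$group == "agree"))
  expect_null(res$disagree$comparison)
})
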