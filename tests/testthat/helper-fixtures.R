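# Fixtures built in code: a tiny hand-written 3-patient cohort and some
# convenience constructors used across test files.

tiny_baselines <- function() {
  data.frame(
    patient_id = c("P001", "P002", "P003"),
    physician_id = c("MD1", "MD1", "MD2"),
    arm = c("treatment", "control", "treatment"),
    age = c(34.5, 36.0, 41.2),
    amh = c(2.1, NA, 0.9),
    afc = c(15, 18, NA),
    bmi = c(23.0, 27.5, 31.1),
    stringsAsFactors = FALSE
  )
}

tiny_visits <- function() {
  data.frame(
    patient_id = c("P001", "P001", "P002", "P003"),
    cycle_day = c(9, 10, 10, 11),
    follicles = c("10;12;14.5", "11;13.5;16", "18;18.5;20", "9;10"),
    e2 = c(900, 1500, 2600, 700),
    fsh_pure = c(225, 225, 150, 300),
    fsh_combo = c(75, 75, 75, 0),
    lh = c(75, 75, 75, 0),
    is_trigger_day = c(FALSE, TRUE, TRUE, TRUE),
    trigger_type = c("none", "hcg", "lupron", "hcg"),
    stringsAsFactors = FALSE
  )
}

tiny_outcomes <- function() {
  data.frame(
    patient_id = c("P001", "P002", "P003"),
    oocytes_retrieved = c(12, 20, 4),
    mii_count = c(9, 15, 3),
    total_fsh_iu = c(600, 225, 300),
    trigger_day = c(10, 10, 11),
    stringsAsFactors = FALSE
  )
}

tiny_surveys <- function() {
  data.frame(
    patient_id = c("P001", "P001", "P003"),
    tool = c("starting_dose", "trigger", "starting_dose"),
    cycle_day = c(NA, 10, NA),
    verdict = c("confirmed", "changed", "ignored"),
    stringsAsFactors = FALSE
  )
}

tiny_cohort <- function(with_surveys = FALSE) {
  cohort(tiny_baselines(), tiny_visits(), tiny_outcomes(),
         if (with_surveys) tiny_surveys() else NULL)
}

# a hand-specified trigger model: intercept + coefficients per sub-model
manual_trigger_model <- function(intercepts, coefs = NULL) {
  feats <- c("bin_lt11", "bin_11_13", "bin_14_15", "bin_16_17",
             "bin_18_19", "bin_gt19", "e2")
  models <- lapply(names(intercepts), function(m) {
    co <- if (is.null(coefs)) stats::setNames(rep(0, 7), feats) else coefs[[m]]
    list(intercept = intercepts[[m]], coefficients = co, n = NA_integer_)
  })
  names(models) <- names(intercepts)
  structure(list(version = "stim-trigger-1", features = feats, models = models),
            class = "trigger_model")
}

constant_trigger_model <- function(mii_today, mii_plus1, mii_plus2,
                                   e2_plus1 = 1000, e2_plus2 = 1200) {
  manual_trigger_model(list(mii_0 = mii_today, mii_1 = mii_plus1,
                            mii_2 = mii_plus2, e2_1 = e2_plus1,
                            e2_2 = e2_plus2))
}
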