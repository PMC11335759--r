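#' Configuration for the synthetic IVF cohort generator
#'
#' Builds the parameter set controlling [simulate_cohort()] and
#' [simulate_reference()].  Defaults describe a multi-physician, two-arm
#' cohort on the scale typical of a mid-size IVF programme: mean age about
#' 36 years, AMH log-normal with mean about 2.6 ng/mL, AFC log-normal with
#' mean about 17, BMI about 25 kg/m^2, daily follicle growth a little over
#' 1 mm/day, and a concave FSH dose-response peaking at `d_star` IU.
#'
#' @param n_per_arm_per_physician patients per arm per physician.
#' @param n_physicians number of physicians.
#' @param seed integer master seed; every draw derives from it.
#' @param age_mean,age_sd baseline age distribution (years).
#' @param log_amh_mean,log_amh_sd log-scale AMH distribution (AMH in ng/mL).
#' @param log_afc_mean,log_afc_sd log-scale AFC distribution.
#' @param bmi_mean,bmi_sd baseline BMI distribution (kg/m^2).
#' @param d_star dose (IU) at which expected MII peaks.
#' @param d_scale saturation scale (IU) of the rising limb.
#' @param dose_decline per-IU linear decline in the stimulation multiplier
#'   past `d_star`; makes the optimum identifiable.
#' @param mii_scale expected MII for a reference-responder patient
#'   (response score 1) dosed at `d_star`.
#' @param growth_mean,growth_sd mean and sd of the per-follicle daily
#'   diameter increment (mm/day); increments are log-normal, so growth is
#'   strictly positive and diameters are non-decreasing.
#' @param follicle_rate_sd log-scale sd of a per-follicle growth-rate
#'   multiplier: individual follicles grow persistently faster or slower,
#'   producing the spread of lead and lagging follicles seen on
#'   monitoring ultrasound (and populating every diameter bin at trigger).
#' @param e2_coef serum E2 produced per follicle-mm (pg/mL per mm).
#' @param e2_noise_sd log-scale multiplicative noise on daily E2.
#' @param outcome_noise_sd additive Gaussian noise (MII) on the outcome model.
#' @param miss_amh,miss_afc missingness rates for baseline AMH/AFC.
#' @param treatment_effect additive shift in expected MII for the treatment
#'   arm (0 gives an exact null).
#' @param bin_coefs,e2_coef_mii,mii_intercept true coefficients of the
#'   MII-generating linear model over the six follicle bins and trigger-day
#'   E2; these are the ground truth the trigger tool estimates.
#' @param trigger_n_lead,trigger_lead_mm trigger when at least
#'   `trigger_n_lead` follicles reach `trigger_lead_mm` mm.
#' @param min_trigger_day,max_day trigger day is clamped to this range.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_arm_per_physician = 25,
                       n_physicians = 4,
                       seed = 1,
                       age_mean = 36.1, age_sd = 4.5,
                       log_amh_mean = log(2.2), log_amh_sd = 0.6,
                       log_afc_mean = log(15.5), log_afc_sd = 0.45,
                       bmi_mean = 24.66, bmi_sd = 3.8,
                       d_star = 300, d_scale = 150, dose_decline = 0.002,
                       mii_scale = 14,
                       growth_mean = 1.35, growth_sd = 0.4,
                       follicle_rate_sd = 0.25,
                       e2_coef = 13, e2_noise_sd = 0.08,
                       outcome_noise_sd = 2,
                       miss_amh = 0.005, miss_afc = 0.05,
                       treatment_effect = 0,
                       bin_coefs = c(0, 0.15, 0.5, 0.8, 0.9, 0.85),
                       e2_coef_mii = 4e-4,
                       mii_intercept = 0.5,
                       trigger_n_lead = 3, trigger_lead_mm = 18,
                       min_trigger_day = 8, max_day = 14) {
  cfg <- as.list(environment())
  sds <- c(cfg$age_sd, cfg$log_amh_sd, cfg$log_afc_sd, cfg$bmi_sd,
           cfg$growth_sd, cfg$outcome_noise_sd)
  if (any(sds <= 0)) abort_input("all sd parameters must be > 0")
  if (cfg$miss_amh < 0 || cfg$miss_amh > 1 || cfg$miss_afc < 0 || cfg$miss_afc > 1) {
    abort_input("missingness rates must lie in [0, 1]")
  }
  if (cfg$n_per_arm_per_physician < 1 || cfg$n_physicians < 1) {
    abort_input("cohort sizes must be >= 1")
  }
  if (length(cfg$bin_coefs) != 6) abort_input("bin_coefs must have length 6")
  if (cfg$min_trigger_day < 1 || cfg$max_day < cfg$min_trigger_day) {
    abort_input("need 1 <= min_trigger_day <= max_day")
  }
  structure(cfg, class = "sim_config")
}

# Deterministic per-patient substream seed: a Lehmer-style mix of the master
# seed and the patient index, so enlarging the cohort never reshuffles the
# draws of earlier patients.
MOD31 <- 2147483647
substream_seed <- function(seed, i) {
  ((seed %% MOD31) * 48271 + i * 16807 + 12345) %% MOD31
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' True expected MII as a function of starting dose
#'
#' The generator's ground-truth dose-response: a saturating-exponential
#' rise with scale `d_scale`, followed by a mild linear decline past
#' `d_star`, normalised so the curve equals `mii_scale * response_score`
#' at `d_star`.  The curve is unimodal with its maximum exactly at
#' `d_star`.
#'
#' @param dose numeric vector of starting doses (IU).
#' @param config a [sim_config()].
#' @param response_score per-patient latent response multiplier.
#' @return expected MII at each dose.
#' @export
true_dose_response <- function(dose, config, response_score = 1) {
  m <- (1 - exp(-dose / config$d_scale)) -
    config$dose_decline * pmax(0, dose - config$d_star)
  m_star <- 1 - exp(-config$d_star / config$d_scale)
  config$mii_scale * response_score * m / m_star
}

# latent response multiplier from the (true, pre-missingness) baselines
response_score <- function(age, amh, afc, config, noise = 0) {
  (pmax(amh, 0.05) / 2.5)^0.35 * (pmax(afc, 1) / 16)^0.45 *
    exp(-0.02 * (age - config$age_mean)) * exp(noise)
}

# clinic-style dosing: more FSH for lower reserve, snapped to half-vials
assign_dose <- function(amh, afc, noise) {
  snap_to_step(clip(300 - 60 * log(pmax(amh, 0.1) / 2.5) -
                      2.5 * (afc - 16) + noise, 75, 450), 37.5)
}

#' Simulate a two-arm, multi-physician stimulation cohort
#'
#' Generates baselines, daily monitoring visits, cycle outcomes and the
#' latent ground truth that produced them.  Per patient, in a fixed
#' substream order: baseline covariates are drawn (AMH and AFC log-normal),
#' a starting dose is assigned by a reserve-dependent dosing rule, a
#' dose-dependent number of follicles is recruited, follicles grow by
#' log-normal daily increments from cycle day 1, daily E2 is proportional
#' to the total follicle diameter with multiplicative noise, the trigger
#' fires when `trigger_n_lead` follicles reach `trigger_lead_mm` mm
#' (clamped to `[min_trigger_day, max_day]`), and the realised MII count is
#' a noisy linear function of the trigger-day follicle-bin counts and E2
#' with the stored true coefficients, rounded and clipped at zero.  Oocytes
#' retrieved are MII plus an independent non-negative count, so
#' `mii_count <= oocytes_retrieved` always holds.  The starting dose enters
#' the outcome only through follicle recruitment, which is scaled by the
#' unimodal multiplier of [true_dose_response()]; expected MII as a
#' function of dose therefore peaks at `d_star`.
#'
#' @param config a [sim_config()].
#' @return a list with elements `cohort` (a validated [cohort()]) and
#'   `ground_truth` (list of `patients`, `visits`, `coefficients`; see
#'   [write_ground_truth()]).  The ground truth is never consumed by any
#'   estimation stage.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_phys <- config$n_physicians
  n_pp <- config$n_per_arm_per_physician
  n <- 2L * n_phys * n_pp
  layout <- expand.grid(slot = seq_len(n_pp),
                        arm = c("treatment", "control"),
                        physician = seq_len(n_phys),
                        stringsAsFactors = FALSE)
  m_star <- 1 - exp(-config$d_star / config$d_scale)
  g_sdlog <- sqrt(log(1 + (config$growth_sd / config$growth_mean)^2))
  g_meanlog <- log(config$growth_mean) - g_sdlog^2 / 2

  # flat accumulators (one data.frame construction at the end keeps the
  # per-patient loop cheap enough for replicate-study simulations)
  B_age <- B_amh <- B_afc <- B_bmi <- numeric(n)
  O_ooc <- O_mii <- O_fsh <- O_tday <- numeric(n)
  GT_r <- GT_dose <- GT_amh <- GT_afc <- numeric(n)
  pids <- sprintf("P%05d", seq_len(n))
  V_fol <- V_e2 <- V_days <- V_ttype <- GTV_exp <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i))
    arm <- layout$arm[i]

    # 1. baselines
    age <- clip(stats::rnorm(1, config$age_mean, config$age_sd), 21, 45)
    amh <- stats::rlnorm(1, config$log_amh_mean, config$log_amh_sd)
    afc <- max(1, round(stats::rlnorm(1, config$log_afc_mean, config$log_afc_sd)))
    bmi <- clip(stats::rnorm(1, config$bmi_mean, config$bmi_sd), 17, 45)

    # 2. latent response, dose, recruitment
    r <- response_score(age, amh, afc, config, noise = stats::rnorm(1, 0, 0.15))
    dose <- assign_dose(amh, afc, stats::rnorm(1, 0, 55))
    m_norm <- ((1 - exp(-dose / config$d_scale)) -
                 config$dose_decline * max(0, dose - config$d_star)) / m_star
    n_fol <- 1L + stats::rpois(1, 15.5 * r * m_norm)

    # 3. follicle growth: day-1 sizes plus positive log-normal increments,
    # scaled by a persistent per-follicle rate (lead vs lagging follicles)
    d0 <- pmax(2, stats::rnorm(n_fol, 5, 1.5))
    rate <- stats::rlnorm(n_fol, -config$follicle_rate_sd^2 / 2,
                          config$follicle_rate_sd)
    inc <- rate * matrix(stats::rlnorm(n_fol * (config$max_day - 1),
                                       g_meanlog, g_sdlog),
                         nrow = n_fol)
    diam <- cbind(d0, d0 + t(apply(inc, 1, cumsum)))   # n_fol x max_day

    # 4. daily E2 and trigger day
    sum_mm <- colSums(diam)
    e2 <- config$e2_coef * sum_mm *
      exp(stats::rnorm(config$max_day, 0, config$e2_noise_sd))
    lead <- colSums(diam >= config$trigger_lead_mm)
    hit <- which(lead >= config$trigger_n_lead)
    t_day <- clip(if (length(hit)) hit[1] else config$max_day,
                  config$min_trigger_day, config$max_day)

    # 5. outcome: linear in trigger-day bins + E2, with stored coefficients
    days <- seq_len(t_day)
    bins_by_day <- vapply(days, function(d) bin_follicles(diam[, d]), numeric(6))
    lin_by_day <- config$mii_intercept +
      as.numeric(config$bin_coefs %*% bins_by_day) +
      config$e2_coef_mii * e2[days] +
      if (arm == "treatment") config$treatment_effect else 0
    lin <- lin_by_day[t_day]
    mii <- max(0, round(lin + stats::rnorm(1, 0, config$outcome_noise_sd)))
    oocytes <- mii + stats::rpois(1, 0.35 * max(lin, 0) + 1)
    ttype <- if (e2[t_day] > 4500) {
      sample(c("lupron", "dual"), 1, prob = c(0.7, 0.3))
    } else "hcg"

    # 6. missingness on the recorded baseline
    B_amh[i] <- if (stats::runif(1) < config$miss_amh) NA_real_ else amh
    B_afc[i] <- if (stats::runif(1) < config$miss_afc) NA_real_ else afc
    B_age[i] <- age; B_bmi[i] <- bmi
    O_ooc[i] <- oocytes; O_mii[i] <- mii
    O_fsh[i] <- dose * t_day; O_tday[i] <- t_day
    GT_r[i] <- r; GT_dose[i] <- dose; GT_amh[i] <- amh; GT_afc[i] <- afc
    V_days[[i]] <- days
    V_fol[[i]] <- vapply(days, function(d)
      paste(signif(diam[, d], 8), collapse = ";"), character(1))
    V_e2[[i]] <- e2[days]
    V_ttype[[i]] <- ifelse(days == t_day, ttype, "none")
    GTV_exp[[i]] <- pmax(lin_by_day, 0)
  }

  nv <- lengths(V_days)
  v_pid <- rep(pids, nv)
  v_days <- unlist(V_days, use.names = FALSE)
  v_dose <- rep(GT_dose, nv)
  baselines <- data.frame(
    patient_id = pids, physician_id = sprintf("MD%d", layout$physician),
    arm = layout$arm, age = B_age, amh = B_amh, afc = B_afc, bmi = B_bmi,
    stringsAsFactors = FALSE
  )
  visits <- data.frame(
    patient_id = v_pid, cycle_day = v_days,
    follicles = unlist(V_fol, use.names = FALSE),
    e2 = unlist(V_e2, use.names = FALSE),
    fsh_pure = 0.75 * v_dose, fsh_combo = 0.25 * v_dose, lh = 0.25 * v_dose,
    is_trigger_day = v_days == rep(O_tday, nv),
    trigger_type = unlist(V_ttype, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  outcomes <- data.frame(
    patient_id = pids, oocytes_retrieved = O_ooc, mii_count = O_mii,
    total_fsh_iu = O_fsh, trigger_day = O_tday, stringsAsFactors = FALSE
  )
  gt <- list(
    patients = data.frame(patient_id = pids, response_score = GT_r,
                          optimal_dose = config$d_star, starting_dose = GT_dose,
                          true_amh = GT_amh, true_afc = GT_afc,
                          stringsAsFactors = FALSE),
    visits = data.frame(patient_id = v_pid, cycle_day = v_days,
                        expected_mii = unlist(GTV_exp, use.names = FALSE),
                        stringsAsFactors = FALSE),
    coefficients = data.frame(
      feature = c("intercept", paste0("bin_", FOLLICLE_BIN_LABELS), "e2"),
      value = c(config$mii_intercept, config$bin_coefs, config$e2_coef_mii),
      stringsAsFactors = FALSE
    )
  )
  list(cohort = cohort(baselines, visits, outcomes), ground_truth = gt)
}

#' Simulate a historical reference table for the starting-dose tool
#'
#' The starting-dose tool retrieves neighbours from a large historical
#' table of (baseline covariates, starting dose, MII outcome) rows.  This
#' generator draws baselines and doses exactly as [simulate_cohort()] does
#' and realises MII directly from the ground-truth dose-response
#' [true_dose_response()] plus Gaussian noise, giving a reference cohort
#' whose optimal dose is `d_star` by construction.  Unlike the trial
#' cohort of [simulate_cohort()], historical starting doses here follow
#' wide practice variation *independent* of the baseline covariates
#' (centred on 300 IU): conditional dose ignorability within a
#' neighbourhood of similar patients is exactly the assumption under
#' which neighbourhood dose-response fitting identifies the optimum.
#'
#' @param n number of historical cycles.
#' @param config a [sim_config()]; `config$seed` drives the draws.
#' @return a data frame with columns `patient_id`, `age`, `amh`, `afc`,
#'   `bmi`, `starting_dose_iu`, `mii_count` and no missing values, with
#'   attribute `optimal_dose`.
#' @export
simulate_reference <- function(n, config) {
  stopifnot(inherits(config, "sim_config"))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i))
    age <- clip(stats::rnorm(1, config$age_mean, config$age_sd), 21, 45)
    amh <- stats::rlnorm(1, config$log_amh_mean, config$log_amh_sd)
    afc <- max(1, round(stats::rlnorm(1, config$log_afc_mean, config$log_afc_sd)))
    bmi <- clip(stats::rnorm(1, config$bmi_mean, config$bmi_sd), 17, 45)
    r <- response_score(age, amh, afc, config, noise = stats::rnorm(1, 0, 0.15))
    dose <- snap_to_step(clip(stats::rnorm(1, 300, 80), 75, 450), 37.5)
    mu <- true_dose_response(dose, config, r)
    mii <- max(0, round(mu + stats::rnorm(1, 0, config$outcome_noise_sd)))
    out[[i]] <- data.frame(patient_id = sprintf("R%06d", i), age = age,
                           amh = amh, afc = afc, bmi = bmi,
                           starting_dose_iu = dose, mii_count = mii,
                           stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out), optimal_dose = config$d_star)
}

#' Simulate clinician survey responses
#'
#' One starting-dose response per patient, plus one trigger-tool response
#' per monitored visit from cycle day 7 up to the trigger day.  Each
#' response agrees (verdict `"confirmed"` or `"changed"`, equally likely)
#' with probability `agree_rate_*`, is `"unavailable"` with probability
#' `unavailable_rate`, and is `"ignored"` otherwise.
#'
#' @param cohort a `stim_cohort`.
#' @param agree_rate_dose,agree_rate_trigger per-response agreement rates.
#' @param seed integer seed.
#' @param unavailable_rate rate of missing-data responses (drawn first).
#' @param from_day first cycle day with trigger-tool responses.
#' @return a survey data frame (see [cohort()]).
#' @export
simulate_survey <- function(cohort, agree_rate_dose, agree_rate_trigger,
                            seed, unavailable_rate = 0, from_day = 7) {
  rates <- c(agree_rate_dose, agree_rate_trigger, unavailable_rate)
  if (any(rates < 0 | rates > 1)) abort_input("rates must lie in [0, 1]")
  set.seed(substream_seed(seed, 0))
  draw <- function(agree_rate, n) {
    u <- stats::runif(n)
    v <- stats::runif(n)
    w <- stats::runif(n)
    ifelse(u < unavailable_rate, "unavailable",
           ifelse(v < agree_rate,
                  ifelse(w < 0.5, "confirmed", "changed"),
                  "ignored"))
  }
  b <- cohort$baselines[order(cohort$baselines$patient_id), , drop = FALSE]
  dose_rows <- data.frame(patient_id = b$patient_id, tool = "starting_dose",
                          cycle_day = NA_integer_,
                          verdict = draw(agree_rate_dose, nrow(b)),
                          stringsAsFactors = FALSE)
  v <- cohort$visits
  v <- v[v$cycle_day >= from_day, , drop = FALSE]
  v <- v[order(v$patient_id, v$cycle_day), , drop = FALSE]
  trig_rows <- data.frame(patient_id = v$patient_id, tool = "trigger",
                          cycle_day = v$cycle_day,
                          verdict = draw(agree_rate_trigger, nrow(v)),
                          stringsAsFactors = FALSE)
  rbind(dose_rows, trig_rows)
}

#' Write ground truth tables
#'
#' Writes `ground_truth.csv` (per-patient latent response score, optimal
#' dose, assigned dose, pre-missingness AMH/AFC), `ground_truth_visits.csv`
#' (expected MII if triggering on each monitored day) and
#' `ground_truth_coefficients.csv` (the true outcome-model coefficients).
#'
#' @param ground_truth the `ground_truth` element of [simulate_cohort()].
#' @param dir output directory.
#' @export
write_ground_truth <- function(ground_truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ground_truth$patients, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, na = "", quote = FALSE)
  utils::write.csv(ground_truth$visits, file.path(dir, "ground_truth_visits.csv"),
                   row.names = FALSE, na = "", quote = FALSE)
  utils::write.csv(ground_truth$coefficients,
                   file.path(dir, "ground_truth_coefficients.csv"),
                   row.names = FALSE, na = "", quote = FALSE)
  invisible(dir)
}
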