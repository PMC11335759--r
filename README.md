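# stimtools

Decision-support algorithms and matched-control evaluation for IVF
ovarian stimulation.

During ovarian stimulation a clinician makes two decisions that largely
determine how many mature (MII) oocytes a cycle yields: the starting
daily dose of FSH, and the day the trigger injection is given.
`stimtools` implements interpretable models for both decisions and the
observational-study machinery used to evaluate such tools against
historical controls:

- **Starting-dose tool.** For a patient with baseline age, BMI, AMH and
  AFC, retrieve the *k* = 100 most similar patients from a historical
  reference cohort (Euclidean distance on standardized, log-transformed
  features) and fit a degree-2 polynomial of MII count on starting dose
  with bootstrap 2.5/97.5-percentile bands:

  ŷ(d) = β₀ + β₁d + β₂d², d ∈ [min, max neighbour dose]

  The recommended dose is the curve's argmax snapped to 37.5-IU
  half-vial increments.

- **Trigger tool.** One OLS regression per horizon h ∈ {0, 1, 2} (MII
  if triggering today / tomorrow / in two days) plus E2 forecasts, all
  linear in (n₁, …, n₆, E2) where nⱼ are the day's follicle counts in
  the six diameter bins <11, 11–13, 14–15, 16–17, 18–19, >19 mm.
  Predictions are clipped at zero and projected onto biologically
  feasible trajectories: a predicted decline tomorrow is never followed
  by a predicted rise in two days.

- **Evaluation pipeline.** KNN imputation of missing baselines,
  per-physician 1-to-1 nearest-neighbour matching with replacement on
  (age, log AMH, log AFC), standardized-mean-difference balance
  diagnostics, Welch/paired t-tests on oocytes, MII, total FSH and
  trigger day, a rule-based classification of whether each cycle was
  triggered in accordance with the tool, and survey-based
  agree/disagree stratification.

- **Synthetic cohorts.** Seeded generators for two-arm multi-physician
  cohorts with daily follicle growth and E2 kinetics, a known concave
  dose–response (optimum 300 IU), stored ground-truth outcome
  coefficients, configurable missingness and treatment effect — so the
  entire pipeline is testable without clinical data.

## Worked example

```r
library(stimtools)

## a synthetic trial cohort: 4 physicians, 25 patients/arm each
sim <- simulate_cohort(sim_config(seed = 42, treatment_effect = 0.5))
coh <- sim$cohort
coh
#> <stim_cohort> 200 patients, 1880 visits, 200 outcomes

## starting-dose tool against a 2000-cycle historical reference
ref <- simulate_reference(2000, sim_config(seed = 7))
patient <- data.frame(patient_id = "NEW", age = 34, amh = 1.8, afc = 14, bmi = 23)
curve <- starting_dose_curve(ref, patient, k = 100, seed = 1)
curve
#> <dose_response_curve> degree 2 on [150, 450] IU; predicted MII max 12.28 at 300 IU
recommend_dose(curve)
#> [1] 300

## trigger tool trained on the cohort's completed cycles
model <- train_trigger_model(build_training_rows(coh))
predict_trigger(model, list(follicles = c(11, 12.5, 14, 15.5, 16, 17, 18, 19.5, 21),
                            e2 = 2100))
#> <trigger_prediction> MII 6.9 today / 7.5 tomorrow / 7.7 in two days; E2 2140 / 2374 pg/mL

## matched-control evaluation
coh$baselines <- impute_baseline(coh$baselines, ref)$patients
m <- match_patients(coh$baselines)
m
#> <match_result> 100 pairs (61 distinct controls) on {age, amh, afc}
#>   covariate     smd_pre    smd_post
#> 1       age -0.01398060 -0.04430184
#> 2       amh  0.13930021  0.06120615
#> 3       afc  0.14989349  0.06352013
#> 4       bmi  0.06007899  0.06630558
subset(as.data.frame(compare_arms(m, coh$outcomes)), physician_id == "All")
#>  physician_id n_pairs     outcome mean_treatment mean_control  delta      t      p
#>           All     100     oocytes          14.90        13.87   1.03  1.358 0.1761
#>           All     100         mii          10.30         9.53   0.77  1.449 0.1490
#>           All     100   total_fsh        2811.00      2841.75 -30.75 -0.255 0.7991
#>           All     100 trigger_day           9.45         9.16   0.29  1.677 0.0952
```

Reading the output: the dose curve predicts a maximum of ~12.3 MII at a
300 IU starting dose for this patient's neighbourhood; the trigger
prediction (rising 6.9 → 7.5 → 7.7) suggests continuing stimulation;
after matching, the covariate imbalance (SMD) drops below 0.07 on every
matching covariate, and the treatment arm shows a +0.77 MII improvement
over matched controls (p = 0.15) — consistent with the +0.5 effect and
slightly longer stimulation built into this simulated cohort.

The end-to-end pipeline (simulate → dose curves → trigger model →
matching → subanalyses, with every report CSV stamped by config hash and
seed) is one call:

```r
run_all(system.file("extdata", "demo_config.yaml", package = "stimtools"), "report/")
```

or from a shell via the thin CLI wrapper
`Rscript inst/cli/stim.R run-all --config inst/extdata/demo_config.yaml --out report/`
(subcommands: `simulate`, `dose`, `train-trigger`, `trigger`,
`evaluate`, `subanalysis`, `run-all`).

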