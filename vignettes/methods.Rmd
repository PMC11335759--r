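---
title: "Models and methods behind stimtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stimtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

stimtools implements two decision-support algorithms used during IVF
ovarian stimulation — a starting-dose tool and a trigger-timing tool —
together with the matched-control machinery needed to evaluate them on a
cohort, and a synthetic-cohort generator that makes the whole pipeline
testable without clinical data. This vignette explains each model, the
parameters that matter, the numerical choices, and what the synthetic
experiments do and do not demonstrate.

## The starting-dose tool

Before stimulation begins, the clinician chooses a daily starting dose of
FSH. The tool estimates, for one patient, the expected number of mature
(MII) oocytes over a range of starting doses:

1. **Standardization.** Reference patients are described by age, BMI, AMH
   and AFC. AMH and AFC are right-skewed, so they are log-transformed
   (`log(x + 0.01)`; the offset keeps a measured zero finite and is
   negligible at typical values around 2 ng/mL and 16 follicles). Each
   feature is then z-scored with the population (divide-by-*n*) standard
   deviation. The reference means/sds are stored and reused to project
   query patients, so a query identical to a reference patient lands
   exactly on it.
2. **Retrieval.** The `k = 100` nearest reference patients by Euclidean
   distance in this space. The notion of "most similar" admits many
   metrics; Euclidean on standardized features is the neutral default
   used here. Ties are broken by
   patient id so results are permutation invariant.
3. **Curve fitting.** A degree-2 least-squares polynomial of neighbour
   MII on neighbour starting dose, evaluated on a 12.5-IU grid spanning
   the neighbours' observed dose range. Degree 2 is the lowest degree
   that admits an interior maximum and is hard to overfit on 100 points;
   it is a configurable knob. The grid never extrapolates beyond
   observed doses.
4. **Bands.** "95th-percentile" bands are realized as pointwise
   2.5/97.5 percentiles of curves refit on bootstrap resamples of the
   neighbour set (500 by default, seeded). Among the many ways to put
   bands on a fitted curve, bootstrap percentiles are a standard,
   assumption-light choice. Bands are widened, where needed,
   to contain the point fit, so `band_low <= fit <= band_high` holds
   pointwise; with noiseless neighbours all three curves coincide.
5. **Recommendation.** The grid argmax, ties toward the lower dose,
   snapped to multiples of 37.5 IU (half a 75-IU vial), exact halves
   rounded down.

**Identifiability caveat.** The neighbourhood curve estimates a causal
dose-response only if, among similar patients, dose assignment is
unrelated to residual prognosis. The synthetic *reference* generator
therefore assigns historical doses by wide practice variation independent
of the baseline covariates. When we instead dose the reference by ovarian
reserve (as clinics do, and as the simulated *trial* cohort does), the
within-neighbourhood dose-outcome association is confounded and the
fitted argmax is biased low — a useful reminder that the tool's validity
on real registries rests on dose-practice variation, not on the fitting
machinery.

## The trigger tool

From cycle day 7 onward the clinician decides each visit whether to
trigger final maturation. The tool fits one OLS regression per target —
MII if triggering today (+0), tomorrow (+1), in two days (+2), and E2
tomorrow / in two days — all over the same seven features: the day's
follicle diameters binned into six groups (<11, 11–13, 14–15, 16–17,
18–19, >19 mm) plus the day's E2. Bins are half-open on the millimetre
scale (11–13 means 11 ≤ d < 14) so every positive diameter falls in
exactly one bin. Only the most recent visit's measurements are used as
inputs.

Training rows come from completed cycles: a visit at day `t` with trigger
at day `T` contributes to horizon `h = T − t` when `h ∈ {0, 1, 2}`. Each
cycle yields a single MII count, so that one label is shared by all its
horizon rows — the only outcome a cycle can provide. This label sharing
means the +1/+2 models estimate the association between *pre-trigger*
morphology and the *eventual* yield, not a counterfactual yield at an
earlier trigger; it is the honest best available from observational
cycles and is stated here rather than hidden.

An optional ridge penalty (intercept unpenalized) handles collinear bins
in small cohorts; at penalty 0 a rank-deficient design is refused with an
error that says so.

**Feasibility projection.** Predicted MII cannot decline tomorrow and
then rise in two days. Raw predictions are clipped at zero, then if
`mii_plus1 < mii_today` the two-day value is capped at `mii_plus1`. Only
the forbidden pattern is specified by the method; capping is the minimal
correction that preserves the other two values, and it is idempotent.

## The evaluation pipeline

- **Imputation.** Missing AMH/AFC/BMI are filled with the mean of the
  `k_impute = 10` nearest complete reference patients in the standardized
  space of the patient's observed features (10 is the common KNN-imputer
  default, and results are insensitive between 5 and 25 on the synthetic
  cohorts). Imputed AFC is
  rounded, since it is a count.
- **Matching.** For each physician separately, each treatment patient is
  paired with that physician's nearest control in standardized (age,
  log AMH, log AFC) space, with replacement. Standardization statistics
  are computed across all patients, both arms pooled. BMI is excluded
  from the distance but reported in the balance table.
- **Comparison.** Means, treatment−control deltas, and two-sided t-tests
  per physician and pooled, for oocytes, MII, total FSH (pure FSH plus
  the FSH component of combined preparations; LH excluded) and trigger
  day.

**Which t-test?** The
default is Welch's unequal-variance test with matched controls
entered once per pair. Because matching is *with replacement*, repeated
controls shrink the apparent control-arm variance: in null simulations
(100 patients/arm, four physicians, 1000 replicates) the pair-weighted
Welch test rejects at ~0.11 and a paired test at ~0.15 instead of 0.05,
with a control duplication factor around 2.2. Counting each distinct
matched control once (`compare_arms(weighting = "unique")`) measures
~0.04 — slightly conservative because matched pairs are positively
correlated — and is what the package's calibration study uses. The
pair-weighted mean remains the default *point estimate* because it is
the arithmetic of a matched cohort; the weighting flag only changes how
the control sample enters the test.

- **Accordance subanalysis.** A treatment cycle counts as triggered in
  accordance with the tool when (1) on trigger day the model predicted
  no MII gain from waiting a day, **and** (2) at the previous monitored
  visit it predicted at least a 5% gain from waiting — or when
  trigger-day E2 exceeded 5000 pg/mL (the OHSS safety threshold).
  Comparisons are read off at face value: "did not predict an increase"
  as `<=`, "at least a 5% increase" as `>= 1.05×`, the E2 threshold as
  strict `>`. A missing prediction makes its condition false (and is
  recorded). The "previous visit" is the most recent monitored visit
  strictly before trigger, regardless of calendar gap; condition (2)
  uses that visit's +1-horizon prediction, matching the wording "if
  waiting to trigger tomorrow". Accordant patients are re-matched and
  re-compared with the same machinery.
- **Survey subanalysis.** A patient is in the *agree* group when every
  recorded verdict is "confirmed" or "changed", and in *disagree* when
  any is "ignored". "Unavailable" verdicts (predictions missing for
  data reasons, not disagreement) are excluded from the quantifier; a
  patient with only unavailable verdicts is agree-by-vacuity and
  reported separately rather than silently pushed into either group.

## The synthetic cohort generator

The generator emulates a two-arm, multi-physician cohort at the scale of
a mid-size IVF programme: age ≈ N(36.1, 4.5²) years, AMH log-normal with
mean ≈ 2.6 ng/mL, AFC log-normal with mean ≈ 17, BMI ≈ N(24.7, 3.8²)
kg/m², about 0.5% missing AMH and 5% missing AFC. Each patient receives
a latent response score increasing in AMH and AFC and mildly decreasing
in age.

Dynamics per cycle: a dose-dependent number of follicles is recruited;
follicles start near 5 mm and grow by positive log-normal daily
increments (mean 1.35 mm/day), each scaled by a persistent per-follicle
rate (log-sd 0.25) so monitoring shows the usual spread of lead and
lagging follicles and every diameter bin is populated at trigger; daily
E2 is 13 pg/mL per follicle-mm with 8% multiplicative noise; the trigger
fires when three follicles reach 18 mm, clamped to days 8–14 (a
conventional lead-follicle rule). These defaults were set once to
reproduce realistic cycle summaries (mean MII ≈ 10, oocytes ≈ 14.5,
total FSH ≈ 2900 IU, trigger day ≈ 9.3, trigger-day E2 ≈ 3100 pg/mL with
a few percent above 5000).

The realized MII count is a noisy linear function of the trigger-day bin
counts and E2, with coefficients (0, 0.15, 0.5, 0.8, 0.9, 0.85 per bin;
4·10⁻⁴ per pg/mL; intercept 0.5) stored as ground truth — mature eggs
come predominantly from mid-to-large follicles. Noise is Gaussian
(sd 2), the count is rounded and clipped at zero, and oocytes retrieved
are MII plus an independent non-negative count, so `mii ≤ oocytes` by
construction. Starting dose influences the outcome *only* through
follicle recruitment, scaled by a saturating-exponential multiplier
(scale 150 IU) with a linear decline of 0.002/IU past the 300 IU
plateau. The decline makes the optimum identifiable; its size was chosen
analytically so that both the true curve's argmax and the least-squares
quadratic projection of the curve over realistic dose designs sit at
≈300 IU. An additive treatment effect on expected MII (default 0) gives
exact nulls for calibration studies.

Randomness is organized as one substream per patient, deterministically
derived from the master seed and the patient index, so enlarging a
cohort never reshuffles earlier patients and any cohort is reproducible
byte-for-byte from its seed.

**What passing tests show — and what they do not.** The generator's
outcome model is exactly the linear model the trigger tool fits, so
coefficient recovery there demonstrates correct estimation machinery,
not that real MII counts are linear in bin counts. Likewise the
reference generator satisfies dose ignorability by design; real
registries may not, and the dose tool inherits whatever confounding they
carry. Missingness is completely at random, survey verdicts are
independent across visits, and there is no dose adjustment mid-cycle, no
cycle cancellation, and no OHSS event process.

## Problem sizes and numerical choices

The statistical checks in the test suite use: 500-patient cohorts with
20 queries for exact KNN-oracle agreement; 20 replicates of 2000
completed cycles for coefficient recovery (CI coverage pooled over the
eight coefficients, expected 95%, required ≥ 90%); 50 seeds of a
2000-cycle reference for dose-optimum recovery within one 37.5-IU step;
1000 null studies of 100 patients/arm for type-I calibration of the
matched comparison (required within [0.03, 0.07]); and 50 seeds of a
150-vs-300 single-pool cohort with a 0.4-sd covariate shift for
post-matching balance (|SMD| < 0.1 on all three matching covariates).
Balance attainable by nearest-neighbour matching degrades with small
control pools — the matching discrepancy scales roughly like the inverse
cube root of the pool size in three matching dimensions — so the balance
property is assessed on one pool large enough that the SMD diagnostic
itself is not noise-dominated.

Degenerate inputs are handled explicitly rather than by accident:
zero-variance features refuse to standardize; fewer than three distinct
neighbour doses refuse a curve; a constant outcome yields a flat curve
whose recommendation falls to the lowest dose by the tie rule; t-tests
on zero-variance samples return t = 0, p = 1 when the means agree;
bootstrap resamples that lose polynomial support are redrawn (bounded).
Model files carry a version tag, the feature order, and coefficients at
17 significant digits, so a load-after-save reproduces predictions
exactly and a mismatched schema fails loudly.

## Known limitations

Trigger-type pharmacology (hCG vs GnRH-agonist) is recorded as a
category only; live-birth and euploidy outcomes are out of scope; the
matched design corrects observed-covariate imbalance only — it is not a
randomized comparison, and unobserved prognostic differences between a
treatment period and a historical control period pass straight through,
exactly as in any historically controlled study.
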