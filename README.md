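# actikids

Device-measured movement behaviours and their developmental trajectories in
young children, as one reproducible R pipeline.

Cohort studies of preschool-aged children increasingly measure physical
activity with hip-worn tri-axial accelerometers. Getting from a raw 30 Hz
signal to a statement like *"energetic play rises through early childhood
but stays below the 60-minute guideline"* requires a long chain of
decisions: windowing and feature extraction, a machine-learned activity
classifier, non-wear detection, valid-day rules, age-specific guideline
scoring, and a longitudinal model flexible enough for non-linear age
effects. `actikids` implements that whole chain for researchers in
paediatric physical-activity epidemiology, together with a fully seeded
synthetic-data module that generates every input with known ground truth —
so each stage, and the pipeline end to end, is testable.

## What is implemented

* **Signal**: vector magnitude $\sqrt{x^2+y^2+z^2}$, 15-s non-overlapping
  windows, a fixed 25-feature time/frequency contract per window
  (`extract_features()`, `feature_names()`).
* **Classifier**: 500-tree random forest over five classes — SED, L_ACT_G,
  MV_ACT_G, WALK, RUN — with leave-one-subject-out validation and pooled
  confusion-matrix metrics (`train_activity_model()`, `loso_cv()`);
  classes map to intensities with energetic play (MVPA) = WALK + RUN +
  MV_ACT_G (`map_to_intensity()`).
* **Wear**: non-wear as vector-magnitude SD < 13 mg for ≥ 30 consecutive
  minutes (`detect_nonwear()`); daily summaries; valid day = ≥ 480 wear
  minutes; valid subject-wave = ≥ 4 valid days incl. ≥ 1 weekend day.
* **Guidelines**: age-specific 24-h movement guideline physical-activity
  scoring — TPA ≥ 180 min/day (toddlers), TPA ≥ 180 incl. energetic play
  ≥ 60 (3–5 y), energetic play ≥ 60 (school-aged), inclusive thresholds
  (`assign_rule()`, `meets_guideline()`, `energetic_play_deficit()`).
* **Models**: restricted-cubic-spline (4 knots, Harrell's
  truncated-power basis) linear and logistic mixed models with age × sex
  interaction, covariate adjustment and child random intercepts
  (`fit_trajectory_lmm()`, `fit_trajectory_glmm()` on `lme4`), marginal
  means over an age 2–7 grid with delta-method 95% CIs
  (`marginal_means()`), Wald joint tests, effect-size and power utilities.
* **Synthetic data**: class-conditional raw signals, annotated training
  corpora, multi-day recordings with embedded non-wear, and two-wave
  day-level cohorts with known spline-shaped trajectories
  (`simulate_annotated_corpus()`, `simulate_recording()`,
  `simulate_cohort()`).
* **Pipeline**: `run_pipeline()` ties the stages together from a YAML
  configuration holding every analysis constant in one place, writes
  CSV/JSON artefacts stamped with a config hash, and reruns
  byte-identically; a thin CLI lives at `inst/cli/actikids.R`.

## Worked example

Train and validate the classifier on a small synthetic corpus, then model
total physical activity trajectories in a simulated 300-child cohort:

```r
library(actikids)

corpus <- simulate_annotated_corpus(n_subjects = 8, session_s = 300, seed = 42)
cv <- loso_cv(corpus, n_trees = 200, seed = 42)
glance(cv)
#>       n accuracy macro_f
#> 1   160    0.988   0.969

cohort <- simulate_cohort(cohort_sim_params(n_children = 300, seed = 42))
fit <- fit_trajectory_lmm(cohort$days, "total_pa",
  covariates = c("maternal_work", "dwelling", "yard", "season", "covid"))
glance(fit)
#>    nobs n_children random_intercept_sd sigma  logLik converged
#> 1  2301        300                21.8  30.2 -11299.      TRUE

marginal_means(fit, ages = c(2, 3, 5, 7))
#>   outcome  sex      age estimate  lo95  hi95
#> 1 total_pa female     2     334.  322.  345.
#> 2 total_pa male       2     354.  344.  363.
#> 3 total_pa female     3     359.  352.  365.
#> 4 total_pa male       3     374.  367.  380.
#> 5 total_pa female     5     380.  370.  390.
#> 6 total_pa male       5     392.  382.  402.
#> 7 total_pa female     7     353.  336.  371.
#> 8 total_pa male       7     366.  348.  384.

wald_joint_test(fit) # age-by-sex interaction block
#>   statistic    df p.value
#> 1      1.56     3   0.669
```

The LOSO table shows subject-independent recognition of the five classes
on synthetic signals (macro F 0.97 here; real-data accuracy will be
lower). The cohort fit recovers the generator's variance components
(truth: intercept SD 20, residual SD 30 min/day) and its marginal means
trace the generating curve — total PA rising from ~334 min/day at age two
to a peak near age five, then declining — with boys ~10 min/day above
girls (the generated offset) and no age-by-sex interaction, as the Wald
test reports. `autoplot(marginal_means(fit))` draws the trajectories with
confidence ribbons.

The full demonstration pipeline, from signal simulation to marginal-means
CSVs:

```r
cfg <- read_config(system.file("extdata", "demo-config.yaml", package = "actikids"))
run_pipeline(cfg, "demo_out")
```

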