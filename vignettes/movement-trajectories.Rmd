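---
title: "Modelling device-measured movement behaviours in young children"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling device-measured movement behaviours in young children}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actikids)
```

## The pipeline in one paragraph

`actikids` implements a complete analysis chain for hip-worn tri-axial
accelerometry in early childhood: raw 30 Hz signal is collapsed to its
vector magnitude and cut into 15-second non-overlapping windows; 25 time-
and frequency-domain features per window feed a 500-tree random forest that
labels each window as one of five activity classes — sedentary (SED),
light-intensity activities and games (L_ACT_G), moderate-vigorous
activities and games (MV_ACT_G), walking (WALK) or running (RUN); non-wear
time is removed, daily behaviour minutes are accumulated under valid-day
rules, children are scored against the age-specific 24-hour movement
guideline physical-activity components; and developmental trajectories of
daily minutes (and of guideline adherence) from ages two to seven are
estimated with restricted-cubic-spline mixed models and summarised as
marginal means by age and sex. Because no real recordings ship with the
package, a first-class synthetic-data module generates every input with
known ground truth, and the test suite is built around that ground truth.

## Windowing and features

Each 15-s window (450 samples at 30 Hz) is reduced to its vector magnitude
$\mathrm{VM}_t = \sqrt{x_t^2 + y_t^2 + z_t^2}$ (in g) and summarised by a
fixed 25-feature contract (`feature_names()`): mean, SD, coefficient of
variation, min, max, the 10th/25th/50th/75th/90th percentiles, IQR,
skewness, kurtosis, lag-1 autocorrelation, zero crossings of the
mean-centred signal, peaks above mean + 1 SD, total power, dominant
frequency and its power and power fraction, second dominant frequency,
normalised spectral entropy, band powers over 0.25–2.5 Hz and 2.5–5 Hz,
and their ratio (with an $\varepsilon$ guard). Choices that the data alone
could not fix, and how we fixed them:

* The spectrum is the periodogram of the *mean-centred, untapered* window.
  Mean-centring within the window removes the gravity line at 0 Hz;
  frequencies below 0.1 Hz are additionally excluded from the
  dominant-frequency search to suppress residual leakage.
* Zero-variance windows (exactly what an off-body device produces) are
  given finite features by convention: skewness, kurtosis, lag-1
  autocorrelation and spectral entropy are defined as 0 there.
* Windows are aligned to the recording start, not to clock minutes — the
  simplest reproducible convention, shared by the simulator's bout log.
* Whether features should be computed on raw or gravity-removed vector
  magnitude is genuinely open; within-window mean-centring (for the
  spectral features only) is this package's convention.

## The classifier

`train_activity_model()` fits a 500-tree random forest (`ranger`) with
`mtry = floor(sqrt(25)) = 5`, unlimited depth and no class weighting —
common defaults, recorded in the model object. Vote ties resolve in the
fixed class order SED < L_ACT_G < MV_ACT_G < WALK < RUN, so prediction is
fully deterministic given the training seed. Validation is
leave-one-*subject*-out (`loso_cv()`): windows of one child are predicted
by a forest trained on all other children, and predictions are pooled into
a single confusion matrix. Subject-level rather than window-level
cross-validation is deliberate — window-level leave-one-out leaks
within-child correlation and flatters accuracy. Per-class *recognition
accuracy* is per-class recall of that pooled matrix; the macro F-score
averages the per-class harmonic means of precision and recall. On the
default synthetic corpus the suite requires macro F $\ge 0.80$ — a
regression bar for the package's own generator-classifier pair, not a
claim about any real corpus.

## Non-wear, valid days, guidelines

Non-wear is any maximal run of consecutive windows with vector-magnitude
SD below 13 mg (0.013 g) spanning at least 30 minutes; the bound is
inclusive (120 windows qualify, 119 do not). The SD is evaluated on the
same 15-s windows used for classification — one windowing pass, trivially
checkable against a brute-force scanner. Runs detected across midnight are
split at midnight, contributing to both days. Days are calendar days; a
day is valid at $\ge 480$ wear minutes, and a subject-wave enters analysis
with $\ge 4$ valid days including $\ge 1$ valid weekend day.

Intensities follow the class mapping: SED is sedentary, L_ACT_G is LPA,
and energetic play (MVPA) is the sum of MV_ACT_G, WALK and RUN. Total
physical activity (TPA) is LPA + energetic play. Guideline rules are
age-specific with inclusive thresholds: toddlers (under three) need TPA
$\ge 180$ min/day; three-to-five-year-olds need TPA $\ge 180$ *including*
energetic play $\ge 60$; school-enrolled children need energetic play
$\ge 60$. Five-year-olds are scored by school enrolment, not age, because
the second measurement wave follows school entry. Adherence is judged on
the mean across valid days (the child-level binary the logistic model
uses); an every-day variant exists behind `method = "every_day"` but is
off by default, since the mean-based binary is what a per-wave adherence
model needs.

## Trajectory models

For a day-level outcome $y_{ij}$ (child $i$, day $j$; minutes/day):

$$y_{ij} = \beta_0 + f(a_i) + \gamma\,\mathrm{male}_i +
  g(a_i)\,\mathrm{male}_i + \mathbf{x}_i^\top\boldsymbol\delta +
  b_i + \varepsilon_{ij},
  \qquad b_i \sim N(0, \sigma_b^2),\ \varepsilon_{ij} \sim N(0, \sigma^2),$$

where $f$ and $g$ are restricted cubic splines of age with four knots
(one linear plus two nonlinear terms each, Harrell's truncated-power
parameterisation, `rcs_basis()`), fitted by REML with `lme4`. Knots
default to the 5th/35th/65th/95th percentiles of observed age
(type-7 quantiles, so placement is reproducible), overridable via
`rcs_spec()`. Guideline adherence uses the same fixed-effect structure
with a logit link and the Laplace approximation (`glmer`, bobyqa
optimiser); a degenerate outcome (everyone meets, as happens for the
toddler TPA rule) is flagged rather than "estimated".

Marginal means (`marginal_means()`) are linear-predictor evaluations over
an age-by-sex grid with delta-method normal 95% intervals, back-transformed
to proportions for logistic fits. Two covariate policies are exposed
because the representative-value choice is genuinely open: `"reference"`
(continuous covariates at their sample mean, categorical at the reference
level — the default) and `"population"` (design rows averaged over the
observed covariate distribution). Confidence intervals use the normal
approximation throughout: intended cohorts have hundreds of children; for
very small simulations the intervals will be slightly narrow, a documented
limitation. Joint hypotheses (typically the age-by-sex interaction block)
use the Wald chi-square `wald_joint_test()`. A small design utility,
`cohens_d()`, expresses a minutes-per-day difference as a standardised
effect (for example, 5 min against an SD of 42 min/day is $d = 0.12$), and
`power_normal_approx()` gives two-group normal-approximation power; the
original study design's exact pairing structure is not reproduced, so
power calculations here are exploratory only.

## What the synthetic data emulate — and what they do not

The raw-signal generator is intentionally minimal: per class, a gravity
baseline on the vertical axis plus per-axis Gaussian noise, a sinusoidal
locomotion component (0.7 Hz light play, 1.3 Hz moderate-vigorous play,
2 Hz walking, 3 Hz running) and, for MV_ACT_G, Bernoulli 1-second bursts
that multiply the amplitude — enough structure to make the five classes
learnable, separable in window SD (SED < L_ACT_G < WALK < MV_ACT_G ≤ RUN)
and confusable in controlled ways. Non-wear is emitted as exactly
zero-variance signal so detector tests have unambiguous truth. Between-
child variation enters as log-normal amplitude and noise factors
(SD 0.08). None of this is biomechanics: there is no wrist placement, no
posture, no sleep, and the class mix of a session (default 35% SED,
30% L_ACT_G, 15% WALK, 10% MV_ACT_G, 10% RUN) is a package choice, since
the composition of real free-play sessions is not pinned down. Passing
classifier tests therefore demonstrate the pipeline's correctness and
determinism on signals with known structure — not field accuracy on real
children.

The cohort generator produces day-level summaries directly: each child's
day value is a smooth true curve of age, plus a sex offset, a child random
intercept and day-level noise. The default curves peak (total PA) or
bottom out (sedentary) near age five, with energetic play rising
monotonically — the developmental shapes the spline model must capture —
and are built as restricted-cubic-spline interpolants on the canonical
knots for ages 2–7 (2.25, 3.75, 5.25, 6.75) through anchor values at
realistic magnitudes (total PA ~340–385, sedentary ~345–385, energetic
play ~32–62 min/day). Building the truth in the model's own function
space is what makes the coverage tests meaningful: with matching knots the
model is correctly specified, so its 95% intervals must cover at ~95%,
and the suite checks that they do. Noise defaults are per-outcome
(intercept SD 20, residual SD 30 min/day for total PA and sedentary; 8 and
12 for energetic play, keeping simulated energetic-play minutes
realistically positive); a scalar is accepted and recycled. Wear time is
sedentary + total PA by construction, so behaviour minutes and wear are
conserved exactly — which also means wear time must *not* be used as an
adjustment covariate in recovery experiments on these data (it would
absorb outcome variance); the pipeline's demonstration model keeps it, as
an applied analysis would, while the recovery tests drop it. Wave-2
retention defaults to 40%, and the wave gap to 2.4 years, mirroring a
two-wave preschool-to-school cohort.

## Numerical choices and degenerate inputs

* Trailing partial windows are dropped; `sample_rate * window_s` must be
  integral.
* Quantiles are type 7 everywhere (knots, percentile features), so
  repeated runs agree exactly.
* All simulation is seeded through `withr::with_seed`; identical
  parameters and seed give bit-identical outputs, and the end-to-end
  pipeline writes byte-identical artefacts on reruns (the suite checks
  this on the bundled demo configuration).
* The Wald test refuses singular covariance sub-blocks
  (`rcond < 1e-12`) rather than pseudo-inverting.
* `summarize_day()` rejects windows spanning midnight; `summarize_days()`
  is the splitting wrapper.
* Aggregate adherence reports print percentages; exact values are retained
  in the returned tibbles.

## Problem sizes used by the checks

The suite validates statistical behaviour at sizes chosen to balance
Monte-Carlo resolution against a laptop-scale run: the classifier corpus
at its default scale (31 children × 1200 s ≈ 2,480 windows, full LOSO);
CI coverage over 200 replicate cohorts of 100 children; Wald test size
over 500 replicate cohorts of 200 children (the acceptance script reports
the same rate over 300 replicates); recovery of variance components from
one 500-child cohort; and non-wear oracle equivalence over 1,000 random
sequences of 5,000 windows. Coverage and test-size bands
([0.90, 0.98] and [0.03, 0.07]) are wide enough to absorb binomial noise
at those replicate counts.

## Known limitations

* Synthetic signals are stylised; classifier accuracies on them say
  nothing quantitative about real recordings.
* Sleep is out of scope — the simulated wear protocols simply place wear
  in waking hours.
* Screen-time and sleep components of the 24-hour guidelines cannot be
  scored from accelerometry and are not modelled.
* No random slopes and no compositional treatment of the 24-hour day;
  random intercepts only.
* Normal-approximation intervals and p-values; no small-sample df
  corrections.
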