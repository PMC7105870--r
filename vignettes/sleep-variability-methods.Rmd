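---
title: "Actigraphy sleep variability and behavior: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Actigraphy sleep variability and behavior: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models implemented in `sleepiiv`, the
assumptions behind them, the parameters that matter, and the design
decisions taken where the underlying methodology left choices open.

## The scoring model

Wrist actigraphs in zero-crossing mode report one activity count per
minute. The scorer is a fixed linear filter over a seven-minute window —
four minutes of history, the current minute (weighted most heavily, 2.30),
and two minutes of lookahead — scaled by 0.0033; a minute is scored sleep
when the score falls below 1. The filter's smoothing has two visible
consequences worth knowing about when interpreting output:

* transitions blur by roughly 3–4 minutes, so detected sleep onset lags
  true onset slightly;
* awakenings shorter than about two minutes at moderate activity levels
  are usually absorbed into sleep, so scored awakening counts undercount
  brief arousals. This is a property of the scoring family, not a defect
  of the implementation.

Minutes without a full window (the first four and last two of a series)
and off-wrist minutes are labeled `undefined`.

### Rescoring

The classical companion to this scorer is a rescoring pass that removes
spurious sleep calls adjacent to long wake bouts. The exact modification
set used by the original device software is not published, so the package
implements the standard Webster rule table, configurable and on by
default:

| trigger | action |
|---|---|
| ≥ 4 min wake | rescore next 1 sleep min |
| ≥ 10 min wake | rescore next 3 sleep min |
| ≥ 15 min wake | rescore next 4 sleep min |
| sleep bout ≤ 6 min flanked by ≥ 10 min wake both sides | rescore bout |
| sleep bout ≤ 10 min flanked by ≥ 20 min wake both sides | rescore bout |

All rules are evaluated against the input labels and applied
simultaneously in a single pass. A subtlety: a literal second application
would see longer wake runs (the rescored minutes) and eat further into
sleep, cascading without bound. Rescoring is therefore defined relative to
raw scorer output: the result carries a `rescored` attribute and
re-application is a documented no-op. This keeps the operation idempotent
without changing the standard single-pass semantics.

### Period detection and night measures

The study workflow this package models used automatic detection plus
expert manual adjustment; a software pipeline needs a stated heuristic
plus an override hook. The heuristic: the period spans the first to the
last run of at least `min_run` (default 20) consecutive sleep-labeled worn
minutes. Detection returns an *invalid value* (never an exception) when no
such run exists, when more than `max_offwrist_frac` (default 0.2) of the
period is off-wrist, or when mean ambient light in the period exceeds
`light_threshold` (default disabled). `detect_sleep_period(override =
list(start, end))` is the manual-adjustment hook. Invalid nights are
excluded from all aggregation, with reasons recorded.

Conventions fixed here: times are minutes relative to the midnight ending
the calendar date the night is assigned to (an episode starting at 22:30
has start −90); `sleep_end` marks the end of the last sleep minute so that
`duration = sleep_end − sleep_start`; undefined minutes inside a detected
period count as wake in both the awakening count and the efficiency
denominator (the conservative reading; the alternative — excluding them —
is not what the efficiency definition "percentage of minutes labeled
sleep within the interval" suggests). Epoch length is fixed at one minute;
other resolutions are rejected rather than resampled.

Age-group adjustment subtracts the recommended duration (600/540/480 min)
or start (−210/−150/−90 min) for ages 6–13 / 14–17 / 18+ from the observed
value.

## Windows and variability

Variability is computed per participant-visit over the *half-open* week
`[visit − 7 d, visit)` — "the week preceding" excludes the visit date.
Windows with fewer than 2 valid nights are excluded (flagged, not
silently dropped). Statistics are the mean, the sample (n−1) SD — the
denominator matters at 2–7 nights per window — and CV = sd/|mean| with an
undefined flag when |mean| < 1e−9: sleep start is signed, so a raw
sd/mean could flip sign or explode.

Two open choices were resolved as follows. Duration is age-adjusted
per-night *before* summarizing: within an age group the adjustment is a
constant offset, so window means shift while SD and CV of duration remain
those of the raw nights. Sleep start is left unadjusted by default
(`adjust_start = TRUE` switches), because reported cohort summaries of
start look raw while duration tables are presented alongside the
adjustment recipe.

## Association models

Each behavior scale is regressed on one actigraphy statistic at a time
with age, sex, and IQ as fixed covariates and a random intercept per
participant (repeated visits). All variables, sex included after 0/1
coding, are centered and scaled on the analysis sample, so the reported
effect is a standardized coefficient. Inference uses Satterthwaite
degrees of freedom (lmerTest); when the random intercept is inestimable —
e.g., one visit per participant throughout — the model falls back to OLS
and the result is flagged `degenerate`. BH false-discovery control is
applied with one family per scale-by-statistic grid; the family structure
is explicit in the API because it is a modeling choice, not a default.

The covariate-adjusted Spearman correlation ranks x, y, and the
covariates, residualizes the x/y ranks on the covariate ranks, and
correlates the residuals, with a t-based p-value on n − 2 − k degrees of
freedom. With no covariates this is exactly classical Spearman rho (the
p-value construction differs from the exact permutation form at small n).

## The prediction protocol

The 17-feature table stacks participant-visit rows: 12 actigraphy
statistics (mean/SD/CV × four measures), the ordinal caregiver sleep item,
and age, sex (0/1), IQ, and ADOS severity; the anxiety total is the
response. Preprocessing: (1) near-zero-variance flagging — unique fraction
< 10% *and* top-to-second frequency ratio strictly > 19; (2) iterative
decorrelation — repeatedly drop, from the most correlated pair at or above
0.7, the member with the larger mean absolute correlation (earlier column
on ties), until an exhaustive pair scan is clean; (3) a VIF audit
(`1/(1 − R²)` of each feature on the rest), asserting all survivors < 10.

The elastic-net solver is cyclic coordinate descent in covariance form
with warm starts and active-set sweeps, on columns standardized to 1/N
variance with a centered response; coefficients return on the original
scale. λ paths are 100 log-spaced values from the analytic λ_max (the
smallest λ with an all-zero solution) down four decades. The solver is
validated in the test suite against an independent reference
implementation (glmnet) at α = 1, against OLS at λ = 0, and against its
own objective (the fitted point never scores worse than the zero vector
or the OLS solution).

Protocol choices where the recipe left room:

* **Split unit.** Outer 70/30 splits are at the *participant* level —
  all visits of a participant fall on one side — preventing leakage from
  repeated visits; a row-level option exists for sensitivity checks.
* **Inner selection.** Per α, K-fold CV repeated `n_inner_reps` times
  (fold assignments shared across α within a repetition); the per-repetition
  minimum CV-MSE is averaged and the α with the smallest average wins,
  ties broken toward smaller α (more ridge-like, more stable). λ at the
  winning α follows the min-MSE rule by default; the min+1SE rule is
  available.
* **Refit.** One refit at (α*, λ*) on the full training part, rather than
  averaging across inner repetitions.
* **Test goodness of fit.** Test R² is 1 − SSE/SST about the test-set
  mean; the F-test regresses held-out responses on the refit model's
  predictions against an intercept-only model. Splits leaving a
  categorical covariate single-classed on either side are redrawn with
  the next sub-seed.
* **Importance.** `raw_j = Σ_s c_sj (r_s f_s) / S` with S the configured
  number of test sets (100 in the full protocol), then normalization by
  the maximum to [0, 1]. `w_s` is floored at zero: out-of-sample R² can
  in principle be negative alongside a significant F, and importances are
  defined as non-negative.

Full-scale settings are 100 inner repetitions × 100 outer splits; the
test suite and the acceptance script run 10 × 20, which this package
treats as its documented desk-scale configuration (selection behavior is
already stable there; the full setting only tightens the importance
averages).

## The synthetic cohort

The generator provides ground truth for every stage. Per participant:
age from a shifted gamma (mean 14.5 y, SD 7.9 y, minimum 6 — strongly
right-skewed, median ≈ 12), IQ ~ N(99, 19.6) clipped to 40–160, ADOS
severity ~ N(7.6, 1.7) clipped to 1–10 (ASD only), 77.7% male. Nightly
structure comes from a per-participant architecture: mean bedtime ~
N(−81, 60) min vs. midnight with 45 min night-to-night SD, duration ~
N(481, 55) between / 45 within, and a Poisson awakening rate centered on
17.5/night (shifted by a latent sleep-quality scalar) with geometric
episode lengths (mean 2.5 min, ≥ 1). Those rates imply a mean efficiency
near 91%. Episodes are placed uniformly inside the sleep interval
*excluding* a 30-min onset and 20-min terminal consolidation, using a
free-space construction that preserves the drawn count without overlap;
consolidated onset and final waking are what make the interval
identifiable, for an expert or an algorithm. Wake minutes draw
negative-binomial counts (mean 150, awakenings 100, size 5); sleep
minutes are zero-inflated (65% zeros, else Poisson mean 3) — zero-crossing
counts are overdispersed non-negative integers and the scorer only needs
separable regimes. Light is lognormal, bright outside the sleep interval
and near zero inside.

Wear compliance draws nights-worn from a configurable distribution whose
2–7-night mass follows a realized cohort wear pattern (21/12/10/9/2/4 of
139), with the below-threshold remainder split between 0 and 1 nights.

The caregiver sleep item is ordinal 0–7 (the instrument's numeric range
is not fixed by published summaries, which disagree between a ≈4.8 and a
≈2.7 mean scoring; the generator targets mean ≈ 2.6, SD ≈ 2.1, consistent
with the ≥ 3 "more than mild" threshold flagging roughly two thirds of an
ASD cohort). The anxiety total is `intercept + 2.5·abi + 2.0·SD(eff) +
15·CV(awak) + N(0, 5)` clipped to 0–63, computed from the *realized*
window statistics of the generated nights — the coupling operates on what
the pipeline can observe, so recovery is a fair test. Other scales are
noisy linear functions of the latent quality scalar.

What the generator does *not* emulate: circadian drift, weekday/weekend
structure, biomechanically realistic accelerometry, daytime wear, device
artifacts beyond a uniform off-wrist flag, and informative missingness
(compliance is independent of sleep quality). Passing tests therefore
demonstrate correctness of the pipeline's logic and recoverability under
a plausible noise model — not validity of the scoring filter on real
recordings, which rests on the device-validation literature.

## Numerical notes

* Coordinate descent converges on max absolute coefficient change:
  1e−10 for single fits (oracle-grade), 1e−7 inside cross-validation.
* Standardization uses 1/N variance throughout the solver (matching the
  reference implementation's convention); constant columns get unit scale
  and a zero coefficient.
* The score threshold is strict (`S < 1` is sleep), the near-zero-variance
  frequency ratio is strict (`> 19`), and the decorrelation trigger is
  inclusive (`≥ 0.7` is removed): each follows the stated rule's wording.
* CV fold assignment uses `sample(rep_len(1:K, n))`, so fold sizes differ
  by at most one.
* All randomness flows from integer seeds through one seeded-evaluation
  helper; every generator and the whole protocol are pure functions of
  (arguments, seed).

## Known limitations

Sleep-onset latency is not computable from this scoring (no lights-out
marker). Detected onset carries the systematic few-minute lag discussed
above, which cancels in variability statistics but biases mean start
slightly late. The mixed-model p-values rely on Satterthwaite
approximation at modest cohort sizes; the partial-Spearman p-value is
asymptotic. The protocol's importance score inherits elastic net's
behavior under strong collinearity: of two near-duplicate drivers, the
preprocessing keeps one and the importance accrues to the survivor.
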