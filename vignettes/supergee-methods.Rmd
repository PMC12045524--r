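---
title: "Simulating and analyzing the Super G motor-skill task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing the Super G motor-skill task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and its model

Super G is a web-based rate-control motor task used as a candidate digital
biomarker for Alzheimer-disease risk. The player steers an astronaut from a
start planet to a target planet with the left/right arrow keys. The
environment has no gravity or drag: holding the right arrow applies a
constant positive acceleration, holding the left arrow an equal negative
one, and releasing both leaves the velocity unchanged. Each 4.5 s trial has
a 1.5 s hold phase (leaving early resets the trial), a 3 s movement window,
and a success rule of one continuous second inside the target planet's
boundary. A session is 75 trials; cursor position and key state are sampled
at 100 Hz.

`supergee` implements this task as a headless, deterministic simulator plus
the downstream analysis used to relate task performance to risk factors:

* **engine** — `run_trial()` / `run_session()` integrate the 1-D dynamics
  with semi-implicit Euler on the 100 Hz grid (velocity first, then
  position with the updated velocity). Key-press onsets are quantized to
  the grid; the boundary test is point-in-disk with ties counting as
  inside. A compiled (Rcpp) fast path with identical semantics — including
  an identical RNG draw order — backs cohort-scale simulation, and the test
  suite asserts exact metric equality between the two routes.
* **metrics** — `trial_metrics()` extracts the four skill variables:
  scaling ratio (SR, total left-press over total right-press time in the
  movement window), time of reversal (TR, first braking onset after the go
  cue), time in target (TinT, cumulative sampled time inside the target),
  and response time (RT, first sample outside the start planet after the
  go cue). `summarize_session()` averages them over the defined trials.
* **cohort + controller** — a generative population whose gameplay and
  covariates carry the associations the regressions must recover.
* **stats** — the study's inferential battery: Wilcoxon rank-sum,
  chi-square, Cohen's d, VIF and Cook's-distance filtering, and five
  multivariable regression models.

## Conventions the data dictate

Several measurement conventions are underdetermined by the task description
alone; the package fixes them as follows.

* **RT on the absolute trial clock.** Published session means for RT
  (1.6-1.9 s) exceed the 1.5 s hold, which is only consistent with RT
  measured from trial start. Both clocks are reported (`rt_ms`,
  `rt_go_ms`), and they differ by exactly the hold duration.
* **TR as the first braking onset after the go cue**, absolute clock;
  additional left presses count toward SR but not TR.
* **TinT is cumulative**, not longest-continuous, and accrues on failed
  trials; a successful trial therefore always has TinT of at least the
  1000 ms landing requirement.
* **Early-exit resets restart the within-trial clock** and do not consume
  one of the 75 attempts; only the final (post-reset) timeline is scored.
  A controller that exits early on every attempt would never terminate, so
  trials are abandoned as failed after `max_resets` (default 20) resets.
* **Undefined metrics stay undefined.** A trial with no movement has no
  RT/SR/TR; session means are taken over defined trials only, avoiding
  imputation.
* **Success ends the trial** at the landed event; no further samples are
  emitted.

The task geometry (thrust 2 screen-units/s², planet distance 1, radius
0.08) is not published. The defaults are feasibility-driven: the ideal
bang-bang strategy — exit at the go cue, thrust for
`sqrt(distance / accel)` ≈ 0.707 s, brake for the same — arrives at rest
inside the target with about 0.9 s of margin, and the suite asserts it
lands all 75 trials. All three constants are configurable in
`task_config()`.

## The generative model

Synthetic participants play an open-loop bang-coast-bang plan: exit near
`t_go_mean`, thrust for about `tau_right`, coast, then brake for
`rho * tau_right` starting near the planned reversal. Every attempt jitters
the exit, both durations and the reversal onset with i.i.d. Gaussian noise
of SD `timing_sd`, and with probability `lapse_prob` the attempt makes no
presses. This is the simplest policy that spans all four metrics
independently: `t_go_mean` moves RT, the reversal plan moves TR, `rho`
moves SR, and `timing_sd` — landing accuracy — moves TinT. No within-session
learning curve is modelled, because the analysis consumes session means
only.

`covariate_link()` maps covariates to these parameters. The default link
encodes the association structure under study:

* age (+0.010 s per SD) inflates timing jitter → lower TinT with age;
* male sex (−0.018 s) and a latent skill trait (−0.010 s per SD) reduce
  it → higher TinT in males, and a skill-TinT correlation;
* APOE e4 carriers plan their exit 0.10 s earlier → faster RT;
* the latent skill trait also raises PAL (paired-associates learning), but
  in males only (`pal_male_skill` in `cohort_config()`), producing the
  sex-dependent PAL-TinT coupling probed by the model-4 interaction.

Two design points deserve comment. First, the reversal is parameterized as
a *coast gap* relative to each participant's own exit plan
(`t_rev_mean = t_go_mean + tau_right + gap`). With an absolute,
independently drawn reversal time, between-participant variation in exit
time would change the coast length and hence the landing position, so exit
heterogeneity (an RT trait) would mechanically dominate TinT; the gap
parameterization keeps the RT and TinT pathways separate. Second, effect
sizes were calibrated once so that the standardized effects on the
session-mean metrics land in the 0.5-1 SD range (male-female TinT gap
≈ 1 SD, age slope ≈ −0.5 SD, carrier RT shift ≈ −0.9 SD), making sign
recovery reliable at a few hundred participants while leaving substantial
overlap between groups. Linked parameters are clamped to their valid
ranges; clamping is recorded in an attribute and affects well under 1% of
participants under the defaults (asserted in the suite).

The cohort generator reproduces the marginal structure of the study
sample: age truncated-normal (mean 62.4, SD 7.4, minimum 45), 39/54
female, genotype counts 2/3: 2, 3/3: 29, 2/4: 4, 3/4: 16, 4/4: 3, a highly
educated four-level education distribution, log-normal median svRT
(median ≈ 400 ms — svRT is right-skewed, which is why the study uses the
median of six trials), afternoon-centered hour of play on the 24-hour
clock, PAL on 0-36 with age and sex effects, and a 5.9 ± 1.4 year
PAL-to-gameplay delay. An `"exact"` sampling mode fixes the categorical
margins by largest-remainder apportionment, reproducing the study's
integer table at n = 54 (23 carriers / 31 noncarriers, 39 female / 15
male); the default `"iid"` mode draws them independently.

## Preprocessing and models

`standardize_analysis()` applies the study's variable constructions: male
and carrier coded `TRUE`, hour of day replaced by `cos(2*pi*h/24)` (so 23:00
and 01:00 are close) and then standardized like every other numeric
variable (n−1 SD convention, transforms stored for exact inversion), the
delay-adjusted PAL score `pal_raw - 0.2 * years_since_pal` (projecting the
historical score forward at the expected decline rate; the direction is
recorded in an attribute), and education ordered with "high school
diploma" as reference. `percentile_vs_reference()` contextualizes a score
against a reference cohort within age-decade × sex × education strata
(midrank ties; sex × education fallback for empty strata) — a stratified
stand-in for cohort-wide norm tables that are not public.

The five models are fit by `fit_model()` / `fit_study_models()`:

1. carrier ~ performance + age + sex + hour + education + svRT + PAL (logistic)
2. male ~ performance + age + hour + education + svRT + PAL + carrier (logistic)
3. age ~ performance + sex + hour + education + svRT + PAL + carrier (linear)
4. PAL ~ performance + age + sex + hour + education + svRT + carrier + sex:performance (linear)
5. as model 4 with delay-adjusted PAL as the outcome

Numeric predictors enter standardized (coefficients are per 1 SD); linear
outcomes stay on their natural scales (years, PAL points), which is the
only reading consistent with how the study states its betas (e.g. "males
scored an average of 7 points lower"). The filtering recipe is: iterative
VIF removal at threshold 5, fit, remove observations with Cook's distance
above 1, refit once. VIF uses the generalized (Fox-Monette) VIF per model
term with the `GVIF^(1/(2df)) > sqrt(5)` rule — identical to the plain
`VIF > 5` rule for single-column terms, and coding-invariant for factors
(per-dummy VIF would spuriously flag education, whose reference level is
rare). The collinearity screen runs on main effects; the model-4/5
interaction is added afterwards if both parents survived, since an
interaction column is near-collinear with its parents by construction.
Cook's distance for logistic models is the standard one-step
approximation, applied to logistic and linear models alike. Logistic CIs
are profile-likelihood by default (the asymmetric intervals appropriate at
n ≈ 54; Wald by flag, and `ci_method = "none"` for simulation loops),
linear CIs are t-based.

## What the tests do and do not show

Because the study's raw data are not public, the fitted coefficients of
the real models are not reproducible; the package instead validates the
*pipeline* against its own generative model:

* **sign recovery** — with the default link, models 1-4 recover the sign of
  every nonzero generative effect (carrier→RT −, male→TinT +, age→TinT −,
  age→PAL −, male→PAL −, male:TinT→PAL +) jointly in well over 80% of 100
  replicate cohorts of n = 500;
* **type-I calibration** — with a zero-effect link and a null cohort, the
  per-term rejection rate of model 3 at α = 0.05 stays inside
  [0.03, 0.07] over 500 replicates of n = 200;
* **oracle equivalence** — the metric extractor agrees exactly with a
  naive full-scan reference on 500 random logs, and the compiled fast path
  agrees exactly with the pure-R engine;
* **printed anchors** — the carrier rule reproduces 23 carriers / 20
  heterozygotes from the genotype table, the Yates chi-square of the sex
  table is exactly 0, and so on.

Replicate counts and cohort sizes (100 × 500 for recovery, 500 × 200 for
calibration) were chosen so each property is decided with comfortable
binomial margin while the whole suite runs in minutes on one core.

Passing these tests shows the machinery is correct and well calibrated; it
does not show that real participants behave like bang-coast-bang
controllers, that real TinT-covariate couplings have these magnitudes, or
anything about the non-response and selection structure of a volunteer
web cohort (the synthetic cohort has no non-response mechanism and is
all non-Hispanic White by construction, matching the study sample's
homogeneity rather than the population's diversity).

## Numerical details

* Integration is semi-implicit Euler at the sample grid; under constant
  thrust it reproduces `v = a t` exactly, and position converges at first
  order (the suite checks a thrust-then-coast trajectory against the
  closed form at a finer step).
* TinT is computed as (in-target sample count) / sample rate — the same
  arithmetic in the R and C++ routes, so cross-route comparisons are
  exact.
* The movement window is half-open, `[hold, hold + window)`, which bounds
  TinT by exactly 3000 ms.
* Landing requires `landing_duration * sample_rate` consecutive in-target
  samples (100 at defaults).
* Ties: a cursor exactly on a planet boundary counts as inside; a reversal
  exactly at the go cue counts as after it.
* Degenerate inputs fail loudly: zero-variance columns name themselves in
  the standardization error, zero-margin contingency tables and malformed
  genotypes are errors, all-tied rank-sum data returns p = 1 with a
  warning, and non-convergent or separated logistic fits fall back from
  profile to Wald intervals with the method recorded in the result.

## Limitations

The controller is open-loop: no within-trial feedback correction, no
learning curve, no fatigue. SR and TR consequently have narrow
between-participant distributions compared with the published ones. The
percentile adjustment is stratified rather than regression-based. The
planet chain cycles after the 16th planet, a convention the 75-trial /
16-planet design never reaches in practice under realistic success rates.
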