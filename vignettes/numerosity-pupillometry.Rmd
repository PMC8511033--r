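---
title: "Modeling pupillary responses to perceived numerosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling pupillary responses to perceived numerosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilnum)
```

`pupilnum` implements a complete analysis chain for passive-viewing
pupillometry of the connectedness numerosity illusion: constraint-matched
dot-array stimuli, a generative model of pupil traces, artifact-aware
preprocessing, a Gamma-kernel general linear model of pupil dynamics,
psychometric estimation of the illusion, and the condition-level
statistics. This vignette explains the science behind each stage, the
parameters that matter, and the choices made where the procedure is
genuinely underdetermined.

## The pupil model

The pupillary light response is treated as a linear time-invariant
system. A stimulus contributes three inputs: an impulse at onset, an
impulse at offset (visual transients), and a boxcar over the presentation
(the sustained luminance drive). Each input is normalized to unit
integral and convolved with the pupil response function, a delayed Gamma
kernel

$$h(t) = \frac{\left(\frac{t-\delta}{\tau}\right)^{n-1}
  e^{-(t-\delta)/\tau}}{\tau\,(n-1)!}, \qquad t \ge \delta,$$

i.e. a Gamma density with integer shape $n$ (a cascade of $n$ identical
low-pass filters), scale $\tau$ and delay $\delta$. The kernel has unit
mass and peaks at $\delta + (n-1)\tau$. Units: $\tau$ and $\delta$ are in
milliseconds — the constraint boxes $n \in [1,8]$, $\tau \in [10,800]$,
$\delta \in [0,200]$ are only plausible on that scale — and are converted
to seconds once, at kernel construction (`gamma_prf()`).

Because the analysis grid is coarse (20 Hz), `build_design()` renormalizes
the *sampled* kernel to unit discrete mass. This makes the regressor
scale, and hence the $\beta$-weights (in mm), invariant to the analysis
rate; for smooth kernels the correction is below a percent, but it keeps
the sharp-kernel limit exact (with $n = 1$, $\tau \to 0$ the sustained
regressor converges to the boxcar itself).

### Fitting

`fit_prf()` is a two-stage estimator, reflecting how per-observer kernels
are used in practice:

1. On the observer's average response across conditions, minimize the
   validity-weighted residual sum of squares over $(n, \tau, \delta)$:
   $n$ is enumerated exactly over 1..8 (the $(n-1)!$ form presumes an
   integer filter count; enumeration is cheap and avoids interpolating
   the factorial), and for each $n$ a bounded quasi-Newton search over
   $(\tau, \delta)$ is run from 5 seeded quasi-random starts, with the
   $\beta$-weights profiled out by least squares at every evaluation.
2. The best kernel is frozen, and per-condition $\beta$-weights are
   estimated by ordinary least squares (`fit_condition_betas()`); all
   three weights are fitted freely per condition.

No intercept is included: traces are baseline-corrected, so the model is
anchored at zero by construction. Variance explained is reported as
$1 - \mathrm{SSE}/\mathrm{SST}$ with the *uncentered* total sum of
squares over valid samples — the appropriate reference for an
intercept-free fit of a zero-baselined trace, and bounded in $[0,1]$ for
any least-squares solution. An all-zero input trace returns zero weights
flagged as degenerate rather than an error, since grand averages of
empty condition cells can legitimately vanish.

The sustained comparison is run on **dark-minus-light difference
traces**: subtracting the response to white arrays from the response to
black arrays cancels the polarity-independent onset/offset transients and
doubles the signed sustained component, isolating the net pupillary
response to luminance. Per-polarity fits remain available through the
same functions. The model-free companion measure is `window_mean()`, the
validity-weighted mean over 1–6 s after onset — the stimulus window minus
its first second, which is dominated by the fast onset transient. The two
measures should and do agree in sign and condition ordering (this is
asserted in the test suite).

## Stimulus construction

Each condition set comprises 2 numerosities (18, 24 dots) × 2
connectedness levels. Connected stimuli join random dot pairs with lines
into dumbbells; isolated controls either displace the lines to random
free positions (family 1: dot diameter 2.2°/1.9° for 18/24 dots, line
width 1.03°, length 2–3°) or remove them and enlarge the dots to absorb
their ink (family 2: line width 0.6°, length 1.6–2.8°). Targets: total
ink 92.7 deg² (family 1) or 82.3 deg² (family 2) and convex hull 513 deg²
for every stimulus, with no two item boundaries closer than 0.5°.

Decisions taken where the construction is underdetermined:

* **Placement field.** The random-coordinate region is a circle of radius
  13.5° around fixation. The radius is chosen so that the matched hull
  can reach 513 deg² with only a modest radial expansion; it is a
  placement region only — matching may move items slightly beyond it.
* **Dots are placed as pairs.** A perfect matching with every pair
  distance inside the printed line-length range essentially never exists
  for independently scattered dots, so `place_items()` samples dumbbell
  geometry directly: pair midpoints, orientations and separations such
  that the boundary gap lies in the connector length range, plus
  free-floating candidate lines. The isolated layouts therefore consist
  of dot *pairs*, and `connect_pairs()` always has a feasible matching.
* **Connector endpoints** sit on the dot boundaries along the
  center-to-center line. The printed line lengths (2–3°) describe the
  visible inter-dot segment, and ink bookkeeping (dot ink + line ink =
  target) is only consistent with that reading; unions are computed on
  the raster in any case, so no junction pixel is double-counted.
* **Hull support points** are the outer ink extents — 64 samples per dot
  boundary and the connector rectangle corners — not the dot centers:
  the hull is read as *covered area*.
* **Matching schedule.** `match_constraints()` alternates an ink step
  (connected: symmetric stretching of each pair separation; displaced
  lines: symmetric stretching of each line; removed lines: uniform dot
  area adjustment — each an analytic step of the right total magnitude)
  with a hull step (global radial scaling of item positions by
  $\sqrt{A_{target}/A}$), until both residuals are below *half* the
  configured tolerance (default tolerance 0.5%) or 500 iterations. The
  halved internal threshold guarantees that any two stimuli matched to
  the same reference differ by at most the full tolerance. Placement
  demands an extra 0.3° clearance margin so these adjustments cannot
  push items below the 0.5° separation floor, which is re-verified on
  exit. Convergence typically takes under ten iterations.
* **Raster resolution.** Ink is measured on a 20 pixels/degree union
  raster and reported in deg² (pixels ÷ ppd²); the family-2 isolated dot
  diameters implied by ink absorption come out near 2.41° (18 dots) and
  2.09° (24 dots), i.e. about 20% more dot area than the connected
  condition.
* **Spectra.** `radial_fourier_amplitude()` takes the modulus of the 2-D
  DFT of the background-subtracted image and averages it in 0.1
  cycles/degree annuli over 0.3–10 cpd. Only the profile shape is
  meaningful; the scale is arbitrary units.

## Preprocessing

The rules are applied in a fixed order — artifact masking, downsampling,
filtering, epoching — and no invalid sample ever contributes to any mean.

* **Masking** (`mark_invalid()`): a sample is invalid if pupil < 0.1 mm;
  if it deviates more than 1 mm from the median of its trial (computed
  over the raw span from 1 s before onset to 1 s after offset, before
  any masking; the whole-trace median is used outside trials); or if it
  falls within a 20 ms window around a velocity exceedance. "Surrounding
  20 ms" is read symmetrically (±10 ms), and the first-difference
  velocity is attributed to both bracketing samples. Masking is
  idempotent and masks only grow.
* **Downsampling**: 500 → 20 Hz by 25-sample bin means over valid
  samples; empty bins become invalid. Excluded samples are dropped, never
  interpolated.
* **Square-window filtering**: the stated operation — convolution with a
  unit-area 500 ms square window — is, taken literally, a moving average
  (a low-pass), and that literal reading is the default, implemented
  validity-aware (normalizing by the valid weight in each window). A
  subtract-the-moving-average variant (a true high-pass) is available via
  `mode = "subtract"` but off by default: a 500 ms high-pass would
  remove precisely the sustained 6 s response the analysis is about. The
  contradiction is surfaced rather than silently resolved.
* **Baseline correction**: each epoch (−1 to +7 s around onset) is
  shifted by its own mean over the 200 ms before onset; epochs with no
  valid baseline sample are dropped with a warning.

## The synthetic-data generator

The generator is the package's study design: it produces data with
exactly the statistical structure the analysis assumes, plus the
nuisances the preprocessing must remove.

* **Trial structure**: 1 s fixation, 6 s stimulus, 1 s post; successive
  onsets 8 s apart, so the interval between stimuli (post + next
  fixation) is 2 s. Sessions hold 60 trials of one numerosity and one
  polarity with connected/isolated intermixed, four sessions per
  observer.
* **Ground-truth kernel**: $n = 4$, $\tau = 250$ ms, $\delta = 100$ ms —
  a plausible triplet inside the fitting bounds (per-observer values
  from real data are not bundled).
* **Condition structure**: the sustained weight is
  $\beta_s = \pm 0.9\,\mathrm{mm} \times g$, negative for white
  (constriction), positive for black (dilation), with gains
  $g = 0.70, 1.00, 0.93, 1.23$ for 18-connected, 18-isolated,
  24-connected, 24-isolated. The gains order the cells by perceived
  numerosity — connected arrays are seen roughly 30% less numerous, so
  18-isolated and 24-connected are nearly equivalent — through a
  compressive mapping that is *additive* in the two factors: the pattern
  a faithful analysis should report is two main effects and no
  interaction. Onset/offset weights (−0.08, −0.05 mm) are shared across
  conditions. With the unit-integral boxcar over 6 s, a gain-$g$ cell
  produces a sustained plateau of $0.9g/6 \approx 0.15g$ mm per
  polarity, or $0.3g$ mm in the dark-minus-light difference — a few
  tenths of a millimeter, the right order for pupillometric condition
  effects.
* **Noise**: AR(1) Gaussian with marginal SD 0.05 mm and coefficient 0.9
  at 500 Hz. Pupil noise is strongly autocorrelated; white noise would
  flatter the estimators. Gaze jitter is AR(1) with SD 0.3°.
* **Blinks**: Poisson events (default 6/min), a 20 ms linear ramp down
  to ~0 mm, a 150 ms plateau, and a 20 ms ramp up — shaped so that each
  blink trips both the small-pupil rule and the 25 mm/s velocity rule.
* **2AFC observer**: responses are Bernoulli with
  $P(\text{"more"}) = \lambda/2 + (1-\lambda)\,
  \Phi((x - \mathrm{PSE})/\sigma)$, lapse $\lambda = 0$ by default.

What the generator does **not** emulate: saccade kinematics and their
pupillary artifacts, slow arousal drifts, session-level fatigue,
non-linear onset/offset asymmetries, or any dependence of the transients
on stimulus content. Passing tests on synthetic data therefore certify
the *estimators* (identifiability, calibration, robustness to the modeled
artifacts), not the physiology: real recordings can violate the linear
model in ways this pipeline is not designed to detect.

## Psychometrics and statistics

`fit_cumulative_gaussian()` maximizes the binomial likelihood rather than
least-squares on proportions, which weights unequal trial counts
correctly; the PSE definition (the fitted median) is unaffected. Starting
values come from a probit regression; the optimizer is bounded
quasi-Newton on $(\mathrm{PSE}, \log\sigma)$ with a derivative-free
polish. Perfectly separated tables (every level unanimously "less" or
"more") identify the step location but not the spread: the PSE is set to
the step midpoint, $\sigma$ is pinned at its lower bound, and a warning
is raised. All-identical responses are a hard error. The bias index
$100(\mathrm{PSE}/N - 1)$ is exact arithmetic, and
`predicted_perceived_numerosity()` inverts it.

`rm_anova_2x2()` tests each within-subject effect against its own
participant-by-effect stratum and reports partial
$\eta^2 = SS_{eff}/(SS_{eff}+SS_{err})$; F and p are recomputed from the
sums of squares so a zero-error (noiseless) design yields an infinite F
with a flag instead of `NaN`. `bcea()` uses
$2\pi k\,\sigma_x\sigma_y\sqrt{1-\rho^2}$ with $k = -\ln(1-P)$ and the
field's usual $P = 0.68$ default (configurable; the coverage convention
is not standardized). No multiple-testing correction is applied, matching
how such condition effects are conventionally reported, and Bayes-factor
analysis is intentionally absent rather than approximated.

## Numerical choices and degenerate inputs

* Seeds: every stochastic function takes an explicit seed;
  `run_pipeline()` derives per-stage sub-seeds from the master seed via a
  multiplicative congruential step, so runs are bit-reproducible and
  stages are decoupled.
* The kernel-fitting objective is smooth in $(\tau, \delta)$ for fixed
  $n$; multi-start guards against the shallow ridge between delay and
  rise time.
* Rank-deficient designs, empty analysis windows, all-invalid traces,
  events outside the trace, overlapping stimulus windows, non-positive
  reference numerosities and degenerate (collinear or zero-variance)
  geometry all raise immediate, named errors.
* Placement and matching are rejection-based with iteration caps
  (default 500); failures name the violated constraint. The set
  generator retries a failed numerosity with derived seeds before giving
  up.

## Problem sizes

The test suite and the acceptance script are sized for a single CPU:
constraint conservation is checked over 20 seeded set generations;
noiseless recovery over 50 parameter-box draws; condition-ordering
recovery over 100 noisy replicates at the SD (0.02 mm) of a
trial-averaged difference trace; psychometric calibration over 200
replicate observers at the experimental design's 15 trials per probe
level (recovery precision is validated against the Fisher-information
standard error, which for that design is ~0.39 dots); and the end-to-end
pipeline at reduced participant/trial counts. Full-scale runs (16
participants × 4 sessions × 60 trials) run in minutes via
`run_pipeline()`.

## Known limitations

* The hull/ink matching reproduces the *constraints* of the published
  stimuli, not their exact pixel layouts; spectra are comparable in
  shape, not absolute level.
* The implied family-2 isolated dot diameter for 18 dots (~2.41°) falls
  just below the printed 2.44–2.64° range — consistent with slightly
  longer connector lines in the original arrays than our mid-range
  draws.
* The literal square-window "high-pass" is a smoothing; see above.
* Two-stage kernel estimation ignores kernel uncertainty in the
  per-condition $\beta$ standard errors; with well-separated trials and
  averaged traces this is the conventional trade-off.
* The simulator's participant variability (log-normal sustained gain,
  Gaussian illusion strength) is a convenience, not an empirical
  distribution.
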