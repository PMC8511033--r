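# pupilnum

Tools for studying whether **perceived numerosity** modulates the
**pupillary light response** — and for building, simulating and analyzing
the kind of passive-viewing pupillometry experiment that asks that
question.

## The scientific problem

The pupil constricts to bright stimuli and dilates to dark ones, but the
*gain* of this reflex is not fixed: attention, illusory brightness and
other high-level factors scale it. If numerosity is a spontaneously
encoded visual feature, arrays that merely *look* more numerous should
drive stronger pupillary responses even when luminance is physically
identical. The classic way to dissociate perceived from physical number is
the **connectedness illusion**: joining pairs of dots with thin lines into
dumbbells makes an array appear 20–30% less numerous without changing the
dot count.

Testing this pupillometrically requires four tightly matched stimulus
classes — 2 numerosities (18, 24) × 2 connectedness levels — in which the
total "ink" (number of non-background pixels, hence luminance) and the
covered area (convex hull) are identical, so that any difference in pupil
response can only reflect perceived number. `pupilnum` implements the
entire chain:

* **Stimulus generation** (`place_items()`, `connect_pairs()`,
  `isolate_by_displacement()`, `isolate_by_removal()`,
  `match_constraints()`, `generate_stimulus_set()`): dot arrays with a
  0.5° minimum separation, dumbbell pairing, and iterative matching of
  ink area (92.7 deg² or 82.3 deg² depending on the stimulus family) and
  convex hull (513 deg²), plus raster rendering and radially averaged
  Fourier amplitude spectra as image diagnostics.
* **Forward simulation** (`sim_config()`, `simulate_trial()`,
  `simulate_session()`, `inject_artifacts()`, `simulate_2afc()`): 500 Hz
  pupil/gaze recordings generated from the same linear model the analysis
  assumes, with AR(1) noise, blink artifacts and a cumulative-Gaussian
  2AFC observer — so every analysis stage is testable without any
  recorded data.
* **Preprocessing** (`mark_invalid()`, `downsample_trace()`,
  `square_window_filter()`, `epoch_and_baseline()`,
  `preprocess_trace()`): the exact exclusion rules (pupil < 0.1 mm, > 1 mm
  from the trial median, velocity > 25 mm/s with a 20 ms exclusion
  window), 20 Hz downsampling, 500 ms square-window filtering and 200 ms
  pre-stimulus baseline correction.
* **Pupil GLM** (`fit_prf()`, `fit_condition_betas()`,
  `difference_trace()`, `window_mean()`): see below.
* **Psychometrics** (`fit_cumulative_gaussian()`, `bias_index()`,
  `predicted_perceived_numerosity()`): PSE estimation and the numerosity
  bias index.
* **Statistics** (`rm_anova_2x2()`, `paired_t()`, `bcea()`): 2×2
  repeated-measures ANOVA with partial η², paired *t* with Cohen's *d*,
  and the bivariate contour ellipse area for fixation stability.
* **Orchestration** (`pipeline_config()`, `run_pipeline()`): a seeded,
  logged, manifest-checksummed end-to-end synthetic study.

## The model at the core

Pupil dynamics are modeled as the linear combination of three predictors
convolved with a **pupil response function** *h(t)*, a delayed Gamma
kernel:

```
h(t) = ((t − δ)/τ)^(n−1) · exp(−(t − δ)/τ) / (τ (n − 1)!),   t ≥ δ
```

with *n* ∈ {1..8} filter stages, change rate τ ∈ [10, 800] ms and delay
δ ∈ [0, 200] ms. The predictors are impulses at stimulus onset and offset
and a boxcar spanning the 6 s presentation, each normalized to unit
integral; their least-squares weights β_onset, β_offset, β_sustained
measure the transient and sustained pupillary components in mm.
`fit_prf()` estimates (n, τ, δ) per observer from the average response
across conditions (integer enumeration over *n*, bounded multi-start
quasi-Newton optimization over τ and δ), then the kernel is frozen and
per-condition β-weights are fitted — typically on dark-minus-light
difference traces, which isolate the net luminance response.

Perceived numerosity is quantified psychophysically by the point of
subjective equality (PSE) of a cumulative-Gaussian psychometric function
and summarized by the bias index

```
Bias = 100 · (PSE / N − 1)
```

relative to the reference numerosity N (negative = underestimation).

## Worked example

```r
library(pupilnum)

## 1. a constraint-matched stimulus set (experiment-1 family)
set <- generate_stimulus_set(experiment = 1, seed = 42)
print(set)
#> Constraint-matched stimulus set
#>   experiment numerosity      connectedness     ink     hull iterations
#> 1          1         18          connected 92.7025 511.7175          4
#> 2          1         18 isolated-displaced 92.7600 511.7175          0
#> 3          1         24          connected 92.6875 511.8663          4
#> 4          1         24 isolated-displaced 92.6850 513.3854          1
```

All four conditions land within 1% of the 92.7 deg² ink and 513 deg² hull
targets, so luminance and covered area cannot drive condition differences.

```r
## 2. simulate a noiseless trial and recover the generating model
cfg <- sim_config(sampling_rate = 20, noise_sd = 0)
tr  <- simulate_trial(cfg, 24, "isolated", "black", noise = FALSE)
ep  <- epoch_and_baseline(tr, attr(tr, "events"))
fit <- fit_prf(average_epochs(ep), seed = 1)
print(fit)
#> Pupil response function fit
#>   Gamma pupil response function: n = 4, tau = 250.0 ms, delta = 100.0 ms
#>   beta-weights (mm):
#>     onset    offset sustained
#>    -0.080    -0.050     1.107
#>   variance explained: 100.0%
```

The two-stage fit recovers the generating kernel (n = 4, τ = 250 ms,
δ = 100 ms) and β-weights exactly: the sustained weight 1.107 mm is the
base 0.9 mm scaled by the 24-isolated condition gain (1.23), positive
because black arrays drive dilation.

```r
## 3. the connectedness illusion, psychophysically
tab <- simulate_2afc(observer_spec(12.6, 2),
                     c(8, 10, 12, 14, 16, 20, 22, 24), 15, seed = 1)
pf  <- fit_cumulative_gaussian(tab)
print(pf)
#> Cumulative-Gaussian psychometric fit: PSE = 12.85, sigma = 1.86 (logL = -5.69)
bias_index(pf, 18)
#> -28.6
```

An observer who sees connected 18-dot arrays as ~12.6 dots yields a PSE
near 13 and a bias near −30%: connected arrays are underestimated by
about a third, which predicts that 24 connected dots should look like
roughly 17 — about the same as 18 isolated dots.

## Documentation

The methods vignette (`vignettes/numerosity-pupillometry.Rmd`) describes
the generative model, the preprocessing rules and their rationale, the
estimators, the design decisions taken where the procedure is
underdetermined, and the known limitations of synthetic validation.
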