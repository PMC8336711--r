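# drexr

Sequential Bayesian prediction and statistical change detection for
stochastic tone sequences varying along multiple perceptual features.

## What this is for

How does a listener notice that "something changed" in an ongoing sound
when the sound is stochastic to begin with, and the change could arrive
at any time along any of several perceptual dimensions (pitch, spatial
location, timbre)? `drexr` is a workbench for that question, aimed at
auditory/computational neuroscientists. It provides:

* a **stimulus generator** for random-fractal (1/f^β) melodies: 60-tone
  sequences whose features follow fractal contours at low (β = 2.5), mid
  (β = 2) or high (β = 0) entropy, with an optional midpoint switch to
  high entropy in one or both features, mapped to physical units by
  F0 = 350·2^(3x/12) Hz, S = 15·y degrees, T = 1200·2^(3z/12) Hz
  (ranges 208–589 Hz, ±45°, 714–2018 Hz at seed bounds ±3);
* the **D-REX predictor** (dynamic regularity extraction): a sequential
  Bayesian model that maintains up to M context hypotheses over possible
  change times with conjugate Gaussian statistics (D = 1: mean/variance;
  D = 2: plus lag-1 covariance), an observation-noise floor N, and a
  constant change hazard. Per tone it emits **surprisal**
  S_t = −ln P(x_t | x_1:t−1) and **belief change**
  δ_t = D_JS(B_t ‖ B_t+1) ∈ [0, ln 2]; a change is detected when
  max_t δ_t ≥ τ;
* the **32 multifeature variants** crossing per-feature D, early vs late
  integration, and the AVG / wAVG / MIN / MAX operators
  (`Late_D22_MAX` and friends);
* **listener simulation and fitting**: exhaustive grid search over
  (M, N, τ, w) minimizing detection-rate MSE across conditions, hinge
  loss against the listener's trial-by-trial responses, corrected
  d′, stratified cross-validation, and OLS of performance on fitted
  parameters;
* **model-guided epoching** for multichannel recordings: high/low
  surprisal percentile events, maximal-belief-change alignment,
  equal-occupancy 1-D (40-bin) and bifurcated 2-D (128-bin) surprisal
  binning, power-based epoch rejection, baseline-relative rms in dB, and
  a synthetic epoch generator for end-to-end checks.

Everything is tibble-first and pipe-friendly; fitted objects support
`tidy()` / `glance()`, and traces and binned results have `autoplot()`
methods.

## Worked example

Build the EEG-style experiment (4 conditions × 50 stimuli at 8.6 Hz),
simulate a listener with the best-fitting model variant, and summarize:

```r
library(drexr)

ex  <- build_experiment("nsp", seed = 1)   # pitch + spatial location
p   <- drex_params(D = 2, M = 10, N = 0.1)
rec <- simulate_listener(ex, "Late_D22_MAX", p, tau = 0.25)

detection_rates(rec)
#> # A tibble: 4 × 3
#>   condition     n  rate
#>   <chr>     <int> <dbl>
#> 1 both         50  0.84
#> 2 control      50  0
#> 3 pitch        50  0.52
#> 4 spatial      50  0.66

performance_summary(rec, attr(ex, "conditions"))
#> # A tibble: 1 × 5
#>   hit_rate fa_rate n_signal n_noise d_prime
#>      <dbl>   <dbl>    <int>   <int>   <dbl>
#> 1    0.673       0      150      50    2.78
```

The detection rate is highest when both features change (0.84) and
exceeds either single-feature condition (0.52, 0.66) — the signature of
integrating change evidence across features with a MAX rule — while the
control false-alarm rate is 0, giving a corrected d′ of 2.78. On a
single both-change stimulus the model flags the change right at the
midpoint:

```r
stim <- build_stimulus(design_conditions("nsp")[1, ], seed = 1)
jt   <- run_variant(stim, "Late_D22_MAX", p)
model_response(jt, tau = 0.25)
#> # A tibble: 1 × 3
#>   detected  time max_delta
#>   <lgl>    <int>     <dbl>
#> 1 TRUE        31     0.547
```

(The first changed tone is tone 31 of 60.) See the vignette in
`vignettes/multifeature-change-detection.Rmd` for the model details,
fitting procedure and epoching utilities, and `inst/cli/drex` for a
small command-line front end (`generate`, `run`, `simulate`).

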