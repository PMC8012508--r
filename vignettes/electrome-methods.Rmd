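---
title: "Methods: electrome signal analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electrome signal analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(electrome)
```

This vignette documents the statistical model behind each estimator in
`electrome`, the default parameters and why they were chosen, and the known
limitations. The intended signal is an electrophytography (EPG) micro-voltage
series ΔV sampled at 62.5 Hz — a 2 h acquisition is
`expected_length(7200, 62.5)` = 450,000 samples — but every function accepts
arbitrary lengths and rates.

## Signal model

A recording is modelled as

> ΔV(t) = colored-noise baseline + low-frequency undulation + sparse spikes

* **Baseline** — stationary `1/f^β` noise: power spectral density
  `S(f) ∝ f^(−β)`. β = 0 is white noise, β ≈ 1 pink, β = 2 Brownian;
  plant electromes typically sit in the "reddened" range β ≈ 0.5–1.5.
* **Undulation** — a slow oscillatory component in roughly 0.002–0.02 Hz
  (periods of 1–8 minutes) that appears *after* a stimulus.
* **Spikes** — sparse transients with fast rise and slow decay whose peak
  amplitudes are heavy-tailed (power-law distributed).

Four scalar parameters summarise a recording: the spectral exponent β, the
approximate entropy ApEn, the autocorrelation time L, and the tail exponent
μ of the |ΔV| distribution.

## Synthetic generators

`gen_colored_noise(beta, n, fs, seed)` uses **spectral synthesis**: Fourier
amplitudes proportional to `f^(−β/2)` (so the PSD goes as `f^(−β)`), phases
i.i.d. uniform on `[0, 2π)`, hermitian assembly, zero DC, then
standardisation to mean 0 / variance 1. This is exact in distribution for
the target spectrum, unlike filtered-noise approximations.

`gen_brownian()` integrates Gaussian steps (`cumsum(rnorm(n))`) and
standardises; its fitted β is ≈ 2 despite the non-stationarity, which is
why it serves as the β = 2 reference rather than `gen_colored_noise(2)`
alone.

`gen_undulation(base, amp, band, n_components)` adds a sum of 5 sinusoids
with random frequencies in the band and random phases, scaled so the
component RMS equals `amp ·
SD(base)`; the mean is preserved and `amp = 0` returns the base unchanged.

`gen_spikes(base, rate, tail_mu, amp_scale, rise_s, decay_s)` superimposes
Poisson-timed biexponential transients (0.2 s rise, 2 s decay) whose peak
heights follow a Pareto law with tail exponent `tail_mu = 4.5`;
`amp_scale = 1.5` keeps the spike layer from dominating the variance so that
undulation-driven changes in L remain visible.

`experiment_configs()` encodes the study design: both *before* conditions
are the bare β = 1.2 baseline (`undulation_amp = 0` — undulation is a
response to the stimulus, not a resting feature), while *bean-after* gets a
strong undulation (amplitude 2.5, spike rate 0.03) and *wheat-after* a
weaker one (1.2, 0.02). `gen_experiment()` implements the **paired design**:
recording *j* of `bean-before` and `bean-after` shares one plant id and one
baseline-noise seed, while the stimulus layers get phase-specific seeds — so
within-plant contrasts isolate the stimulus effect exactly as a paired test
assumes.

All generators draw from a private RNG stream (`with_seed()`), with
per-recording seeds produced by `derive_seed()`; user-level `set.seed()`
state is never disturbed.

## Descriptive statistics

`dispersion()` returns the biased (population) moment estimators; kurtosis
is **raw** by default (Gaussian = 3), matching the convention in which
leptokurtic electrome distributions are reported as values above 3. Use
`kurtosis_convention = "excess"` for the Gaussian-zero convention.

`correlation_time()` offers two estimators of L from the biased sample ACF:

* `"integral"` (default): the sum of the ACF up to its first non-positive
  lag. For an AR(1) with coefficient φ this converges to `1 / (1 − φ)`.
* `"one_over_e"`: the first lag at which the ACF drops below `1/e`.

When the ACF never crosses the threshold within `max_lag`, the returned L is
flagged `lower_bound = TRUE` rather than silently truncated — long-memory
(pink/brown) signals routinely hit this.

## Spectral estimation

`psd()` implements Welch's method: Hann window, 50 % overlap, per-segment
mean removal, density scaling such that `sum(psd) * df ≈ var(x)`. The
default segment length is `min(2^14, n/8)` rounded down to a power of two —
long enough to resolve 0.01 Hz at full problem size, short enough to average
many segments. The one-sided convention doubles every mirrored bin; the
Nyquist bin of an even-length segment has no mirror and is not doubled
(verified against `stats::spec.pgram`).

`fit_psd_exponent()` regresses `log10 S(f)` on `log10 f` by OLS over
0.01–10 Hz, excluding 4.5–5.5 Hz (a narrow artifact band at this acquisition
rate); β is minus the slope. At `n = 2^17` the fitted β recovers the
generator value within ±0.1 across seeds for white, pink and Brownian
noise. `classify_noise()` maps β to the nearest canonical color within a
±0.25 tolerance.

`cwt_scalogram()` computes an analytic Morlet transform (ω₀ = 6, FFT
convolution, L2 normalisation) on log-spaced scales; pseudo-frequency is
`fs · ω₀ / (2π a)`.

## Complexity

`apen()` is Pincus's approximate entropy — Chebyshev distance, self-matches
included, `Φ^m − Φ^(m+1)` in nats; `sampen()` excludes self-matches and
returns `−log(A/B)`. Defaults `m = 2`, `r = 0.2 · SD` are the standard
settings for physiological series of this length. Both kernels are O(N²)
C++; for series beyond `max_n = 20000` samples a centred sub-window is used
(recorded in the `"n_used"` attribute), since ApEn stabilises well below
that length while the full 450,000-point evaluation would be ~500× slower.

`multiscale_entropy()` coarse-grains by non-overlapping block means and
fixes the tolerance from the scale-1 SD (the Costa convention), so the
profile reflects structure, not the mechanical variance shrinkage of
averaging. White noise gives a falling profile; Brownian noise a rising one.
A constant series returns all zeros by definition.

`pdf_tail_fit()` estimates the tail exponent μ of `f(|ΔV|) ∝ |ΔV|^(−μ)`:
centre, take `|ΔV|`, bin into 60 log-spaced bins, and fit OLS on log–log
axes over bins above the 0.90 quantile. Two safeguards matter:

* bins with fewer than `min_count = 5` events are excluded — their
  log-density is dominated by discreteness noise and flattens the slope
  (without the filter, μ = 4 samples fit as ≈ 3.6; with it, calibration
  over μ ∈ {2, 2.5, 3, 4, 5} at n = 10⁵ recovers the generator value
  within ±0.05 on average);
* the `ok` flag requires r² ≥ 0.9, ≥ 5 tail bins, **and** near-zero
  log–log curvature (quadratic coefficient > −2). A true power law is
  exactly linear in log–log; a Gaussian tail is strongly concave
  (curvature ≈ −15 at these settings) and fails the flag even when its
  local linear r² is high.

## ML pipeline

`segment()` cuts a recording into 10 windows with 30 % overlap
(window length `w = floor(n / (k − (k−1)·overlap))`, step
`w − round(overlap · w)`). `extract_window_features()` computes, per window,
six summary statistics (mean, max, min, variance, skewness, kurtosis) over
three representations — FFT amplitude spectrum, Welch PSD, and Morlet
scalogram magnitudes — plus the window's ApEn: 19 features.
`pca_features()` z-scores them and keeps the first three principal
components (sign fixed so the largest loading is positive) alongside the
entropy.

`evaluate_models()` runs repeated stratified k-fold cross-validation
(defaults k = 5, 50 repeats) over a battery of seven classifiers plus a
`dummy_stratified` baseline that predicts labels proportional to the
training class frequencies — its accuracy converges to the sum of squared
class proportions and anchors the chance level. Accuracies are reported as
mean ± SD in percent; per-class sensitivity `TP/(TP+FN)` and precision
`TP/(TP+FP)` are attached. Fold assignment is stratified round-robin within
class, and every repeat of every model draws from its own derived seed, so
results are bit-reproducible.

`compare_conditions()` builds the five standard contrasts (within-treatment
before/after, between-treatment within-phase, and pooled bean-vs-wheat) from
a labelled recording set.

## Group statistics

`paired_compare()` and `independent_compare()` gate on a Shapiro–Wilk
normality test at α = 0.05: normal data get a paired *t* / Student's *t*
(equal variances); otherwise the Wilcoxon signed-rank / Mann–Whitney U test
is used. All tests are two-sided. Identical inputs are reported as a
degenerate no-effect rather than an error. `table_report()` applies this
machinery to seven parameters (asymmetry, kurtosis, mean, L, ApEn, PSD
slope, PDF tail slope) across the four conditions, matching before/after
pairs by plant id.

With n = 23 pairs and a 1-SD shift, the analytic power of the gated paired
procedure is ≈ 0.90 — adequate for the effect sizes the synthetic design
produces, and the type-I error stays at the nominal level on null data
(verified by simulation in the test suite).

## Reporting pipeline

`run_pipeline(pipeline_config(...))` chains generate → describe →
complexity → classify → stats, writing plain-text artefacts
(`descriptive.csv`, `multiscale_entropy.csv`, `features.csv`,
`model_reports.json`, `parameter_table.csv`, `parameter_tests.csv`) and a
`manifest.json` recording the config and seed. `render_report()` produces a
Markdown summary and marks skipped stages explicitly. A stage failure
aborts with the stage name in the error.

## Limitations

* The generators produce *stationary* surrogates (apart from the Brownian
  reference); real electromes drift, and no detrending beyond per-segment
  mean removal is applied.
* Spectral-synthesis noise has exactly uniform random phases; any
  phase coupling present in real signals is not modelled.
* ApEn on sub-windows assumes local stationarity; for strongly
  non-stationary data pass `max_n = Inf` and accept the cost.
* `pdf_tail_fit()` is a binned OLS estimator chosen for transparency, not a
  maximum-likelihood (Hill/Clauset-style) tail estimator; its `ok` flag is
  a heuristic screen, not a hypothesis test.
* Default examples and tests use n in the 4,000–131,072 range for speed;
  defaults scale unchanged to the full 450,000-sample recordings.
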