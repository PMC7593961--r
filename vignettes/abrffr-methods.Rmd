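---
title: "Methods: ABR/FFR measurement and censored Bayesian inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ABR/FFR measurement and censored Bayesian inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abrffr)
```

`abrffr` implements an analysis chain for two electrophysiological probes of
age-related cochlear synaptopathy: the click-evoked auditory brainstem
response (ABR), whose wave I indexes auditory-nerve activity and wave V
brainstem activity, and the frequency following response (FFR) to amplitude
modulated (AM) tones, whose envelope (ENV) and temporal-fine-structure (TFS)
components index sustained phase-locked activity. Because synaptopathy is
thought to spare threshold measures while thinning the supra-threshold fiber
population, the analysis centers on differential measures — wave I
amplitude ratios between high and low click levels, and FFR amplitude
differences between shallow and full modulation — and on regression of
these measures on age with audiometric and noise-exposure covariates
partialed out.

This vignette records the models, the tunable parameters, and the reasoning
behind every genuinely open design choice. No empirical claim is made here
that the test suite or `scripts/acceptance.R` does not itself compute.

## Stimulus design

Four stimulus objects are specified (`click_stimulus()`, `highpass_masker()`,
`am_tone()`, `notched_noise()`) and realized by `synthesize_stimulus()`.

* **Click**: a 100-µs rectangular pulse convolved with a linear-phase
  windowed-sinc bandpass filter (0.35–3 kHz); 2 ms of the filtered
  sequence centered on its peak form the stimulus. The filter order (1024,
  Hamming window) is a documented module constant: the corner frequencies
  are the substantive parameters, and any design with adequate stopband
  rejection reproduces the stimulus; tests check band concentration, not
  tap values. Click level is stored as dB ppeSPL: the waveform's
  peak-to-peak pressure equals that of a sinusoid at the stated SPL.
* **Highpass masker**: a 20-ms burst of pink (−3 dB/octave) noise,
  3.5–8 kHz, 5-ms raised-cosine ramps, used to mask basal cochlear regions
  so that the ABR originates from low-frequency regions.
* **AM tones**: carriers at 0.6 and 2 kHz, 75 dB SPL each, modulated at one
  of four rates near 100 Hz (93.3, 102.2, 111.1, 120 Hz) at 70% or 100%
  depth. Modulation adds sideband power:
  overall level = carrier + 10·log10(1 + m²/2), hence 76.76 dB SPL at full
  depth and 75.95 dB SPL at 70%.
* **Notched noise**: pink noise, 20 Hz–3 kHz, with notches two
  equivalent-rectangular-bandwidths wide centered on each carrier. Notch
  edges sit exactly one ERB-number above and below the carrier on the Cam
  scale, Cam(f) = 21.4·log10(0.00437·f + 1), rounded half-away-from-zero to
  1 Hz; this placement reproduces the band edges 515, 694, 1773 and
  2253 Hz. Rounding convention matters only at the 1-Hz print precision.

Calibration is abstract: pressure waveforms are in pascals with 0 dB SPL ≡
20 µPa RMS, and no transducer transfer function is modeled. Noise synthesis
is frequency-domain shaping of complex white Gaussian noise (band-limited,
−3 dB/octave magnitude), seeded and deterministic.

The presentation schedule (`build_abr_schedule()`) enforces the exact
conservation `burst + silence = 1/rate`: at 14.1 stimuli/s across
alternating ears with 20-ms bursts, the silent interval is 50.9 ms and the
per-ear rate 7.05/s; the click onset is jittered uniformly over 5–13 ms
after masker onset so that the masker onset response averages out.

## Preprocessing

* **Trigger compensation**: earphone tubes delay the acoustic stimulus by
  0.9 ms relative to the electrical trigger; `compensate_trigger_delay()`
  shifts trigger times accordingly.
* **Zero-phase FIR filtering**: the 256-tap linear-phase bandpass (0.1–1.5
  kHz for ABR, 0.06–1 kHz for FFR) is applied forward and its group delay
  removed exactly. A 256-tap (even) filter has a *half-sample* group delay
  (127.5 samples), so the compensation is an FFT-domain fractional-delay
  phase ramp — exact for band-limited signals and valid for either tap
  parity, rather than an approximation by integer shifting or
  forward-backward filtering (which would square the magnitude response).
  The taps are recentred to sum to zero, giving an exact DC null: the raw
  design attenuates DC by only ~30 dB with a 100-Hz lower corner, which is
  insufficient for electrode drift; the recentring perturbs the passband by
  less than 0.1%. A zero-phase contract test verifies that steady-state
  component phases pass through filtering unbiased.
* **Epoching**: windows are half-open `[t0, t1)` in samples with the
  trigger sample at t = 0 (−3 to 12 ms for ABR, −5 to 450 ms for FFR);
  per-epoch baseline means (3 ms / 5 ms) are subtracted. Triggers whose
  window exceeds the recording are dropped and counted.
* **Iterative-weighted averaging**: epochs (blocks of one epoch by default)
  are combined with weights proportional to the inverse of each block's
  residual-noise variance — the time-domain variance of the block minus the
  current grand estimate — iterating to a relative tolerance of 1e-6 (at
  most 50 iterations; convergence is typically immediate). The cited
  method's exact blocking constants are not restated in the source
  literature available here, so block size, tolerance and iteration cap are
  configuration, with these defaults. Under equal noise variance the
  procedure reduces to the arithmetic mean; under heteroscedastic noise it
  dominates the plain mean in MSE (verified by simulation). The residual
  noise variance of the average is estimated as `1/Σ(1/v_b)`, which the
  peak picker uses as its detection reference.

## ABR measurement

`pick_wave()` measures a wave as peak minus following trough: the peak is
the largest local maximum in the search window (ties to the earlier
latency), the trough the first local minimum within 4 ms after it; both are
refined by parabolic interpolation, giving sub-sample latencies. Default
search windows are wave I 1.0–3.5 ms and wave V 4.5–9.0 ms, widened by
0.5 ms at the 80 dB ppeSPL level where latencies are longer; the human
cross-checking step of the original semi-automatic procedure is out of
scope, so the windows are configuration, surfaced in `default_peak_windows()`.

**Detectability.** The criterion is a local SNR of at least 1, with the
noise reference defined as 4.5 × the residual-noise SD of the average.
The constant was calibrated once against the Monte-Carlo distribution of
peak-trough amplitudes that band-limited noise alone produces in the wave I
window (median ≈ 2.6 SD, 95th percentile ≈ 4.4 SD): at 4.5 SD a pure-noise
response is declared undetected roughly 95% of the time, which is the
operating characteristic the detection-floor simulations require. With a
noiseless response any positive amplitude is detected.

`estimate_noise_floor()` applies the same picker to a pre-stimulus window
of the same duration (detectability disabled — the dummy wave *is* the
noise) and reports the geometric mean and geometric SD of the measurable
dummy amplitudes plus the unmeasurable fraction.

`assemble_measurement_table()` sets the censoring bound to the dataset-wide
minimum detected amplitude (in the cohort that motivated this pipeline that
minimum was 0.38 nV) and flags undetected rows as censored at that bound.

## FFR measurement

Averages to rarefaction and condensation stimuli are combined as
`(r + c)/2` (addition; ENV survives, TFS cancels) and `(r − c)/2`
(subtraction; TFS survives). The halving keeps both on the single-response
scale; any common scale would cancel in the SNRs.

`component_snr()` Hamming-windows the −5…450-ms segment (no zero padding;
bin width ≈ 2.198 Hz), takes signal power at the bin nearest the target
frequency, and estimates noise as the **mean** power over the twelve bins
at offsets ±3…±8 (six per side, the two adjacent bins per side excluded to
limit leakage). ENV components are read at both modulation frequencies from
the addition waveform; TFS components at CF−MF, CF and CF+MF of the
0.6-kHz carrier from the subtraction waveform (the 2-kHz carrier's TFS
frequencies are too high to elicit an FFR). Components enter group-delay
estimation only when SNR strictly exceeds 6.64 dB — the 1% criterion of an
F(2, 2m) test with m = 12 — and only when all four components of a target
region pass.

Two estimator properties are worth recording:

* **Normalization.** With the noise power per bin defined as the mean of
  the twelve bins, the estimator is calibrated: under pure noise the
  average signal-bin power equals the average per-bin noise power (pooled
  null SNR ≈ 0 dB), whereas a raw 12-bin sum would sit ≈ −10.8 dB. The
  per-realization averages are *not* zero-centred even under this
  convention: the mean of dB values is ≈ −2.2 dB (Jensen gap of the log of
  an exponential power ratio), and the dB of the mean linear ratio is
  ≈ +0.7 dB because the Hamming window correlates neighbouring bins and
  inflates the expectation of an inverse mean. The calibration study
  (`null_snr_calibration()`) therefore reports the pooled statistic as the
  headline and the others as diagnostics.
* **Modulator spacing.** The two modulators within one stimulus are
  17.8 Hz ≈ 8.1 bins apart, so the outermost (+8) noise bin of the lower
  modulation frequency lies on the shoulder of the other tone's mainlobe.
  Noiseless ENV SNR consequently saturates near 10.8 dB. This is a faithful
  consequence of the published segment length, bin offsets and modulator
  spacing, not an artifact of this implementation; component-level
  calibration tests therefore use single-component simulations.

## Group delay

A single neural source at latency τ imposes phase φ(f) = φ₀ − 2πfτ on
nearby components; τ is estimated from the four modulation-frequency
components by exhaustive unwrapping: every vector of 2π adjustments
consistent with some τ in 0–30 ms is enumerated (the first component's
adjustment fixed at zero — a common 2π shift moves only the intercept),
each candidate is fitted by ordinary least squares of phase on frequency,
and the minimum-MSE candidate wins, with ties broken toward the smaller
latency (a determinism choice; the source algorithm is silent). The fit is
accepted only if the latency lies in 0–30 ms and the MSE is strictly below
0.01 rad², the printed acceptance criterion, computed on the phase
residuals about the OLS line so its units match the criterion's.

An independent oracle (`oracle_grid_delay()`) scans τ on a 0.01-ms grid,
minimizing the circular residual Σ wrap(φᵢ + 2πfᵢτ − μ)² with μ the
circular intercept. It shares no code with the unwrapping path; agreement
within 0.02 ms over a thousand random noiseless phase sets is an acceptance
requirement. With the real modulator spacing (~8.9 Hz) the delay ambiguity
period is ≈ 112 ms, so the 0–30 ms range identifies τ uniquely.

Only ENV latencies propagate to inference; TFS latencies are dropped,
mirroring their >75% missingness in the motivating cohort.

## Synthetic data

The generators exist so that every downstream stage is testable against
known truth; their defaults are the study conditions the package targets.

* **Cohorts** (`sample_cohort()`): a Gaussian copula over the configured
  correlation matrix (defaults: age↔PTA₄₋₁₂ 0.84, age↔PTA₀.₅₋₂ 0.37,
  PTA₀.₅₋₂↔PTA₄₋₁₂ 0.49, all else ≈ 0) with empirical-range marginals —
  age uniform 18–73 spanning the young/middle-aged/older groups,
  pure-tone averages on bounded scaled-beta ranges respecting the ≤30.5 dB
  HL low-frequency inclusion bound, log₁₀ noise exposure normal, cube-root
  musical experience scaled beta, and a 27:7 female:male ratio. Latent
  correlations are de-attenuated by 2·sin(πr/6) (the normal
  Pearson–Spearman relation) so that sampled Pearson correlations converge
  to the configured values after the marginal transforms; this is exact for
  uniform marginals and accurate to ≈0.02 for the beta marginals.
* **ABR recordings** (`simulate_abr_recording()`): Gaussian-windowed
  biphasic deflections (width 0.5 ms for wave I, 1 ms for wave V; defaults
  at 1.7/2.2 ms and 5.6/6.5 ms for 105/80 dB — plausible configured
  values, since simulation latency constants are not part of the published
  analysis) with peak-trough amplitude exp(linear predictor + subject
  effect), embedded in 1/f-below-100-Hz-plus-white noise at configured RMS,
  triggers alternating ears on the 14.1/s schedule, and an optional
  0.9-ms acoustic embedding delay so trigger compensation is exercised
  end-to-end.
* **FFR recordings** (`simulate_ffr_recording()`): steady-state ENV
  components at both modulation frequencies (polarity-invariant) and TFS
  components at CF−MF, CF, CF+MF (polarity-inverting), phases
  φ₀ − 2πfτ with τ = 14 ms by default (the motivating cohort's ENV
  latencies averaged 13–14 ms), balanced rarefaction/condensation sweeps.
* **Measurement tables** (`simulate_abr_measurement_table()`): a
  measurement-level shortcut for inference studies — per-subject random
  intercepts (SD 0.25 on the log scale), Student-t residuals (scale 0.2,
  df 15), censoring at the 0.38-nV floor. The recovery fixture sets the
  wave I baseline to 0.49 nV, back-computed so that expected censoring is
  ≈30% given the marginal log-amplitude SD.

What the generators deliberately do **not** emulate: biophysical cochlear
mechanics, montage-specific source projections (montage enters only as a
label/replicate), myogenic and movement artifacts with heavy-tailed
amplitude distributions, and drifting electrode impedances. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated statistical model, not robustness to every pathology of real
EEG.

## Inference

All outcome families use robust mixed-effects regression fitted by MCMC
with JAGS (via `rjags`): Student-t observation noise with the df a free
parameter bounded below at 2 (an exponential prior on the excess, mean 28),
subject random intercepts, and weakly informative zero-centred normal
priors (SD 10) on coefficients of standardized predictors. "Robust" is
realized as t errors; the source analysis names robustness without fixing
the mechanism, and a t family with free df is the standard choice that
nests the normal. Censored amplitudes enter through interval-indicator data
augmentation (`dinterval`): the latent response is t-distributed and its
indicator is observed below the bound, which marginalizes to the censored
likelihood ∫₋∞^bound p(y|θ) dy. (A truncated-node formulation would be
wrong: truncation renormalizes the density and contributes no information
about θ.) Amplitudes are modeled on the natural-log scale, which also
enforces positivity of the censored values; latencies and SNRs are modeled
untransformed and uncensored.

Each family's audiometric covariate follows the cochlear region probed:
PTA₀.₅₋₂ plus PTA₄₋₁₂ for ABR in quiet, PTA₀.₅₋₂ alone under highpass
masking, PTA₁₋₂ for FFR. Noise exposure enters as log₁₀ TCNE (a unit is a
tenfold energy difference) and musical experience as cube-root years; both
transforms and the centering/scaling are in `transform_covariates()`, with
scalers stored for inversion. Interaction sets beyond the named main
predictors are configurable rather than fixed, since the full term lists
live outside the available text.

Summaries are posterior medians with 99% credibility intervals (estimation
first; no multiplicity adjustment beyond the wide intervals), with
effective sample sizes and potential-scale-reduction diagnostics; fits are
reproducible given the seed (chains seeded `seed + chain`). Age effects on
log amplitude are reported as percent change per decade,
100·(exp(10β) − 1); derived contrasts (level-ratio age effects, wave I/V
ratio, modulation-depth differences) are computed drawwise before
summarizing.

The covariate correlation matrix uses a multivariate-t scale-mixture model
(Wishart prior on the precision, discrete uniform prior on a df grid).
Because every full conditional is conjugate, it is sampled with a Gibbs
sampler written in this package rather than through JAGS, which lacks a
sampler for a Wishart node with scale-mixture children; near-collinear
input triggers a degeneracy warning.

MCMC defaults (2 chains, 500 adaptation, 500 burn-in, 1500 kept draws for
`fit_model()`) are sized for the simulation studies shipped with the
package; convergence is flagged, not silently assumed, and users fitting
real cohorts should raise the budget.

## Orchestration and reproducibility

`run_pipeline()` chains simulate → abr → ffr → delay → fit → report over a
single configuration object (`default_config()`), writing plain-text
artifacts (CSV/JSON/YAML) plus a provenance record with a content hash of
the configuration; stages are independently runnable, re-deriving
deterministic inputs from the seed, and a missing upstream artifact names
the stage that produces it. The package's interface is R functions plus
`scripts/acceptance.R`; no shell front-end is provided because the intended
users drive analyses from R. Reruns with the same configuration are
byte-identical.

Problem sizes in the shipped studies — 20 replicate cohorts of 100
subjects for censored recovery, 10⁴ null draws for SNR calibration, 10³
phase sets for oracle agreement, 20-subject toy end-to-end runs at reduced
sampling rates (8192/4096 Hz) and sweep counts — were chosen as the
smallest sizes at which the Monte-Carlo error is comfortably inside each
acceptance band.

## Known limitations

* Peak picking is fully automatic; the human confirmation step of
  semi-automatic procedures is not modeled, so pathological double-peaked
  morphologies may be measured at the wrong local maximum.
* The group-delay model assumes a single dominant source; multi-source
  interference biases τ and is not decomposed.
* The 6.64-dB criterion is used verbatim; deriving it from first principles
  (exact F(2,24) vs large-m approximation) is left outside scope, and the
  strictness of the inequality follows the printed rule.
* EDF/BDF ingestion is not provided (no reader available in the supported
  dependency set); recordings enter via the documented plain-text container
  or in memory.
* Censoring is supported for amplitude families only; latency missingness
  is treated as missing-at-random by omission, mirroring the motivating
  analysis.
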