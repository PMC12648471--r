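---
title: "Methods: models, parameters, and design choices in insdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in insdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`insdyn` quantifies how auditory cortex entrains to pulsed infrared neural
stimulation (INS) of the thalamus: evoked-potential dose-response curves,
band-limited oscillatory power, entrainment at the pulse-repetition
frequency, chaotic versus stochastic single-response dynamics, stimulus
information transfer, and spike-field coupling. The package operates on
trial-epoched recordings — per-trial LFP waveforms, sorted spike times, and
stimulus metadata — and ships a synthetic generator that emulates the same
trial structure with known ground truth. This vignette records the models,
their assumptions, the tunable parameters, and the choices made where the
design was genuinely open. It states no empirical result that the test suite
or the acceptance script does not itself compute.

# Trial geometry and windows

A trial is `trial_length_s` seconds long (default 1 s) with a
`prestim_s = 0.2` s baseline. A stimulus train of `n_pulses` pulses of width
`pulse_width_ms` separated by offset-to-onset gaps `isi_ms` starts at the end
of the baseline. Derived windows (all half-open `[start, end)`, seconds,
trial-relative):

| window | definition | used by |
|---|---|---|
| baseline | `[0, prestim)` | peak z-scores, baseline power, tMTF `P_B` |
| onset | `[prestim, prestim + train + 0.1 s)` | evoked stats, band power, tMTF `P_s`, SFC |
| offset | `[onset end, trial end)` | offset band power |
| N1–P2 search | onset start to ≤ 150 ms past train end | peak detection |

Sample indexing is 0-based with the half-open rule `start ≤ k/rate < end`,
which makes adjacent windows partition the trial without double-counting a
sample at any rate (tested with rational-arithmetic assertions). A train that
would not fit before the trial end is rejected at construction. When a
dataset does not record pulse widths, 10 ms (mid-range of the hardware
capability) is assumed.

# Preprocessing

**Rate conversion.** Acquisition-rate LFPs (24.414 kHz) are decimated to the
1526 Hz analysis rate: an 8th-order Butterworth low-pass at 0.8× the target
Nyquist is applied forward–backward, then every 16th sample kept. The
achieved rate 24414.0625/16 = 1525.88 Hz is recorded under the nominal
1526 Hz label (mismatch < 0.1%). Two-stage 4×4 decimation agrees with the
single stage to < 0.1% RMS on band-limited input.

**Drift removal.** Slow baseline drift is removed with a Chebyshev type II
high-pass, cutoff 10 Hz. Only the filter family and cutoff are fixed by the
analysis definition; we chose order 4 and 40 dB stopband attenuation, applied
forward–backward (`filtfilt`) so the net phase is zero and N1/P2 latencies
are not shifted. The trial mean is subtracted first: a Chebyshev II stopband
is equiripple (−40 dB), so without explicit demeaning a DC offset would leak
through at the 10⁻⁴ level. Because no DSP package is available in the target
environment, the designs (analog prototype → bilinear transform) and the
zero-phase filter with odd-symmetric edge extension and steady-state initial
conditions are implemented in-package and validated against analytic
frequency responses.

The double-pass filter attenuates the evoked template by a constant factor
(the template's spectrum overlaps the 10 Hz transition band). Since the
factor is condition-independent it shifts only the regression intercept,
never the slopes — dose-response slope recovery is unaffected, which the
recovery tests confirm.

**Responsiveness.** A unit is INS-responsive when some PSTH bin inside the
onset window has firing rate at least 3.92 baseline SDs (twice the 1.96
critical z) above the mean spontaneous rate; the threshold is inclusive.
The analysis definition leaves open whether the criterion applies per bin or
to the whole-window rate; the per-bin maximum is implemented and the maximum
z is reported alongside the verdict. Default PSTH bin width is 10 ms, enough
to resolve 5-pulse trains at short ISIs. A zero spontaneous SD with evoked
spikes yields the explicit verdict "undefined z; responsive by nonzero evoked
count" rather than an exception.

# Evoked N1–P2 features

N1 is the first local minimum after stimulus onset whose z-score against the
same trial's baseline (mean/SD) is ≤ −2; P2 is the first subsequent local
maximum with z ≥ +2; both must lie within train end + 150 ms. The response
magnitude is the RMS of the filtered LFP from the stimulus-onset sample
through the P2 sample (inclusive). Choices: "first significant negative …
second positive" is implemented as first-qualifying-minimum then
next-qualifying-maximum with ties broken by the earlier sample; the RMS
window starts at stimulus onset (not N1); RMS is computed per trial rather
than on the trial-mean LFP (the aggregation level is not fixed by the
analysis definition; per-trial retains within-condition variance for the
hierarchical models).

# Wavelet band power

Bands: θ (4–8), α (8–13), β (13–30), low-γ (30–80), high-γ (80–200 Hz). For
spectral analyses the 10 Hz drift filter is **not** applied (only the 3 Hz
hardware high-pass is assumed), and the decomposition runs on the
per-condition trial-mean LFP.

The transform is an analytic Morlet CWT implemented as a constant-Q Gaussian
filter bank in the FFT domain, center-frequency parameter ω₀ = 6, grid
log-spaced at 12 voices per octave over 4–200 Hz. The one-sided PSD is
normalized as `S_f(t) = |W_f(t)|² / (4√π σ_f)` with `σ_f = f/ω₀`, so that
`P_f = 2∫S_f df` (the factor 2 restoring the negative-frequency half)
recovers the time-domain power of band-limited signals to within ~10%
(verified against a time-domain oracle). Integration uses composite
Simpson's rule on the nonuniform grid, exact for quadratics; a leftover
interval is integrated with the quadratic through the last three points, and
fewer than 3 in-band grid points fall back to the trapezoid rule with a
warning.

Stimulus-induced change is `dB_Δ = 10·log₁₀(P_f/μ_b)` with `μ_b` the mean
band power over the 200 ms baseline of the same trials. Samples inside the
cone of influence (edge margin `√2·ω₀/(2πf)` per frequency) are excluded
from window averages; when that would empty a window (the baseline at θ
frequencies with 1 s trials) the full window is used instead — θ/α baseline
estimates therefore carry some edge bias, which is a physical limit of 1 s
epochs, not a tunable.

For the regressions, the onset-window statistic is the **maximum** of the
instantaneous `dB_Δ` over the window (matching the modeled `max(dB_Δ)`
response); the offset statistic is the window **mean** (the aggregation for
offset windows is not fixed by the analysis definition; the mean is the
conservative summary for a sustained suppression and is flagged in outputs).
Between-band Pearson correlations are computed within 500 µJ energy bins with
a two-sided shuffle-surrogate p (`(1 + #{|R*| ≥ |R|})/(n_shuffle + 1)`,
default 1000 shuffles, seeded).

# Temporal modulation transfer functions

`tMTF = 10·log₁₀(P_s/P_B)` where `P_s`, `P_B` are LFP power at the ISI
frequency in the stimulation (train + 100 ms) and baseline windows; |tMTF| ≥
3 dB (a doubling or halving) is significant; ISI frequencies at or above the
763 Hz analysis Nyquist are excluded.

Power at an exact (off-grid) frequency is the single-frequency chirp-z value
— the windowed DTFT evaluated at `f` — with a Hann taper and coherent-gain
normalization `2|X(f)|²/(Σw)²`. This normalization makes a unit sinusoid read
0.5 (its power) regardless of window length, which is what lets the 200 ms
baseline be compared against stimulation windows of varying length; it is
the natural scale for line components such as pulse-locked entrainment
(a density normalization would make line-component power grow with window
length). The analyzed frequency defaults to `1/ISI` (so 100, 50, 25, 10,
5 ms ↔ 10, 20, 40, 100, 200 Hz); the pulse-period alternative
`1/(pulse_width + ISI)` — the frequency the synthetic generator actually
injects — is exposed as `freq_mode = "pulse_period"`. One response per
(electrode, condition) is computed on the trial-mean LFP; percentages of
±3 dB responses are tabulated over energy bins 0–0.5, …, 3–3.5, >3.5 mJ with
empty cells reported as NA.

# Nonlinear dynamics

**Modified 0–1 test.** The series φ(n) is mapped to translation variables
`p(n+1) = p(n) + φ(n)cos(cn)`, `q(n+1) = q(n) + φ(n)sin(cn)` for 100 draws of
`c ~ U(π/5, 4π/5)` (the restricted support avoids resonance overestimation).
The time-averaged mean squared displacement `M(n)` is computed for
`n ≤ N₀ = N/10` with additive uniform noise `σρ_n`, `ρ_n ~ U(−½, ½)`,
σ = 0.5, which suppresses spurious correlation of small bounded oscillations.
The reported statistic is `Kc = median_c corr(M, n)`, clipped to [0, 1]
(raw correlations can be slightly negative; the unclipped value and the
per-c values are retained in the result). The `log M / log n` growth-rate
form is kept as a diagnostic only — the correlation/median form is the
final statistic. The displacement sum is evaluated via FFT autocorrelation
(O(N log N)); the literal O(N·N₀) definition is retained as an internal
reference implementation and the two are asserted equal in the tests.

**Stochasticity gate.** The 0–1 test cannot distinguish chaos from noise
(an AR(1) series also scores Kc ≈ 1), so responses pass through a
permutation-entropy gate first. Normalized permutation entropy uses
embedding dimension m = 5, lag τ = 1 (common practice for ordinal-pattern
determinism screens; series should exceed (m+1)! samples). A series is
"deterministic" iff its entropy falls below 0.95 × the 5th percentile of 100
shuffled surrogates — shuffling destroys all temporal structure, so genuinely
stochastic series are statistically indistinguishable from their surrogates,
while deterministic dynamics (with forbidden ordinal patterns) fall far
below. Constant series are "degenerate". Only strongly non-stochastic
responses should be forwarded to chaos reporting, mirroring the strict
inclusion rule of the analysis this package implements.

**Mutual information.** MI in bits between stimulus energy condition and a
scalar response (per-response N1–P2 RMS; the response reduction is not fixed
by the analysis definition and RMS is the package's choice, configurable by
passing any scalar). Conditional densities `p(r|s)` are Gaussian-kernel
smoothed histograms on a common 21-bin grid, each class using its own
normal-reference bandwidth (per-class bandwidths keep well-separated classes
resolved; a pooled bandwidth oversmooths exactly when MI is high); the
marginal is the class-weighted mixture, which guarantees `I ≥ 0`. The fixed
21-bin count is the default; the Doane rule is available as the data-driven
alternative (`n_bins = "doane"`). Estimation bias is removed by the quadratic
law `I_est(N) = I_true + a/N + b/N²` solved exactly through mean estimates at
subsample fractions 1, 0.5, 0.25 (stratified within class, 10 seeded draws
per fraction; the replicate count is a variance-control choice).

**Regime clustering.** (MI, Kc) points are standardized and clustered by
K-means (10 restarts) for k = 2…6; k is chosen by maximum mean silhouette
width. A best silhouette below 0.5 flags weak cluster structure (the
"no interior maximum" degenerate case). The MI bifurcation readout is the
minimum of the MI-marginal kernel density between the two cluster centers —
a descriptive statistic, not a fitted parameter.

# Spike-field coherence

`SFC(f) = |⟨S_ny⟩| / (√⟨S_nn⟩·√⟨S_yy⟩)` over trials, bounded in [0, 1] by
Cauchy–Schwarz, with SFC ≡ 1 for a single trial (a useful identity test).
Spikes are binarized on the LFP sample grid within the onset window; spike
indicator and LFP are mean-removed and Hann-tapered; per-trial cross- and
auto-spectra are averaged before normalization. The estimator (simple tapered
periodograms) is the package's choice — the upstream toolbox's taper is not
specified — and mean removal prevents the spike-rate DC from dominating low
bands. Band SFC is the mean over in-band frequency bins.

# Bayesian models

All models: broad Normal(0, 10²) priors on intercepts and slopes, half-Normal
(10) on scale parameters, 95% HDI inference, significance iff the HDI
excludes 0, MAP = mode of the kernel-smoothed marginal (clamped into the HDI,
multimodality flagged). The HDI is the narrowest interval of the required
mass, never wider than the equal-tailed interval. Posterior-predictive checks
report the Bayesian p-value of a χ²-type discrepancy; split-chain R-hat above
1.05 flags (never silently drops) a fit.

**Sampler.** No MCMC engine is available in the target environment, so the
models are sampled by a blocked Gibbs sampler written for this
linear-Gaussian family: all coefficients are drawn jointly from their exact
conditional multivariate normal (one Cholesky solve per iteration), while the
residual SD and each group-level slope SD move by adaptive random-walk
Metropolis on the log scale (targeting 44% acceptance during warmup). For
conditionally conjugate linear models the joint coefficient draw mixes
essentially perfectly, so this meets the "any MCMC satisfying the contract"
bar; defaults are 4 chains × 2000 draws after 1000 warmup (tests use smaller,
stated settings).

**Hierarchical dose-response.** `ln(RMS)` (or a dB statistic, already on log
scale) on `ln E`, `ln ISI`, and `ln E·ln ISI`, with group-level deviations on
the three slopes per electrode-within-animal group and one half-normal SD per
slope block (a two-level non-centered-equivalent parameterization; the full
multi-level graph of the original analysis is not restated in its main text).
The interaction is the product of the transformed predictors — the
transform of the interaction is not fixed by the log-transform statement, and
the product-of-logs choice keeps the design full-rank on the condition grid.
`E = 0` rows are dropped before the log transform (ln 0 undefined); an
ε-offset variant (`log_offset`) is exposed instead of silently imputing.
Shrinking the group-scale prior toward 0 demonstrably collapses the model to
the pooled regression (limit-checked in the tests).

**Spike-rate model.** The printed form of the spike-rate regression,
`a + ln(β₁·rate) + ln(β₂·ISI)`, has no identifiable slopes (the β's fold into
the intercept); the reported estimates are only consistent with slopes on log
predictors, so the model is `ln(RMS) = a + β₁ ln(rate) + β₂ ln(ISI)`, rate
averaged over the stimulus interval + 50 ms, positive-rate rows only.

**Knots and splines.** The knot is located where the derivative of mean SFC
with respect to `ln E` has its largest jump (absolute first difference of the
discrete derivative); if no jump exceeds twice the median absolute jump plus
a numerical floor, the verdict is "no knot" and a plain linear model applies.
The piecewise model is the continuous two-segment form
`SFC = α + β_below·min(lnE, ln t) + β_above·max(lnE − ln t, 0)`, so each
slope influences only its own domain (the basis-spline domain-confinement
property); segments with fewer than 4 points are flagged.

# The synthetic world

The generator's defaults state the emulated study design: 5-pulse trains,
energies on a 0–4.5 mJ grid, ISIs 0.2–100 ms, 1 s trials at 1526 Hz with
200 ms baseline, 30–60 trials per condition (default 30; tests state smaller
sizes where they scale down), 4 electrodes in 2 animals. Dose-response
coefficients default to `β_E = 0.087`, `β_ISI = 0.065`, `β_E×ISI = −0.0038`,
residual SD 0.51 — the population-level estimates the generator is meant to
emulate — with `β₀ = 3` giving ~20 µV responses at 1 mJ/1 ms, a realistic
evoked-LFP scale. Each trial sums:

- an N1–P2 template (difference of two gamma-shaped lobes, N1 at 25 ms and
  P2 at 70 ms post onset by default, completing inside the 150 ms search
  window) scaled so its onset-through-P2 RMS follows the log-linear law
  exactly (amplitude 0 at E = 0);
- stimulus-gated band oscillations with power proportional to E (log-linear
  with unit slope) and per-band gains emphasizing β/γ;
- a stimulus-locked sinusoid at the pulse rate `1/(width + ISI)` during the
  train, amplitude proportional to E — *locked* (fixed phase relative to
  train onset) because it models evoked entrainment, so it survives
  trial-averaging, unlike the random-phase band oscillations which model
  induced power;
- 1/f Gaussian background noise (exponent 1, SD 3 µV), the standard LFP
  background model.

Spikes are an inhomogeneous Bernoulli process on the sample grid
(`λ₀ + gain·E` in the onset window), optionally thinned by a von Mises factor
of concentration κ on the phase of a chosen LFP band; κ = 0 makes spiking
independent of the LFP.

The regime-feature generator emulates the two-regime chaos-vs-MI scatter: a
low-information cluster (MI < 0.4 bits) of uniformly high-chaos responses,
and an informative cluster (MI > 0.4) whose K values are drawn from two
broad, overlapping modes — bimodal but not separable into sub-clusters, so
the stated two-regime structure is what the silhouette criterion recovers.

**What the generator does not emulate** — and hence what a green test does
not establish: no biophysical (conductance-based) dynamics, no thermal or
optical tissue physics, no traveling waves or inter-electrode structure, no
latency shifts with energy, no bursting or refractory spike statistics, no
non-stationary or artifact-laden noise. Recovery tests demonstrate that the
estimators are correct and calibrated on data obeying their assumed models;
they cannot certify behavior on real recordings that violate those
assumptions. Dose-response recovery tests run with band oscillations and the
ISI component disabled, because with them enabled the measured onset RMS
provably does not follow the pure template law — the clean configuration is
the experiment that tests the estimator against its own stated world.

# Numerical conventions and degenerate inputs

- LFP samples are snapped to float32-representable doubles at construction,
  so the float32 on-disk format (`manifest.json` + per-electrode binary LFP
  matrix + CSV spike table) round-trips bit-exactly.
- All generators and samplers are pure functions of (config, seed); the
  pipeline derives per-stage seeds as `seed + stage index`, so disabling one
  stage never changes another's output.
- Degenerate inputs produce explicit verdicts, not exceptions, wherever the
  quantity is well-defined to be absent: zero baseline SD (invalid N1–P2
  feature with reason), zero baseline power (undefined dB/tMTF, flagged),
  constant series (degenerate chaos/gate verdicts), spikeless units
  (undefined SFC, flagged), empty tMTF bins (NA).
- Monte-Carlo tests fix their seeds; thresholds come from the stated
  protocols, and where a fixed-seed check guards a distributional property
  the property was separately verified across independent seeds (noted in
  the test).

# Known limitations

- θ-band baseline power in 1 s trials is edge-biased (cone of influence
  wider than the baseline); results there should be read comparatively, not
  absolutely.
- The permutation-entropy gate's exact threshold in the upstream toolbox is
  not restated in the analysis definition; the surrogate-based rule here is
  principled but not guaranteed identical, so pass-rates (e.g. the fraction
  of responses deemed deterministic) are not comparable across
  implementations.
- The sampler is exact for the implemented linear-Gaussian family only;
  extending the models (e.g. non-Gaussian errors) requires revisiting it.
- Headline statistics of the original study (coefficient tables, tMTF
  percentages, knot energies) depend on its recordings and are not
  reproduced here; the package reproduces the *machinery* and verifies it on
  calibration targets and synthetic ground truth.
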