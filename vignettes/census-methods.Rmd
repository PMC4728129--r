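---
title: "An electrophysiological census pipeline: models, measurements, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An electrophysiological census pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephyscensus)
```

## The problem

Censuses of neuronal populations characterize each recorded cell with a
battery of protocols — voltage-clamp IV steps, current-clamp step and
cosine injections, paired-pulse synaptic stimulation, and spontaneous
recording — and reduce each cell to a few dozen named variables. Two
features make the analysis statistically delicate. First, not every
protocol succeeds in every cell, so the feature matrix has substantial
missingness (around 18% in the tectal census this package is modelled
on), which most multivariate methods do not tolerate natively. Second,
many scientific claims concern *variability* (is the population more
diverse at a later stage? less diverse after sensory stimulation?), which
calls for cloud-geometry and clustering statistics rather than mean
comparisons.

`ephyscensus` implements the full chain: a generative simulator with
known ground truth, extraction of 33 canonical variables, and the
multivariate statistics, so that every stage is testable end to end
without any real recordings.

## The generative model

All protocols are sampled at 10 kHz. A `cell_params()` object carries the
ground truth the extraction stage tries to recover. A cell with
`noise_sd = 0` is fully deterministic (bit-identical sweeps), which turns
extraction tests into exact round trips.

**IV steps.** One 150 ms sweep per command potential from −65 to +115 mV
in 20 mV steps. (+115 mV absolute is an unusually depolarized endpoint
for a physiological command series; it is retained as the protocol's
printed specification.) Voltage-clamp traces are built directly from the
same curve families the extraction stage fits — a sigmoid Na⁺ IV with a
brief Gaussian time envelope peaking 2 ms post-step, a hinged-exponential
stable K⁺ current reaching steady state by 10 ms, and a sigmoid transient
K⁺ component decaying with a 15 ms constant — plus white noise. The
passive component is treated as already subtracted, as users of real data
must leak-subtract upstream. Generating from the fit forms makes
fit-recovery an exact oracle: that is a design choice, not a claim that
real IV curves are noiseless sigmoids.

**Step injections.** Ten 300 ms pulses, 0–180 pA in 20 pA steps. The
spike count per sweep follows the difference-of-exponentials tuning
`ns(i)` with fixed shape (onset 10 pA, constants 300 and 60 pA) and
amplitude `spike_gain`, so "I best" has a closed form (≈ 130.7 pA)
independent of the cell. Spikes are raised-cosine waveforms with exact
closed-form 10–90% rise (0.5904 × rise duration) and half-height width
((rise + fall)/2), riding on a subthreshold potential that is driven to
the threshold with a fast 3 ms constant in spiking sweeps — so every
kink sits at `spike_thresh` — while repolarization after the pulse decays
with the membrane constant `rm × cm`, the ground truth for the tail fit.
Successive inter-spike intervals grow geometrically by
`1 + 15 ms / spike_adapt` and amplitudes shrink by a fixed 0.9 per spike,
giving known accommodation ratios. The spike generator is
phenomenological, not conductance-based: the analysis consumes only
trace-level features, and a phenomenological model provides exact ground
truth.

**Cosine injections.** Ten repeated sweeps of five 200 ms bouts at 100,
50, 30, 25 and 20 Hz. Spikes per bout follow a difference-of-exponentials
period tuning whose onset is pinned at zero period (real cells do spike
at 100 Hz) and whose fast constant is solved so the argmax falls at
`res_period`; this requires `res_period < res_width`. The amplitude is
6 × `spike_gain`: bouts must carry enough spikes that *integer* counts
resolve the tuning curve — with identical deterministic sweeps, per-bout
counts quantize to whole spikes, and a curve sampled at ±0.5 spike around
a ~30-spike peak still localizes its argmax to within the 15% round-trip
tolerance, whereas a ~5-spike peak would not. Within the 100 Hz bout,
spikes are spread over waves by a rise-and-decay envelope peaking at wave
`wave_decay`; deterministic cells use error-diffusion integerization,
stochastic cells draw per-wave Poisson counts and jitter spike times by
`spike_jitter`.

**Synaptic stimulation.** Five shocks at each of ten inter-stimulus
intervals (10–50, 100–300 ms), five repeats each (50 sweeps). Each shock
contributes a 1 ms biphasic artifact, an alpha-shaped EPSC (onset 5.5 ms,
constant 1.8 ms) whose charge follows a facilitation/depression state
model (facilitation per `syn_facil`/`syn_tau`; short-ISI depression per
`syn_dep`/`syn_tau_dep`, which is what gives the charge-vs-ISI curve its
interior peak), and a delayed polysynaptic hump spanning the 15–145 ms
window. The model's total charge per ISI has a closed form used as the
round-trip oracle.

**Spontaneous recording.** One minute of Poisson-timed alpha-shaped
EPSCs (mean amplitude `mini_amp`, 10% scatter) over Gaussian noise.

**Cohorts.** Per-group parameter distributions are configuration, not
estimates of real animals: the defaults encode qualitative directions
(excitability rising to a transient peak at the middle stage, broader
distributions at the oldest stages, spikier but less variable cells after
stimulation). Missingness is applied completely at random, never removing
a row's or column's last observation; the census this package mirrors
does not characterize its missingness mechanism, so MCAR is the neutral
choice. A direct latent-factor generator (`simulate_feature_matrix()`)
provides feature matrices for statistical-stage tests where trace-level
simulation would add nothing.

## Extraction: formulas and numerical choices

**IV windows.** The peak Na⁺ (window minimum) and peak K⁺ (window
maximum) currents are read from an early window and the steady-state K⁺
current from a late window, with the transient K⁺ current as their
difference (`I_KT = I_K_peak − I_KS` holds exactly by construction). The
conventional window bounds are read as samples at 10 kHz — 0–18.5 ms and
116.5–136.5 ms — so both windows fit inside the 150 ms step; both are
configurable.

**Fit formulas.** The sigmoid is canonicalized as
`I(v) = c/(1+exp(−(v−a)/b)) + d`, which has the stated half-maximum
property at `v = a`. In the stable-K⁺ hinge formula the symbol `e` is
Euler's constant, so the activation potential is `a + b`. The
linear-times-exponential family `(x−a)·exp(−(x−b)/c)·d + e` is
over-parameterized (`d·exp(b/c)` is one degree of freedom); the fitter
pins `b` at the observed peak and estimates the identifiable four, which
leaves every reported quantity unchanged. Fits use bounded
Levenberg–Marquardt least squares with deterministic multi-starts
(including starts whose curve peaks at the observed peak); the hinge
family, whose steep exponentials span many decades and defeat
gradient-based optimization, is fitted by profiling `(activation, log b)`
on a grid with the linear parameters solved exactly, then refining by
Nelder–Mead from the best eight grid seeds. Curve argmaxes and extrema
are evaluated on a 0.1-unit grid over the sampled range; a
linear-times-exponential fit whose maximum lands on the last sampled
point, or whose curve is flat, is flagged (`pinned`).

**Spike detection.** A running-median baseline (25 ms window) is
subtracted; the residual is lightly smoothed (5-sample moving average:
noise shrinks by √5 while a ≥ 0.5 ms spike barely attenuates) and
thresholded at the larger of a 10 mV amplitude floor and 6 robust SDs;
peaks are snapped back to the raw residual, separated by a 1.5 ms
refractory gap, and shapes outside a [0.2, 10] ms width band are
rejected. All thresholds are arguments. The kink point is the maximum of
the second time-derivative in an 8 ms pre-peak window, with smoothing
applied only when the local noise demands it, since smoothing drags the
curvature maximum up the rising phase. At 10 kHz the kink potential of a
0.4 ms-rise spike is quantized: the first on-rise sample already sits
~3 mV above the true initiation point. Accommodation ratios are reported
as 2nd/1st (ISI) and 2nd/1st (amplitude), so values below 1 mean
amplitude accommodation.

**Jitter.** Spike trains become delta trains on the sampling grid,
convolved with a σ = 2 ms Gaussian and normalized to unit L2 norm; the
index is `ln(1 − mean pairwise scalar product)`. Two single-spike trains
offset by Δt have the closed form `ln(1 − exp(−Δt²/4σ²))`. Empty sweeps
are excluded from pairing; a mean product of 1 (identical trains) is
clamped to `1 − 1e−12` before the log, so the index is always finite and
non-positive.

**Synaptic windows.** Artifact samples (2 ms post-shock, configurable)
are bridged by linear interpolation rather than dropped, so the charge
integral does not lose response area under the blank. Total charge is
integrated from the first shock to 300 ms after the last (the protocol
leaves the window end unstated; "onset to next stimulus or +300 ms" is
the default). Monosynapticity is oriented mono/poly — the mean 5–14 ms
window current over the mean 15–145 ms current, larger meaning more
monosynaptic, matching the name — computed on the long-ISI conditions
with the late window clipped at the next shock; a near-zero poly-window
mean yields a missing value rather than an unstable ratio.

**Minis.** Matched-filter detection with an alpha template; amplitudes
are read from the filtered peak divided by the filter's known gain for a
unit-amplitude event, which is far more noise-robust than the raw sample
maximum. No junction-potential correction is applied anywhere.

**Open choices resolved.** "Mean spikes per cosine injection" is
computed per wave (per-frequency bout count divided by its wave count,
averaged over frequencies); per-bout averaging is available from the same
bookkeeping.

## The statistical stage

Correlations are pairwise-complete with per-pair n reported; the FDR
procedure is Benjamini–Hochberg step-up (the standard reading of "the FDR
procedure"), returning the implied per-test p threshold. Principal
variables use the mean squared correlation share, whose noise floor for
an uncorrelated variable is exactly 1/p (3.0% at p = 33); subset shares
use the mean multiple-R² of every variable on the subset, one of several
equivalent formulations of the squared-RM criterion — users comparing
against other definitions should note this choice.

PCA with missing values is probabilistic PCA fitted by EM over observed
entries: deterministic initialization from the SVD of the mean-imputed,
column-standardized matrix (standardization before all PCA and distance
computations is the default); convergence when the relative change in
expected reconstruction error falls below 1e−6, capped at 5000
iterations; a final E-step refreshes scores against the converged
loadings, and loadings are rotated to principal axes so they are
orthogonal with non-increasing explained shares. Shares are computed on
observed entries only — with missing data they are biased low, because
missing values cannot contribute to explained variance even though the
model predicts them, and should not be compared against complete-data
PCA shares. Promax rotation is varimax followed by oblique Procrustes
toward the power-4 target (the conventional default); scores are
counter-rotated so the data approximation is unchanged. Projection of
new cells uses the same regression-scoring formula as the fit's E-step,
so self-projection is exact.

Multiple imputation is Gaussian chained equations with posterior draws
of coefficients and residual variance (5 sweeps, 50 imputations by
default), each replicate reproducible from (seed, index). The
cloud-geometry engine standardizes, imputes, then subsamples each group
to 50 cells 10 times per imputation, computing a statistic per subsample
(median city-block distance; AGNES coefficient via `cluster::agnes`,
cross-checked in tests against the first/final merge-height definition;
local-PCA two-component share) and comparing the 500 values per group by
Welch t-test. The subsample size compensates for unequal group sizes.

The variance screen is directional by default: the scientific question
is "did variability increase?", and at the census's group sizes
(n ≈ 60/group) the one-sided F test has ~82% analytic power against an
SD ratio of 1.4 where the two-sided test has ~72%. The alternative is an
argument for users who want the two-sided test. Sequential regression
reports type-I sums of squares as shares of total response variance —
order-dependent by construction, so the predictor order is explicit
configuration. Rank renormalization (for de-banding activation-potential
plots) maps ranks back to original units through a cubic polynomial with
a final strict-monotonicity correction, guaranteeing the output ordering
equals the input ordering.

Victor–Purpura distances use the standard dynamic program (insert/delete
1, shift q·|Δt| capped at 2) with q = 0.1/ms; step-protocol trains are
concatenated in ascending current order first. The 2D embedding is
classical (Torgerson) MDS — the variant is not dictated by the method's
description; nonmetric MDS would be a reasonable alternative — with a
deterministic sign convention. Similar-spiking groups are the reference
cell plus its five nearest neighbors in the embedding.

## What the tests establish — and what they do not

Round-trip tests on noiseless cells show the extraction formulas are
implemented correctly (activation potentials to ±0.5 mV, maximal currents
to ±2%, resonance argmax to ±15%), and the statistical stage is verified
against closed forms, brute-force oracles, and power simulations at the
study's sample sizes (e.g. the imputation + subsampling procedure detects
an injected 22% cloud-size inflation between groups of 64 and 56 cells at
18% missingness). None of this validates the generator as a model of real
tectal neurons: real spikes are not raised cosines, real IV curves
deviate from the fit families, electrode drift and seal quality are not
simulated, and real missingness need not be MCAR. The synthetic defaults
reproduce directions of change, not the real data's values.

Problem sizes in the shipped tests and acceptance script are chosen to
keep full runs interactive: cohorts of 8–24 fully simulated cells
(spontaneous traces shortened to 10–20 s where only the bookkeeping is
under test), 500 draws for Monte-Carlo checks, 50 imputations × 10
subsamples for the cloud analysis — the same resampling depth the
census design specifies.

## Known limitations

Leak subtraction is out of scope (the simulator emits passive-subtracted
traces; real traces must be pre-subtracted). There is no manual spike
curation, no online analysis, and no nonlinear ordination beyond the R²
quality metric used to compare embeddings. The EM PCA treats the noise
variance as a single scalar; a fully Bayesian treatment with per-variable
noise would be a natural extension. Trace containers are CSV/JSON; a
hierarchical binary container would be preferable for very large cohorts.
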