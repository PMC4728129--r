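# ephyscensus

Tools for large-scale electrophysiological censuses of neuronal
populations: simulate whole-cell patch-clamp recordings with known ground
truth, extract a canonical set of 33 cell variables, and analyze the
resulting feature matrices with the multivariate machinery this kind of
study needs — correlation screens under FDR control, principal-variable
rankings, PCA with missing values, imputation-based cloud geometry and
clustering summaries, and spike-train similarity analysis.

The package is modelled on censuses of developing *Xenopus* tadpole optic
tectum neurons, where each cell is characterized by voltage-clamp IV
steps, current-clamp step and cosine injections, paired-pulse synaptic
stimulation of the optic chiasm, and a minute of spontaneous recording —
and where no cell contributes every measurement, so every downstream
statistic must tolerate missing data.

## What it computes

**Per-cell variables (33).** Passive properties (Cm, Rm, Ra, holding
current); IV-curve parameters for the transient Na⁺, stable K⁺ and
transient K⁺ currents, from least-squares fits of

    I(v) = c / (1 + exp(-(v - a)/b)) + d          (Na, K-transient)
    I(v) = max(0, exp((v - a)/b) - e) · c + d     (K-stable, e = Euler's)

with half-activation `a` and activation `a + b`; spike shape (threshold at
the maximum of the second time-derivative, amplitude, 10–90% rise, width
at half-height) and train dynamics (ISI and amplitude accommodation,
repolarization tail); spiking tuning from

    ns(i) = max(0, exp(-(i-a)/b) - exp(-(i-a)/c)) · d

(argmax = "I best", maximum = "N spikes, step"), and the analogous
period-tuning, per-wave transient `(x-a)·exp(-(x-b)/c)·d + e` (argmax =
`a + c`), spike-timing jitter `ln(1 − mean pairwise product)` of
Gaussian-smoothed (σ = 2 ms) unit-norm trains; synaptic charge-vs-ISI
resonance, paired-pulse facilitation ratio, monosynapticity (5–14 ms vs
15–145 ms window means), and mEPSC frequency/amplitude.

**Across cells.** Pairwise-complete correlations with Benjamini–Hochberg
FDR; principal variables (mean squared correlation shares, noise floor
1/p); probabilistic PCA fitted by EM over observed entries only, promax
rotation, and projection of new cells; Gaussian chained-equation multiple
imputation feeding median city-block cloud sizes, AGNES clustering
coefficients and local-PCA variance shares compared across groups;
Victor–Purpura spike-train distances (q = 0.1/ms) with classical MDS;
group tests (Mann–Whitney, Welch, directional variance ratio, one-way
ANOVA with η²) and sequential-regression variance partitioning.

## Worked example

```r
library(ephyscensus)

# one synthetic cell with known ground truth
params <- cell_params(noise_sd = 1.5, seed = 42)
recs   <- simulate_cell(params, spont_duration_s = 60)
feats  <- extract_all(recs)
round(feats[c("I Na activation", "I Na", "N spikes step", "I best")], 2)
#> I Na activation            I Na   N spikes step          I best
#>          -34.84         -400.25            3.99           98.90
```

The cell was generated with half-activation −35 mV and peak Na⁺ current
−400 pA; the extracted values recover both to within the fit tolerance,
and the spiking tuning identifies the current producing maximal spiking.
A cohort run ties everything together:

```r
cfg <- run_config(design = cohort_design(
  n_cells = c(s45_46.naive = 12, s48_49.naive = 12),
  missing_rate = 0.1, spont_duration_s = 20, seed = 7),
  out_dir = "demo_run", n_imputations = 10, n_subsamples = 5,
  subsample_size = 10, seed = 7)
art <- run_pipeline(cfg)
report_run(art, n_top = 3)
#> Census run: 24 cells x 33 variables; 9.0% missing
#>
#> FDR-significant correlations: 3 of 528 pairs (implied p threshold 2e-04)
#>   N spikes cosine          ~ Jitter                   r = -0.98 (n = 20)
#>   Spiking resonance        ~ Spiking resonance width  r = +0.74 (n = 20)
#>   Synaptic resonance       ~ Synaptic resonance width r = +0.72 (n = 23)
#> ...
#> Cloud size (median city-block): s45_46.naive 35.1 vs s48_49.naive 41.0;
#> ratio 1.17, p = 4.6e-49
```

Cells that spike reproducibly to cosine injections have low jitter (the
r = −0.98 pair), and the older-stage group — generated with broader
parameter distributions — shows a measurably larger 33-dimensional cloud,
the package's core variability analysis. All artifacts (feature matrix,
correlation/FDR tables, PCA loadings/scores, group statistics, distance
matrices, a JSON manifest) are written under `out_dir`.

## Documentation

The methods vignette (`vignettes/census-methods.Rmd`) describes the
generative model behind the simulators, every fit formula and its derived
quantities, the numerical choices (windows, thresholds, multi-start
fitting, convergence tolerances), and what passing the synthetic-data
tests does and does not establish about real recordings.
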