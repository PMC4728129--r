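Package: ephyscensus
Title: Electrophysiological Census of Neuronal Phenotypes: Simulation,
    Feature Extraction and Multivariate Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for large-scale whole-cell patch-clamp censuses of
    neuronal populations, modelled on developing Xenopus tectal neurons.
    Simulates protocol-faithful recordings (voltage-clamp IV steps,
    current-clamp step and cosine injections, paired-pulse synaptic
    stimulation, spontaneous mEPSC traces) with known ground truth;
    extracts a canonical set of 33 electrophysiological variables via
    sigmoid/hinge IV-curve fits, difference-of-exponential tuning fits and
    a spike-timing jitter index; and analyses the resulting feature
    matrices with pairwise correlations under false-discovery-rate
    control, principal-variable rankings, probabilistic PCA with missing
    values followed by promax rotation, Gaussian chained-equation multiple
    imputation with cloud-geometry and agglomerative-clustering summaries,
    Victor-Purpura spike-train distances with classical multidimensional
    scaling, group comparisons with effect sizes, and sequential
    regression variance partitioning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
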