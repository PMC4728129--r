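#' Ground-truth biophysical parameters for a simulated cell
#'
#' Bundles every generative parameter used by the protocol simulators. The
#' fields mirror the quantities the extraction stage tries to recover:
#' passive membrane properties, IV-curve activation/maximum parameters for
#' the three voltage-gated currents, spiking scale and adaptation, spike
#' waveform geometry, short-term synaptic dynamics, and spontaneous-event
#' statistics. All potentials are mV, currents pA, times ms, capacitance pF,
#' resistances GOhm (membrane) and MOhm (access).
#'
#' @param cm Membrane capacitance (pF), > 0.
#' @param rm Membrane resistance (GOhm), > 0. The membrane time constant
#'   used for subthreshold charging and the repolarization tail is
#'   `rm * cm` (GOhm x pF = ms).
#' @param ra Access resistance (MOhm).
#' @param e_rest Resting potential (mV); the holding current needed to keep
#'   the membrane at -65 mV is `(-65 - e_rest) / rm` (pA).
#' @param na_act,na_max Half-activation potential (mV) and peak amplitude
#'   (pA, <= 0) of the transient sodium current.
#' @param ks_act,ks_max First activation potential (mV) and maximal
#'   amplitude (pA, >= 0) of the stable (steady-state) potassium current.
#' @param kt_act,kt_max Half-activation potential (mV) and maximal
#'   amplitude (pA, >= 0) of the transient potassium current.
#' @param spike_gain Overall spiking scale: the amplitude parameter of the
#'   difference-of-exponentials current tuning curve (spikes).
#' @param spike_adapt Spike-frequency adaptation constant (ms): successive
#'   inter-spike intervals grow geometrically by `1 + isi0 / spike_adapt`.
#' @param spike_thresh Spike threshold (kink) potential (mV).
#' @param spike_amp First-spike amplitude above threshold (mV).
#' @param spike_rise First-spike 10--90\% rise time (ms).
#' @param spike_width First-spike width at half-height (ms).
#' @param res_period Preferred cosine-injection period (ms): the argmax of
#'   the generative period tuning curve.
#' @param res_width Build-up time constant (ms) of the period tuning curve
#'   (its slow exponential parameter).
#' @param wave_decay Within-bout adaptation constant (waves) at the highest
#'   cosine frequency; the generative per-wave envelope peaks at wave
#'   `wave_decay`.
#' @param spike_jitter Across-sweep SD of spike timing (ms) for stochastic
#'   cells.
#' @param syn_amp Unitary evoked synaptic charge (pA s).
#' @param syn_facil,syn_tau Facilitation increment per preceding stimulus
#'   and its decay time constant (ms).
#' @param syn_dep,syn_tau_dep Short-ISI depression weight and its decay
#'   time constant (ms); depression is what makes the charge-vs-ISI curve
#'   peak at intermediate intervals.
#' @param poly_amp Peak amplitude (pA) of the delayed polysynaptic
#'   (recurrent) response component.
#' @param mini_rate Spontaneous EPSC rate (Hz), >= 0.
#' @param mini_amp Mean spontaneous EPSC amplitude (pA).
#' @param noise_sd Additive Gaussian noise SD (pA in voltage clamp, mV in
#'   current clamp). Zero gives fully deterministic traces.
#' @param seed Integer seed attached to the cell; simulators use it.
#'
#' @return An object of class `cell_params` (a named list).
#' @export
cell_params <- function(cm = 12, rm = 2, ra = 25, e_rest = -49,
                        na_act = -35, na_max = -400,
                        ks_act = -20, ks_max = 350,
                        kt_act = -25, kt_max = 250,
                        spike_gain = 8, spike_adapt = 60,
                        spike_thresh = -40,
                        spike_amp = 60, spike_rise = 0.4, spike_width = 1.5,
                        res_period = 40, res_width = 55, wave_decay = 4,
                        spike_jitter = 1,
                        syn_amp = 0.25, syn_facil = 0.8, syn_tau = 80,
                        syn_dep = 1.2, syn_tau_dep = 12, poly_amp = 4,
                        mini_rate = 1, mini_amp = 12,
                        noise_sd = 2, seed = 1L) {
  p <- list(cm = cm, rm = rm, ra = ra, e_rest = e_rest,
            na_act = na_act, na_max = na_max,
            ks_act = ks_act, ks_max = ks_max,
            kt_act = kt_act, kt_max = kt_max,
            spike_gain = spike_gain, spike_adapt = spike_adapt,
            spike_thresh = spike_thresh,
            spike_amp = spike_amp, spike_rise = spike_rise,
            spike_width = spike_width,
            res_period = res_period, res_width = res_width,
            wave_decay = wave_decay, spike_jitter = spike_jitter,
            syn_amp = syn_amp, syn_facil = syn_facil, syn_tau = syn_tau,
            syn_dep = syn_dep, syn_tau_dep = syn_tau_dep,
            poly_amp = poly_amp,
            mini_rate = mini_rate, mini_amp = mini_amp,
            noise_sd = noise_sd, seed = as.integer(seed))
  stopifnot(p$cm > 0, p$rm > 0, p$na_max <= 0, p$ks_max >= 0,
            p$kt_max >= 0, p$mini_rate >= 0, p$noise_sd >= 0)
  class(p) <- "cell_params"
  p
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params> Cm", x$cm, "pF, Rm", x$rm, "GOhm, threshold",
      x$spike_thresh, "mV, gain", x$spike_gain, "\n")
  invisible(x)
}

stage_levels <- c("s43_44", "s45_46", "s47", "s48_49")
condition_levels <- c("naive", "stimulated")

# Group-level parameter distributions (mean, sd) for each cell_params field.
# The defaults are configuration, not estimates of the real animals: they
# encode the qualitative directions of developmental change (excitability
# rising to a transient peak, then broadening variability at the oldest
# stages) and of sensory stimulation (more step spiking, less cell-to-cell
# variability).
default_group_distributions <- function() {
  base_mean <- unlist(cell_params(seed = 0L)[
    c("cm", "rm", "ra", "e_rest", "na_act", "na_max", "ks_act", "ks_max",
      "kt_act", "kt_max", "spike_gain", "spike_adapt", "spike_thresh",
      "spike_amp", "spike_rise", "spike_width", "res_period", "res_width",
      "wave_decay", "spike_jitter", "syn_amp", "syn_facil", "syn_tau",
      "syn_dep", "syn_tau_dep", "poly_amp", "mini_rate", "mini_amp",
      "noise_sd")])
  base_sd <- abs(base_mean) * 0.15
  base_sd["e_rest"] <- 6; base_sd["na_act"] <- 3; base_sd["ks_act"] <- 3
  base_sd["kt_act"] <- 3; base_sd["spike_thresh"] <- 2.5
  base_sd["noise_sd"] <- 0
  groups <- list()
  for (st in stage_levels) for (cd in condition_levels) {
    m <- base_mean; s <- base_sd
    scale_gain <- switch(st, s43_44 = 0.5, s45_46 = 0.8, s47 = 1.6,
                         s48_49 = 1.0)
    m["spike_gain"] <- base_mean["spike_gain"] * scale_gain
    if (st == "s48_49") s <- s * 1.35          # older cells more diverse
    if (st == "s43_44") s <- s * 0.8
    if (cd == "stimulated") {
      m["spike_gain"] <- m["spike_gain"] * 1.5 # stimulation: spikier ...
      m["cm"] <- m["cm"] * 0.85
      s <- s * 0.75                            # ... but less variable
    }
    groups[[paste(st, cd, sep = ".")]] <- list(mean = m, sd = s)
  }
  groups
}

#' Draw ground-truth parameters for one cell of a given group
#'
#' Samples each `cell_params` field from the configured per-group Gaussian
#' distribution (truncated where sign constraints apply). Deterministic
#' given `(stage_group, condition, seed)`.
#'
#' @param stage_group One of `"s43_44"`, `"s45_46"`, `"s47"`, `"s48_49"`.
#' @param condition `"naive"` or `"stimulated"`.
#' @param seed Integer seed for this draw.
#' @param distributions Optional list as produced by
#'   `default_group_distributions()`; entries named `"<stage>.<condition>"`
#'   with `mean` and `sd` vectors.
#' @return A `cell_params` object with `seed` set.
#' @export
make_cell_params <- function(stage_group, condition, seed,
                             distributions = default_group_distributions()) {
  stage_group <- match.arg(stage_group, stage_levels)
  condition <- match.arg(condition, condition_levels)
  key <- paste(stage_group, condition, sep = ".")
  d <- distributions[[key]]
  if (is.null(d)) stop("no parameter distribution configured for ", key)
  draw <- local_rng(seed, {
    v <- stats::rnorm(length(d$mean), d$mean, d$sd)
    names(v) <- names(d$mean)
    v
  })
  # enforce sign invariants without re-drawing
  pos <- c("cm", "rm", "ra", "ks_max", "kt_max", "spike_gain",
           "spike_adapt", "spike_amp", "spike_rise", "spike_width",
           "res_period", "res_width", "wave_decay", "spike_jitter",
           "syn_amp", "syn_tau", "syn_tau_dep", "mini_rate", "mini_amp",
           "poly_amp", "syn_dep", "syn_facil", "spike_jitter")
  draw[pos] <- pmax(draw[pos], abs(d$mean[pos]) * 0.05)
  draw["na_max"] <- min(draw["na_max"], 0)
  draw["noise_sd"] <- max(draw["noise_sd"], 0)
  # keep spike geometry fittable (fall phase must be positive)
  draw["spike_width"] <- max(draw["spike_width"],
                             draw["spike_rise"] / 0.5904 * 0.6)
  args <- as.list(draw)
  args$seed <- as.integer(seed)
  do.call(cell_params, args)
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards. All simulator randomness goes through this.
local_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Cohort design for the synthetic census
#'
#' @param n_cells Named integer vector; names are `"<stage>.<condition>"`
#'   keys (e.g. `"s45_46.naive"`), values are cell counts.
#' @param missing_rate Fraction of feature-matrix entries to mask
#'   completely at random downstream, in `[0, 1)`.
#' @param distributions Per-group parameter distributions (see
#'   [make_cell_params()]).
#' @param spont_duration_s Length of the spontaneous recording (s).
#' @param seed Master seed; per-cell seeds are derived from it.
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(n_cells = c(s45_46.naive = 64, s48_49.naive = 56,
                                      s48_49.stimulated = 60),
                          missing_rate = 0.18,
                          distributions = default_group_distributions(),
                          spont_duration_s = 60,
                          seed = 1L) {
  stopifnot(all(n_cells >= 0), missing_rate >= 0, missing_rate < 1)
  structure(list(n_cells = n_cells, missing_rate = missing_rate,
                 distributions = distributions,
                 spont_duration_s = spont_duration_s,
                 seed = as.integer(seed)),
            class = "cohort_design")
}
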