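# Protocol simulators. All traces are sampled at 10 kHz. Voltage-clamp
# protocols yield currents in pA (passive component already subtracted, as
# for real data after leak subtraction); current-clamp protocols yield
# membrane potential in mV. A cell with noise_sd == 0 is fully
# deterministic: no Poisson draws, no timing jitter, bit-identical sweeps.

FS_HZ <- 10000
MS_PER_SAMPLE <- 1000 / FS_HZ

IV_POTENTIALS <- seq(-65, 115, by = 20)      # mV command steps
STEP_CURRENTS <- seq(0, 180, by = 20)        # pA injections
COSINE_PERIODS <- c(10, 20, 100 / 3, 40, 50) # ms (100, 50, 30, 25, 20 Hz)
SYNAPTIC_ISIS <- c(10, 20, 30, 40, 50, 100, 150, 200, 250, 300) # ms

# --- generative curve families (shared with the fitting stage oracles) ----

#' Canonical sigmoid IV curve
#'
#' `I(v) = c / (1 + exp(-(v - a)/b)) + d`: half of the asymptotic amplitude
#' is reached at `v = a`. Used generatively for the transient sodium and
#' transient potassium currents and as the model the extraction stage fits.
#' @param v Potential (mV). @param a,b,c,d Parameters.
#' @return Current (pA).
#' @export
iv_sigmoid_curve <- function(v, a, b, c, d = 0) {
  c / (1 + exp(-(v - a) / b)) + d
}

#' Hinged exponential IV curve for the stable potassium current
#'
#' `I(v) = max(0, exp((v - a)/b) - e) * c + d`, with `e` Euler's constant,
#' so the current first activates at `v = a + b`.
#' @param v Potential (mV). @param a,b,c,d Parameters.
#' @export
iv_hinge_curve <- function(v, a, b, c, d = 0) {
  pmax(0, exp((v - a) / b) - exp(1)) * c + d
}

#' Difference-of-exponentials tuning curve
#'
#' `f(x) = max(0, exp(-(x - a)/b) - exp(-(x - a)/c)) * d` with `b > c`.
#' Its argmax is `a + b c log(b/c) / (b - c)`. Used for spikes-vs-current
#' and spikes-vs-cosine-period tuning.
#' @param x Abscissa (pA or ms). @param a,b,c,d Parameters.
#' @export
diffexp_curve <- function(x, a, b, c, d) {
  pmax(0, exp(-(x - a) / b) - exp(-(x - a) / c)) * d
}

#' Analytic argmax of the difference-of-exponentials curve
#' @param a,b,c Parameters (`b != c`).
#' @export
diffexp_argmax <- function(a, b, c) a + b * c * log(b / c) / (b - c)

#' Linear-times-exponential transient curve
#'
#' `f(x) = (x - a) * exp(-(x - b)/c) * d + e`; argmax at `x = a + c`. Used
#' for per-wave spike counts and the synaptic charge-vs-ISI curve.
#' @param x Abscissa. @param a,b,c,d,e Parameters.
#' @export
linexp_curve <- function(x, a, b, c, d, e = 0) {
  (x - a) * exp(-(x - b) / c) * d + e
}

# --- per-cell generative ground truth ------------------------------------

# spike count vs injected current: a fixed onset/shape with amplitude
# spike_gain, so 'I best' has a closed form independent of the cell.
STEP_TUNING_A <- 10; STEP_TUNING_B <- 300; STEP_TUNING_C <- 60

step_count_model <- function(params, current) {
  diffexp_curve(current, STEP_TUNING_A, STEP_TUNING_B, STEP_TUNING_C,
                params$spike_gain)
}

# spikes per cosine bout as a function of wave period. The curve's onset
# is pinned at zero period (cells do spike at 100 Hz) and the fast
# constant c is solved so the argmax lands at res_period; this requires
# res_period < res_width, else c is clamped near b. The amplitude is
# 6 x spike_gain: bouts carry enough spikes that integer counts resolve
# the tuning curve.
cosine_tuning_model <- function(params, period) {
  b <- params$res_width
  target <- min(params$res_period, 0.975 * b)
  f <- function(cc) b * cc * log(b / cc) / (b - cc) - target
  c <- tryCatch(stats::uniroot(f, c(1e-3 * b, 0.999 * b))$root,
                error = function(e) 0.95 * b)
  diffexp_curve(period, 0, b, c, 6 * params$spike_gain)
}

# within-bout envelope at the highest cosine frequency: weight of wave x,
# peaking at wave_decay waves.
wave_envelope_model <- function(params, x) {
  pmax(0, x) * exp(-x / params$wave_decay)
}

# facilitation/depression state before stimulus k of a 5-shock train
syn_gain_seq <- function(params, isi) {
  k <- 1:5
  fac <- dep <- numeric(5)
  for (i in k) {
    prev <- seq_len(i - 1)
    fac[i] <- 1 + params$syn_facil * sum(exp(-(i - prev) * isi / params$syn_tau))
    dep[i] <- 1 / (1 + params$syn_dep *
                     sum(exp(-(i - prev) * isi / params$syn_tau_dep)))
  }
  fac * dep
}

# total evoked charge (pA s) for a 5-shock train at a given ISI, including
# the polysynaptic hump (81.55 pA ms per unit poly_amp per shock).
POLY_ONSET <- 15; POLY_TAU <- 30  # ms
syn_charge_model <- function(params, isi) {
  vapply(isi, function(ii) {
    mono <- sum(syn_gain_seq(params, ii)) * params$syn_amp
    poly <- 5 * params$poly_amp * POLY_TAU * exp(1) / 1000
    mono + poly
  }, numeric(1))
}

# --- spike waveform -------------------------------------------------------

# Raised-cosine rise (duration R) then raised-cosine fall (duration F),
# starting exactly at the kink/threshold level. Closed forms used by the
# round-trip tests: 10-90% rise time = 0.5904 R; width at the level midway
# between kink and peak = (R + F)/2.
RISE_1090_FACTOR <- (acos(-0.8) - acos(0.8)) / pi

spike_waveform <- function(amp, rise_1090, half_width) {
  R <- rise_1090 / RISE_1090_FACTOR
  F <- max(2 * half_width - R, 0.2)
  # sample the continuous waveform at exact sample times so the closed
  # forms above hold to sub-sample precision after interpolation
  t <- seq(MS_PER_SAMPLE, R + F, by = MS_PER_SAMPLE)
  amp * ifelse(t <= R, (1 - cos(pi * t / R)) / 2,
               (1 + cos(pi * (t - R) / F)) / 2)
}

add_spike <- function(trace, at_sample, wave, floor_level) {
  idx <- at_sample + seq_along(wave) - 1L
  keep <- idx >= 1L & idx <= length(trace)
  trace[idx[keep]] <- pmax(trace[idx[keep]], floor_level + wave[keep])
  trace
}

# deterministic "error diffusion" integerization of expected counts
diffuse_counts <- function(expected) {
  cum <- cumsum(expected)
  diff(c(0L, floor(cum + 1e-9)))
}

new_recording <- function(protocol, sweeps, stimulus, params,
                          cell_id = "cell", stage_group = "s48_49",
                          condition = "naive") {
  stopifnot(is.matrix(sweeps), nrow(stimulus) == ncol(sweeps))
  structure(list(protocol = protocol, fs = FS_HZ, sweeps = sweeps,
                 stimulus = stimulus, cell_id = cell_id,
                 stage_group = stage_group, condition = condition,
                 params = params),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording>", x$protocol, ":", ncol(x$sweeps), "sweeps x",
      nrow(x$sweeps), "samples @", x$fs, "Hz\n")
  invisible(x)
}

# --- simulators -----------------------------------------------------------

#' Simulate the voltage-clamp IV step protocol
#'
#' One 150 ms sweep per command potential from -65 to +115 mV in 20 mV
#' increments (the printed +115 mV endpoint is unusually depolarized for a
#' physiological command but is followed as specified for the protocol).
#' The active current is built directly from the generative IV curve
#' families: a brief sodium transient (Gaussian envelope peaking 2 ms after
#' the step), a stable potassium current reaching steady state by 10 ms,
#' and a transient potassium component peaking at 10 ms and decaying with a
#' 15 ms constant, plus white noise. The passive component is treated as
#' already subtracted.
#'
#' @param params A [cell_params()] object.
#' @param seed Seed for the noise (defaults to the cell's own seed).
#' @return A `recording` with `protocol = "iv_steps"`; sweeps are currents
#'   in pA.
#' @export
simulate_iv_protocol <- function(params, seed = params$seed) {
  n <- 1500L
  t <- (seq_len(n) - 1L) * MS_PER_SAMPLE
  g_na <- exp(-(t - 2)^2 / (2 * 0.5^2))
  s_ks <- pmin(1, pmax(0, (t - 4) / 6))
  g_kt <- ifelse(t < 4, 0,
                 ifelse(t <= 10, (t - 4) / 6, exp(-(t - 10) / 15)))
  sweeps <- local_rng(seed, {
    vapply(IV_POTENTIALS, function(v) {
      i_na <- iv_sigmoid_curve(v, params$na_act, 6, params$na_max)
      i_ks <- iv_hinge_curve(v, params$ks_act - 35, 35,
                             ks_hinge_scale(params))
      i_kt <- iv_sigmoid_curve(v, params$kt_act, 8, params$kt_max)
      tr <- i_na * g_na + i_ks * s_ks + i_kt * g_kt
      if (params$noise_sd > 0) tr <- tr + stats::rnorm(n, 0, params$noise_sd)
      tr
    }, numeric(n))
  })
  new_recording("iv_steps", sweeps,
                data.frame(command_mV = IV_POTENTIALS), params)
}

# scale of the hinge curve chosen so the stable-K current reaches ks_max at
# the most depolarized command (+115 mV)
ks_hinge_scale <- function(params) {
  a <- params$ks_act - 35
  denom <- exp((115 - a) / 35) - exp(1)
  if (denom <= 0) 0 else params$ks_max / denom
}

# deterministic spike times for a step injection of a given expected count
step_spike_times <- function(params, n_spikes, onset_ms) {
  if (n_spikes < 1) return(numeric(0))
  isi0 <- 15
  g <- 1 + isi0 / params$spike_adapt
  isis <- isi0 * g^(seq_len(max(n_spikes - 1, 0)) - 1)
  onset_ms + 15 + c(0, cumsum(isis))
}

#' Simulate the current-clamp step injection protocol
#'
#' Ten 600 ms sweeps with 300 ms square current pulses of 0--180 pA in
#' 20 pA increments, starting 100 ms into the sweep. The per-sweep spike
#' count follows the generative difference-of-exponentials tuning
#' `ns(i)` with amplitude `spike_gain`; spikes ride on a subthreshold
#' potential that charges toward the threshold with the membrane time
#' constant `rm * cm`, and the post-pulse repolarization decays
#' exponentially with the same constant (the ground truth for the tail
#' fit). Spike amplitudes decay by a fixed factor of 0.9 per spike, giving
#' a known amplitude-accommodation ratio.
#'
#' @inheritParams simulate_iv_protocol
#' @return A `recording` with `protocol = "current_steps"`; sweeps in mV.
#' @export
simulate_step_protocol <- function(params, seed = params$seed) {
  n <- 6000L; onset <- 100; offset <- 400
  t <- (seq_len(n) - 1L) * MS_PER_SAMPLE
  tau_m <- params$rm * params$cm
  expected <- step_count_model(params, STEP_CURRENTS)
  sweeps <- local_rng(seed, {
    counts <- if (params$noise_sd == 0) round(expected + 1e-9)
              else stats::rpois(length(expected), expected)
    counts[STEP_CURRENTS == 0] <- 0L
    vapply(seq_along(STEP_CURRENTS), function(k) {
      i_inj <- STEP_CURRENTS[k]
      spiking <- counts[k] >= 1
      # spiking sweeps are driven to the threshold potential with a fast
      # (active) time constant so the kink of every spike sits at
      # spike_thresh; subthreshold sweeps charge passively with rm * cm
      depol <- if (spiking) params$spike_thresh + 65
               else min(i_inj * params$rm, params$spike_thresh + 63)
      tau_chg <- if (spiking) 3 else tau_m
      v <- rep(-65, n)
      during <- t >= onset & t < offset
      v[during] <- -65 + depol * (1 - exp(-(t[during] - onset) / tau_chg))
      after <- t >= offset
      v_off <- -65 + depol * (1 - exp(-(offset - onset) / tau_chg))
      v[after] <- -65 + (v_off + 65) * exp(-(t[after] - offset) / tau_m)
      times <- step_spike_times(params, counts[k], onset)
      if (params$noise_sd > 0 && length(times))
        times <- sort(times + stats::rnorm(length(times), 0,
                                           params$spike_jitter))
      times <- times[times < offset - 5]
      if (length(times)) {
        amps <- params$spike_amp * 0.9^(seq_along(times) - 1L)
        for (j in seq_along(times)) {
          wave <- spike_waveform(amps[j], params$spike_rise,
                                 params$spike_width)
          v <- add_spike(v, round(times[j] / MS_PER_SAMPLE) + 1L, wave,
                         params$spike_thresh)
        }
      }
      if (params$noise_sd > 0) v <- v + stats::rnorm(n, 0, params$noise_sd)
      v
    }, numeric(n))
  })
  new_recording("current_steps", sweeps,
                data.frame(current_pA = STEP_CURRENTS,
                           onset_ms = onset, offset_ms = offset), params)
}

#' Simulate the cosine-injection resonance protocol
#'
#' Ten repeated sweeps, each containing five 200 ms bouts of cosine current
#' injection at 100, 50, 30, 25 and 20 Hz (peak amplitude 135 pA by
#' protocol), separated by 100 ms rests. The expected number of spikes per
#' bout follows the generative period tuning curve peaking at
#' `res_period`; within the 100 Hz bout, spikes are distributed over waves
#' according to a rise-and-decay envelope peaking at wave `wave_decay`.
#' Deterministic cells emit identical sweeps; stochastic cells draw
#' per-wave Poisson counts and jitter spike times by `spike_jitter`.
#'
#' @inheritParams simulate_iv_protocol
#' @return A `recording` with `protocol = "cosine"`; sweeps in mV. The
#'   stimulus table records bout onsets and periods for the common layout.
#' @export
simulate_cosine_protocol <- function(params, seed = params$seed) {
  bout_ms <- 200; gap_ms <- 100; pre_ms <- 100
  bout_on <- pre_ms + (seq_along(COSINE_PERIODS) - 1L) * (bout_ms + gap_ms)
  n <- round((pre_ms + 5 * bout_ms + 4 * gap_ms + 100) / MS_PER_SAMPLE)
  t <- (seq_len(n) - 1L) * MS_PER_SAMPLE
  ripple <- rep(0, n)
  for (b in seq_along(COSINE_PERIODS)) {
    inb <- t >= bout_on[b] & t < bout_on[b] + bout_ms
    ripple[inb] <- 5 * (1 - cos(2 * pi * (t[inb] - bout_on[b]) /
                                  COSINE_PERIODS[b])) / 2
  }
  lambda_bout <- cosine_tuning_model(params, COSINE_PERIODS)
  sweeps <- local_rng(seed, {
    vapply(1:10, function(sw) {
      v <- -65 + ripple
      for (b in seq_along(COSINE_PERIODS)) {
        Tb <- COSINE_PERIODS[b]
        waves <- seq_len(floor(bout_ms / Tb))
        w <- wave_envelope_model(params, waves)
        e_x <- lambda_bout[b] * w / sum(w)
        cnt <- if (params$noise_sd == 0) diffuse_counts(e_x)
               else stats::rpois(length(e_x), e_x)
        for (x in waves) {
          if (cnt[x] < 1) next
          base_t <- bout_on[b] + (x - 0.5) * Tb
          st <- base_t + (seq_len(cnt[x]) - 1L) * 3
          if (params$noise_sd > 0)
            st <- st + stats::rnorm(length(st), 0, params$spike_jitter)
          for (s1 in st) {
            wave <- spike_waveform(params$spike_amp, params$spike_rise,
                                   params$spike_width)
            v <- add_spike(v, round(s1 / MS_PER_SAMPLE) + 1L, wave,
                           params$spike_thresh)
          }
        }
      }
      if (params$noise_sd > 0) v <- v + stats::rnorm(n, 0, params$noise_sd)
      v
    }, numeric(n))
  })
  new_recording("cosine", sweeps,
                data.frame(sweep = 1:10,
                           bout_onsets_ms = I(rep(list(bout_on), 10)),
                           periods_ms = I(rep(list(COSINE_PERIODS), 10))),
                params)
}

#' Simulate the paired-pulse synaptic stimulation protocol
#'
#' Five shocks per sweep at each of ten inter-stimulus intervals (10--50,
#' 100--300 ms), each condition repeated five times (50 sweeps). Every
#' shock produces a 1 ms biphasic stimulation artifact, an evoked EPSC
#' (alpha-shaped, onset 5.5 ms, time constant 1.8 ms) whose charge follows
#' the facilitation/depression model, and a delayed polysynaptic hump
#' (15--145 ms window). Currents are positive-going (magnitudes).
#'
#' @inheritParams simulate_iv_protocol
#' @return A `recording` with `protocol = "synaptic"`; sweeps in pA.
#' @export
simulate_synaptic_protocol <- function(params, seed = params$seed) {
  pre_ms <- 100
  n <- round((pre_ms + 4 * max(SYNAPTIC_ISIS) + 400) / MS_PER_SAMPLE)
  t <- (seq_len(n) - 1L) * MS_PER_SAMPLE
  tau_s <- 1.8; onset_lat <- 5.5
  design <- expand.grid(repeat_id = 1:5, isi_ms = SYNAPTIC_ISIS)
  sweeps <- local_rng(seed, {
    vapply(seq_len(nrow(design)), function(r) {
      isi <- design$isi_ms[r]
      stim_t <- pre_ms + (0:4) * isi
      gains <- syn_gain_seq(params, isi)
      tr <- rep(0, n)
      for (k in 1:5) {
        dt <- t - stim_t[k]
        art <- dt >= 0 & dt < 1
        tr[art] <- tr[art] + 2000 * ifelse(dt[art] < 0.5, 1, -1)
        u <- dt - onset_lat
        epsc <- ifelse(u > 0, u / tau_s^2 * exp(-u / tau_s), 0)
        q_ms <- gains[k] * params$syn_amp * 1000   # pA ms
        up <- dt - POLY_ONSET
        poly <- ifelse(up > 0, params$poly_amp * (up / POLY_TAU) *
                         exp(1 - up / POLY_TAU), 0)
        tr <- tr + q_ms * epsc + poly
      }
      if (params$noise_sd > 0) tr <- tr + stats::rnorm(n, 0, params$noise_sd)
      tr
    }, numeric(n))
  })
  new_recording("synaptic", sweeps,
                data.frame(design,
                           first_stim_ms = pre_ms), params)
}

#' Simulate the one-minute spontaneous recording
#'
#' A voltage-clamp trace with Poisson-timed alpha-shaped EPSC events of
#' mean peak amplitude `mini_amp` (10\% amplitude scatter) over Gaussian
#' noise. A `mini_rate` of zero yields pure noise.
#'
#' @inheritParams simulate_iv_protocol
#' @param duration_s Trace duration in seconds (protocol default 60).
#' @return A `recording` with `protocol = "spontaneous"`; one sweep in pA.
#' @export
simulate_spontaneous <- function(params, seed = params$seed,
                                 duration_s = 60) {
  n <- round(duration_s * FS_HZ)
  tau <- 2 # ms; alpha kernel peaks at t = tau with value 1
  kern_t <- seq(0, 20, by = MS_PER_SAMPLE)
  kern <- (kern_t / tau) * exp(1 - kern_t / tau)
  tr <- local_rng(seed + 7L, {
    x <- if (params$noise_sd > 0) stats::rnorm(n, 0, params$noise_sd)
         else rep(0, n)
    n_ev <- stats::rpois(1, params$mini_rate * duration_s)
    if (n_ev > 0) {
      at <- sort(sample.int(n - length(kern), n_ev, replace = TRUE))
      amps <- params$mini_amp * pmax(0.2, 1 + stats::rnorm(n_ev, 0, 0.1))
      for (j in seq_len(n_ev)) {
        idx <- at[j] + seq_along(kern) - 1L
        x[idx] <- x[idx] + amps[j] * kern
      }
      attr(x, "event_samples") <- at
    }
    x
  })
  ev <- attr(tr, "event_samples"); attributes(tr) <- NULL
  rec <- new_recording("spontaneous", matrix(tr, ncol = 1),
                       data.frame(duration_s = duration_s), params)
  rec$event_samples <- ev
  rec
}

#' Simulate all five protocols for one cell
#'
#' @param params A [cell_params()] object.
#' @param cell_id Identifier attached to each recording.
#' @param stage_group,condition Group labels.
#' @param spont_duration_s Spontaneous-trace duration (s).
#' @param protocols Subset of protocols to simulate.
#' @return Named list of `recording` objects.
#' @export
simulate_cell <- function(params, cell_id = "cell",
                          stage_group = "s48_49", condition = "naive",
                          spont_duration_s = 60,
                          protocols = c("iv_steps", "current_steps",
                                        "cosine", "synaptic",
                                        "spontaneous")) {
  out <- list()
  if ("iv_steps" %in% protocols)
    out$iv_steps <- simulate_iv_protocol(params)
  if ("current_steps" %in% protocols)
    out$current_steps <- simulate_step_protocol(params, params$seed + 1L)
  if ("cosine" %in% protocols)
    out$cosine <- simulate_cosine_protocol(params, params$seed + 2L)
  if ("synaptic" %in% protocols)
    out$synaptic <- simulate_synaptic_protocol(params, params$seed + 3L)
  if ("spontaneous" %in% protocols)
    out$spontaneous <- simulate_spontaneous(params, params$seed + 4L,
                                            spont_duration_s)
  for (nm in names(out)) {
    out[[nm]]$cell_id <- cell_id
    out[[nm]]$stage_group <- stage_group
    out[[nm]]$condition <- condition
  }
  out
}
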