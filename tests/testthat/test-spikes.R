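# Spike detection and shape measurement.

test_that("detection ignores flat traces and subthreshold bumps", {
  flat <- rep(-65, 5000)
  expect_length(detect_spikes(flat)$times, 0)
  bumps <- flat + 2 * sin(seq(0, 20 * pi, length.out = 5000))
  expect_length(detect_spikes(bumps)$times, 0)
  expect_error(detect_spikes(c(flat, NA)))
})

test_that("injected waveforms are found at their true peaks", {
  tr <- rep(-65, 10000)
  at <- c(100, 250, 400, 550, 700)
  for (a in at) tr <- inject_spike(tr, a, amp = 60)
  st <- detect_spikes(tr)
  expect_length(st$times, 5)
  # generator peak = onset + rise duration
  rise_dur <- 0.4 / ephyscensus:::RISE_1090_FACTOR
  expect_true(all(abs(st$times - (at + rise_dur)) < 0.2))
})

test_that("shape metrics match closed forms", {
  # triangular spike: kink -40 mV, peak +10 mV -> amplitude 50
  tr <- rep(-40, 2000)
  up <- seq(-40, 10, length.out = 21); dn <- seq(10, -40, length.out = 41)
  tr[1000:1020] <- up; tr[1020:1060] <- dn
  s <- spike_shape(tr, (1020 - 1) * 0.1)
  expect_equal(unname(s["amplitude"]), 50, tolerance = 0.05)

  # Gaussian spike, sigma = 0.5 ms: kink sits at -sqrt(3) sigma, so the
  # width at the level midway between kink and peak has a closed form
  sigma <- 0.5; t <- seq(0, 100, by = 0.1); A <- 60
  g <- -65 + A * exp(-(t - 50)^2 / (2 * sigma^2))
  s <- spike_shape(g, 50)
  kink_frac <- exp(-3 / 2)             # value at the 2nd-derivative max
  lvl <- (kink_frac + 1) / 2           # midway kink -> peak, as fraction
  width_true <- 2 * sigma * sqrt(2 * log(1 / lvl))
  expect_equal(unname(s["width"]), width_true, tolerance = 0.05 * width_true)

  # generator waveform: known 10-90% rise time and half-height width,
  # rising from the -65 mV baseline
  tr <- rep(-65, 2000)
  tr <- inject_spike(tr, 50, amp = 60, rise_1090 = 0.4, width = 1.5)
  st <- detect_spikes(tr)
  expect_lt(abs(st$rise[1] - 0.4), 0.05)
  expect_lt(abs(st$width[1] - 1.5), 0.1)
  # kink potential is quantized by the 0.1 ms sampling of a 0.4 ms rise:
  # the first on-rise sample sits ~3 mV above the true initiation point
  expect_lt(abs(st$kink[1] - (-65)), 3.5)
  expect_lt(abs(st$amplitude[1] - 60), 3.5)
})

test_that("detection F1 is at least 0.95 at SNR 5", {
  set.seed(31)
  f1s <- replicate(10, {
    tr <- rep(-65, 20000) + rnorm(20000, 0, 12)  # amplitude 60 / SD 12
    at <- sort(sample(seq(50, 1900, by = 10), 12))
    at <- at[c(TRUE, diff(at) > 10)]
    for (a in at) tr <- inject_spike(tr, a, amp = 60)
    st <- detect_spikes(tr)
    tp <- sum(vapply(at, function(a)
      any(abs(st$times - a) < 3), logical(1)))
    prec <- if (length(st$times)) tp / length(st$times) else 0
    rec <- tp / length(at)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  })
  expect_gte(mean(f1s), 0.95)
})
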