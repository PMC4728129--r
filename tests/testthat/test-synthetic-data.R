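# The protocol simulators and cohort generation: determinism, protocol
# fidelity, and parameter recovery on noiseless cells.

test_that("cell parameter draws are deterministic and track configured SDs", {
  p1 <- make_cell_params("s48_49", "naive", 7)
  p2 <- make_cell_params("s48_49", "naive", 7)
  expect_identical(p1, p2)
  p3 <- make_cell_params("s48_49", "naive", 8)
  expect_false(identical(p1[names(p1) != "seed"], p3[names(p3) != "seed"]))

  draws <- vapply(1:500, function(s)
    make_cell_params("s48_49", "naive", s)$na_max, numeric(1))
  dists <- default_group_distributions()
  cfg_sd <- dists[["s48_49.naive"]]$sd["na_max"]
  expect_lt(abs(sd(draws) - cfg_sd) / cfg_sd, 0.10)

  # zero-SD design: every cell identical apart from its seed
  dists0 <- dists
  dists0[["s48_49.naive"]]$sd[] <- 0
  q1 <- make_cell_params("s48_49", "naive", 1, dists0)
  q2 <- make_cell_params("s48_49", "naive", 2, dists0)
  expect_equal(q1[names(q1) != "seed"], q2[names(q2) != "seed"])

  expect_error(make_cell_params("s99", "naive", 1))
})

test_that("IV step protocol matches the command series and round-trips", {
  p <- cell_params(noise_sd = 0)
  rec <- simulate_iv_protocol(p)
  expect_equal(ncol(rec$sweeps), 10)  # -65 .. +115 in 20 mV steps
  expect_equal(rec$fs, 10000)
  expect_equal(rec$stimulus$command_mV, seq(-65, 115, by = 20))

  # no transient currents: early-window minimum is zero everywhere
  p0 <- cell_params(na_max = 0, kt_max = 0, noise_sd = 0)
  iv0 <- measure_iv_currents(simulate_iv_protocol(p0))
  expect_true(all(abs(iv0$i_na) < 1e-9))

  # noiseless sodium IV recovers the configured half-activation
  iv <- measure_iv_currents(rec)
  fit <- fit_iv_sigmoid(iv$command_mV, iv$i_na)
  expect_true(fit$converged)
  expect_lt(abs(fit$derived$half_activation - p$na_act), 0.5)
  expect_lt(abs(fit$derived$max_current - p$na_max) / abs(p$na_max), 0.02)
})

test_that("step protocol spiking follows the generative tuning", {
  p0 <- cell_params(spike_gain = 0, noise_sd = 0)
  rec0 <- simulate_step_protocol(p0)
  trains <- apply(rec0$sweeps, 2, detect_spikes, simplify = FALSE)
  expect_true(all(vapply(trains, function(tr) length(tr$times),
                         numeric(1)) == 0))

  p <- cell_params(noise_sd = 0)
  rec <- simulate_step_protocol(p)
  expect_equal(rec$stimulus$current_pA, seq(0, 180, by = 20))
  trains <- apply(rec$sweeps, 2, detect_spikes, simplify = FALSE)
  counts <- vapply(trains, function(tr) length(tr$times), numeric(1))
  expect_equal(counts[1], 0)  # 0 pA sweep never spikes
  fit <- fit_spikes_vs_current(rec$stimulus$current_pA, counts)
  i_best_true <- diffexp_argmax(10, 300, 60)
  expect_lt(abs(fit$derived$argmax - i_best_true), 20)
})

test_that("cosine protocol is deterministic without noise and resonant", {
  p <- cell_params(noise_sd = 0, spike_gain = 25)
  rec <- simulate_cosine_protocol(p)
  expect_equal(ncol(rec$sweeps), 10)
  expect_true(all(apply(rec$sweeps, 1, function(r) length(unique(r)) == 1)))
  # 100 Hz bout: 20 waves in 200 ms
  expect_equal(floor(200 / min(rec$stimulus$periods_ms[[1]])), 20)

  cf <- ephyscensus:::cosine_features(rec)
  expect_lt(abs(cf$resonance - p$res_period) / p$res_period, 0.15)
})

test_that("synaptic protocol has 50 sweeps and a known charge model", {
  p <- cell_params(noise_sd = 0)
  rec <- simulate_synaptic_protocol(p)
  expect_equal(ncol(rec$sweeps), 50)  # 10 ISIs x 5 repeats
  expect_setequal(unique(rec$stimulus$isi_ms),
                  c(10, 20, 30, 40, 50, 100, 150, 200, 250, 300))

  # facilitation and depression off: flat charge across ISIs
  pf <- cell_params(syn_facil = 0, syn_dep = 0, noise_sd = 0)
  qf <- synaptic_charge_curve(simulate_synaptic_protocol(pf))
  expect_lt(diff(range(qf$q_pAs)) / mean(qf$q_pAs), 0.05)

  # extracted charges track the generative model
  q <- synaptic_charge_curve(rec)
  q_true <- ephyscensus:::syn_charge_model(p, q$isi_ms)
  expect_lt(max(abs(q$q_pAs - q_true) / q_true), 0.1)

  # purely monosynaptic cell: window ratio far above 1
  pm <- cell_params(poly_amp = 0, noise_sd = 0)
  expect_gt(monosynapticity(simulate_synaptic_protocol(pm)), 10)
})

test_that("spontaneous recording has Poisson minis over noise", {
  p0 <- cell_params(mini_rate = 0, noise_sd = 2)
  sp0 <- simulate_spontaneous(p0)
  expect_equal(nrow(sp0$sweeps), 600000)  # 60 s at 10 kHz
  expect_equal(detect_minis(sp0$sweeps[, 1])$frequency_hz, 0)

  # 1 Hz at SNR >= 5: detected count within the Poisson 99% band
  p <- cell_params(mini_rate = 1, mini_amp = 12, noise_sd = 2.4, seed = 11)
  sp <- simulate_spontaneous(p)
  mm <- detect_minis(sp$sweeps[, 1])
  expect_gte(mm$n_events, 45)
  expect_lte(mm$n_events, 75)
})

test_that("cohorts have the designed size and are reproducible", {
  design <- cohort_design(n_cells = c(s45_46.naive = 64, s48_49.naive = 56,
                                      s48_49.stimulated = 60), seed = 5)
  coh <- make_cohort(design, protocols = character(0))
  expect_equal(length(coh$cells), 180)
  expect_equal(nrow(coh$truth), 180)
  expect_equal(unname(table(coh$truth$stage_group)["s45_46"]), 64L)

  # same seed, same downstream features (small cohort, two protocols)
  d2 <- cohort_design(n_cells = c(s48_49.naive = 3), seed = 9,
                      spont_duration_s = 5)
  f1 <- extract_cohort_features(make_cohort(d2, protocols = c("iv_steps",
                                                              "current_steps")))
  f2 <- extract_cohort_features(make_cohort(d2, protocols = c("iv_steps",
                                                              "current_steps")))
  expect_identical(unclass(f1), unclass(f2))
})

test_that("missingness masking is MCAR at the requested rate with guards", {
  x <- matrix(rnorm(155 * 33), 155, 33)
  expect_identical(apply_missingness(x, 0), x)
  xm <- apply_missingness(x, 0.18, seed = 4)
  n_masked <- sum(is.na(xm))
  ci <- qbinom(c(0.005, 0.995), 155 * 33, 0.18)
  expect_gte(n_masked, ci[1])
  expect_lte(n_masked, ci[2])
  # heavy masking still leaves every row and column observed
  xs <- matrix(rnorm(20 * 5), 20, 5)
  xh <- apply_missingness(xs, 0.6, seed = 2)
  expect_true(all(colSums(is.finite(xh)) >= 1))
  expect_true(all(rowSums(is.finite(xh)) >= 1))
  expect_error(apply_missingness(x, 1))
})
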