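# Difference-of-exponentials and linear-times-exponential tuning fits:
# parameter recovery on exact curves, degenerate inputs.

test_that("spikes-vs-current fit recovers the analytic argmax", {
  cur <- seq(0, 180, by = 20)
  counts <- diffexp_curve(cur, a = 10, b = 300, c = 60, d = 2)
  fit <- fit_spikes_vs_current(cur, counts)
  expect_true(fit$converged)
  expect_lt(abs(fit$derived$argmax - diffexp_argmax(10, 300, 60)), 5)

  z <- fit_spikes_vs_current(cur, rep(0, 10))
  expect_equal(z$derived$max_value, 0)
  expect_true(is.na(z$derived$argmax))

  one <- rep(0, 10); one[6] <- 4
  f1 <- fit_spikes_vs_current(cur, one)
  expect_gte(f1$derived$max_value, 2)  # smoothing keeps >= half the count
})

test_that("cosine tuning fit round-trips the generative parameters", {
  per <- c(10, 20, 100 / 3, 40, 50)
  y <- diffexp_curve(per, a = 5, b = 60, c = 25, d = 12)
  fit <- fit_cosine_tuning(per, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$derived$b - 60) / 60, 0.20)
  expect_lt(abs(fit$derived$argmax - diffexp_argmax(5, 60, 25)) /
              diffexp_argmax(5, 60, 25), 0.15)

  z <- fit_cosine_tuning(per, rep(0, 5))
  expect_equal(z$derived$max_value, 0)
  expect_true(is.na(z$derived$argmax))
})

test_that("wave-train fit finds the argmax at a + c", {
  x <- 1:20
  y <- linexp_curve(x, a = 0, b = 3, c = 4, d = 1, e = 0)
  fit <- fit_wave_train(x, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$derived$argmax - 4), 0.5)  # analytic argmax a + c

  flat <- fit_wave_train(x, rep(2, 20))
  expect_true(flat$derived$pinned || flat$derived$c > 100)

  dec <- fit_wave_train(x, 3 * exp(-(x - 1) / 3))
  expect_lte(dec$derived$argmax, 2)
})

test_that("synaptic resonance fit yields argmax, width and PPF", {
  isi <- c(10, 20, 30, 40, 50, 100, 150, 200, 250, 300)
  q <- linexp_curve(isi, a = 0, b = 30, c = 40, d = 1, e = 2)
  fit <- fit_synaptic_resonance(isi, q)
  expect_true(fit$converged)
  expect_lt(abs(fit$derived$argmax - 40), 2)   # a + c = 40 ms
  expect_lt(abs(fit$derived$c - 40) / 40, 0.1)

  flat <- fit_synaptic_resonance(isi, rep(2, 10))
  expect_equal(flat$derived$ppf, 1, tolerance = 0.05)

  # simulator round-trip: extracted PPF tracks the generative curve ratio
  p <- cell_params(noise_sd = 0, syn_facil = 2.0, syn_tau = 60,
                   syn_dep = 1.0, syn_tau_dep = 10, poly_amp = 1)
  qc <- synaptic_charge_curve(simulate_synaptic_protocol(p))
  f2 <- fit_synaptic_resonance(qc$isi_ms, qc$q_pAs)
  q_true <- ephyscensus:::syn_charge_model(p, seq(10, 300, by = 1))
  ppf_true <- max(q_true) / min(q_true)
  expect_true(f2$converged)
  expect_gt(f2$derived$ppf, 1 + 0.5 * (ppf_true - 1))
  expect_lt(f2$derived$ppf, 1 + 1.5 * (ppf_true - 1))
})
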