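test_that("mono-exponential fit recovers generating parameters exactly", {
  t <- seq(0, 1, by = 0.002)
  y <- 50 * exp(-8.99 * t) + 60
  fit <- fit_mono_exponential_decay(t, y)
  expect_true(fit$accepted)
  expect_equal(fit$k, 8.99, tolerance = 1e-6)
  expect_equal(fit$amplitude, 50, tolerance = 1e-5)
  expect_equal(fit$offset, 60, tolerance = 1e-5)
  expect_lt(fit$rmse, 1e-8)
})

test_that("degenerate decays are flagged, not silently fitted", {
  t <- seq(0, 1, by = 0.01)
  flat <- fit_mono_exponential_decay(t, rep(5, length(t)))
  expect_false(flat$accepted)
  expect_match(flat$reason, "constant")
  expect_true(is.na(flat$k))
  # rising signal yields k <= 0 and is flagged
  rising <- fit_mono_exponential_decay(t, 10 - 5 * exp(-3 * t))
  expect_false(rising$accepted)
  expect_error(fit_mono_exponential_decay(t[1:5], rep(1, 5)), "need >= 20")
})

test_that("simulated caffeine decays fit to the closed-form removal rate", {
  out <- simulate_myocyte(control_preset(), protocol("caffeine"))
  sc <- attr(out, "schedule")
  tm <- transient_metrics(out$time_s, out$ca_free_nM, sc$caffeine_time,
                          post_window_s = 2)
  expect_true(tm$accepted[1])
  expect_equal(tm$k_decay[1], caffeine_decay_rate(control_preset()),
               tolerance = 0.01)
})

test_that("transient metrics: amplitude from pulse geometry and flat traces", {
  t <- seq(0, 2, by = 0.001)
  ca <- ifelse(t >= 1 & t < 1.3, 143, 60)
  tm <- transient_metrics(t, ca, stim_times = 1, post_window_s = 0.25)
  expect_equal(tm$amplitude, 83)
  expect_equal(tm$diastolic_ca, 60)
  flat <- transient_metrics(t, rep(60, length(t)), stim_times = 1)
  expect_equal(flat$amplitude, 0)
  expect_error(transient_metrics(t, ca, stim_times = 5), "outside")
})

test_that("steady-state beat metrics match simulator ground truth", {
  rec <- clean_control_record()
  pm <- rec$protocols$systolic
  tr <- rec$traces$systolic
  tm <- transient_metrics(tr$time_s, tr$ca_free_nM, tail(pm$stim_times, 1),
                          fit_after = pm$step_dur_s)
  expect_equal(tm$amplitude, rec$truth_summary$amplitude_nM,
               tolerance = 0.01)
  expect_equal(tm$diastolic_ca, rec$truth$ca_rest, tolerance = 0.01)
  expect_true(tm$accepted)
  expect_equal(tm$k_decay, rec$truth_summary$k_sys, tolerance = 0.01)
})

test_that("rate decomposition is exact subtraction with sign flags", {
  d <- decompose_rates(8.99, 0.745)
  expect_identical(d$k_sr, 8.99 - 0.745)
  expect_equal(d$k_sr, 8.245)
  expect_length(d$flagged, 0)
  expect_identical(decompose_rates(3.2, 3.2)$k_sr, 0)
  neg <- decompose_rates(0.5, 0.9)
  expect_equal(neg$k_sr, -0.4)
  expect_match(neg$flagged, "k_sr < 0")
  # the decomposition always re-sums
  for (k in list(c(9, 1), c(2, 0.4), c(0.8, 0.79))) {
    d <- decompose_rates(k[1], k[2])
    expect_identical(d$k_sr + d$k_caff, d$k_sys)
  }
})

test_that("APD measurement: linear geometry, limit behaviour, template", {
  # triangular AP repolarizing linearly over 100 ms: APD90 = 90 ms
  t <- seq(0, 0.2, by = 1e-4)
  vm <- ifelse(t < 0.05, -80,
               ifelse(t < 0.05 + 0.1, 20 - (t - 0.05) / 0.1 * 100, -80))
  expect_equal(apd(t, vm, 0.9), 90, tolerance = 0.5)
  # fraction -> 1 approaches the full repolarization time
  expect_equal(apd(t, vm, 0.999), 100, tolerance = 0.5)
  expect_lt(apd(t, vm, 0.5), apd(t, vm, 0.9))
  # synthetic template built for a 357 ms APD90
  wf <- make_ap_template(apd90_ms = 357)
  expect_equal(apd(wf$time_s, wf$vm_mV, 0.9), 357, tolerance = 1)
  wf2 <- make_ap_template(apd90_ms = 280)
  expect_equal(apd(wf2$time_s, wf2$vm_mV, 0.9), 280, tolerance = 1)
  # a trace that never repolarizes errors
  expect_error(apd(t[1:700], vm[1:700] + c(rep(0, 500), rep(100, 200)), 0.9),
               "never repolarizes")
  expect_error(apd(t, vm, 1.2), "fraction")
})

test_that("fitted removal rates recover generating rates on noisy cells", {
  # four independent noisy control cells; mean bias below 2%
  ks <- kc <- truth_s <- truth_c <- numeric(4)
  for (i in 1:4) {
    p <- noisy_control(seed = 100L + i)
    rec <- atriaflux:::simulate_cell_record(
      p, atriaflux:::default_protocols()[c("systolic", "caffeine")],
      sprintf("c%d", i), "a1")
    res <- analyze_cell(rec)
    ks[i] <- res$k_sys; kc[i] <- res$k_caff
    truth_s[i] <- rec$truth_summary$k_sys
    truth_c[i] <- rec$truth_summary$k_caff
  }
  expect_lt(abs(rel_bias_pct(ks, truth_s)), 2)
  expect_lt(abs(rel_bias_pct(kc, truth_c)), 2)
})
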