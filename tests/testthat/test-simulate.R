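test_that("a cell with no Ca sources stays at the resting steady state", {
  p <- control_preset()
  p$g_cal_peak <- 0
  p$frac_release <- 0
  out <- simulate_myocyte(p, protocol("voltage_step", n_beats = 2))
  expect_equal(out$ca_free_nM, rep(p$ca_rest, nrow(out)), tolerance = 1e-10)
  expect_equal(max(abs(out$i_cal_pA)), 0)
  expect_equal(max(abs(out$i_ncx_pA)), 0, tolerance = 1e-8)
  expect_equal(out$ca_sr_uM, rep(p$sr_init, nrow(out)), tolerance = 1e-10)
})

test_that("seeded simulations are bit-identical across runs", {
  p <- noisy_control(seed = 42L)
  pr <- protocol("voltage_step", n_beats = 2)
  a <- simulate_myocyte(p, pr)
  b <- simulate_myocyte(p, pr)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # a different seed changes the noise
  p2 <- noisy_control(seed = 43L)
  c <- simulate_myocyte(p2, pr)
  expect_false(identical(a$i_total_pA, c$i_total_pA))
})

test_that("caffeine protocol conserves Ca: SR content equals total extrusion", {
  out <- simulate_myocyte(control_preset(), protocol("caffeine"))
  sc <- attr(out, "schedule")
  truth <- attr(out, "truth")
  vol <- truth$cm / truth$sa_to_vol
  pre <- max(which(out$time_s < sc$caffeine_time))
  sr_onset <- out$ca_sr_uM[pre]
  win <- out$time_s >= sc$caffeine_time
  t <- out$time_s[win]
  ncx_umol <- atriaflux:::trapz(t, -out$i_ncx_pA[win]) * 1e6 / (96485 * vol)
  pmca_umol <- atriaflux:::trapz(
    t, truth$k_pmca_flux * truth$beta * 1e-3 *
      (out$ca_free_nM[win] - truth$ca_rest))
  expect_lt(abs((ncx_umol + pmca_umol) / sr_onset - 1), 0.01)
})

test_that("pacing from the analytic steady state sits on a limit cycle, and a
          perturbed SR converges back within the documented beat count", {
  p <- control_preset()
  out <- simulate_myocyte(p, protocol("voltage_step", n_beats = 10))
  sched <- attr(out, "schedule")
  dia <- sapply(sched$stim_times, function(s)
    out$ca_sr_uM[max(which(out$time_s < s))])
  steps <- abs(diff(dia) / dia[-length(dia)])
  expect_lt(max(steps), 0.005)
  # start 20% over the steady state: within 80 beats the limit cycle is
  # re-established to < 0.5% beat-to-beat
  p2 <- p
  p2$sr_init <- p$sr_init * 1.2
  out2 <- simulate_myocyte(p2, protocol("voltage_step", n_beats = 80))
  s2 <- attr(out2, "schedule")$stim_times
  dia2 <- sapply(tail(s2, 2), function(s)
    out2$ca_sr_uM[max(which(out2$time_s < s))])
  expect_lt(abs(diff(dia2)) / dia2[1], 0.005)
  expect_lt(abs(dia2[2] / steady_state_sr(p) - 1), 0.01)
})

test_that("caffeine decay follows the documented closed-form rate constant", {
  for (p in list(control_preset(), hf_preset())) {
    out <- simulate_myocyte(p, protocol("caffeine"))
    sc <- attr(out, "schedule")
    fit <- fit_mono_exponential_decay(
      out$time_s, out$ca_free_nM,
      window = c(sc$caffeine_time + 0.05, sc$caffeine_time + 8))
    expect_true(fit$accepted)
    expect_equal(fit$k, caffeine_decay_rate(p), tolerance = 1e-3)
  }
  # with NCX blocked the decay is PMCA-only
  p <- control_preset()
  out <- simulate_myocyte(p, protocol("caffeine_ni"))
  sc <- attr(out, "schedule")
  fit <- fit_mono_exponential_decay(
    out$time_s, out$ca_free_nM,
    window = c(sc$caffeine_time + 0.05, sc$caffeine_time + 11))
  expect_equal(fit$k, p$k_pmca_flux, tolerance = 1e-2)
})

test_that("apply_condition scales parameters and leaves the input unchanged", {
  p <- control_preset()
  nic <- apply_condition(p, "nicardipine")
  expect_equal(nic$g_cal_peak, p$g_cal_peak * 0.70)
  expect_equal(nic[setdiff(names(nic), "g_cal_peak")],
               p[setdiff(names(p), "g_cal_peak")])
  expect_equal(p$g_cal_peak, 2.27)  # original untouched
  expect_identical(apply_condition(p, "none"), p)
  iso <- apply_condition(p, "isoprenaline", ical_factor = 4.26 / 2.27)
  expect_equal(iso$g_cal_peak, 4.26)
  expect_gt(iso$k_serca, p$k_serca)
  expect_error(apply_condition(p, "caffeine-free"), "valid")
})

test_that("parameter validation rejects impossible values", {
  p <- unclass(control_preset())
  p$beta <- 0.5
  expect_error(do.call(sim_params, p), "beta")
  p <- unclass(control_preset()); p$ca_rest <- -1
  expect_error(do.call(sim_params, p), "ca_rest")
  p <- unclass(control_preset()); p$k_serca <- -0.1
  expect_error(do.call(sim_params, p), "k_serca")
})

test_that("fluorescence emission is monotone, saturating, and flat at rest", {
  dye <- fluo5f_dye()
  const <- emit_fluorescence(rep(60.7, 100), dye)
  expect_equal(const, rep(dye$f_max * 60.7 / (60.7 + dye$kd), 100))
  ca <- 10^seq(1, 7, by = 0.1)
  f <- emit_fluorescence(ca, dye)
  expect_true(all(diff(f) > 0))
  expect_true(all(f < dye$f_max))
  expect_lt(dye$f_max - tail(f, 1), 1e-3 * dye$f_max)
  r <- emit_fluorescence(ca, fura2_dye())
  expect_true(all(diff(r) > 0))
  expect_true(all(r < fura2_dye()$r_max & r > fura2_dye()$r_min))
  expect_error(emit_fluorescence(c(10, -5), dye), "> 0")
})

test_that("make_cohort bookkeeping: sizes, ids, determinism, degenerate CVs", {
  pr <- list(systolic = protocol("voltage_step", n_beats = 2))
  coh <- make_cohort(control_preset(), NULL, n_animals = 6,
                     cells_per_animal = 4, seed = 5, protocols = pr)
  expect_length(coh, 24)
  expect_length(unique(vapply(coh, `[[`, "", "animal_id")), 6)
  coh2 <- make_cohort(control_preset(), NULL, n_animals = 6,
                      cells_per_animal = 4, seed = 5, protocols = pr)
  expect_identical(coh, coh2)
  # zero CV at both levels: every cell shares the base parameters
  coh0 <- make_cohort(control_preset(), NULL, n_animals = 2,
                      cells_per_animal = 2, cv_animal = 0, cv_cell = 0,
                      seed = 5, protocols = pr)
  betas <- vapply(coh0, function(r) r$truth$beta, numeric(1))
  expect_equal(betas, rep(565, 4))
})
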