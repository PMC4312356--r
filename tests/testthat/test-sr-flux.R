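test_that("cell volume follows capacitance over surface-to-volume ratio", {
  expect_equal(cell_volume_from_capacitance(59.6, 5.06), 11.78,
               tolerance = 1e-3)
  expect_equal(cell_volume_from_capacitance(125.9, 4.89), 25.75,
               tolerance = 1e-3)
  expect_equal(cell_volume_from_capacitance(7.3, 7.3), 1)
  expect_error(cell_volume_from_capacitance(-1, 5), "cm")
  expect_error(cell_volume_from_capacitance(50, 0), "sa_to_vol")
  g <- cell_geometry(59.6, 5.06)
  expect_lt(abs(g$volume * g$sa_to_vol - g$cm), 1e-9)
})

# a clean synthetic caffeine current: flat baseline, then a constant inward
# deflection of depth_pA for dur_s, then baseline again
square_caffeine_trace <- function(depth_pA = 100, dur_s = 1, baseline = 0,
                                  dt = 1e-3) {
  t <- seq(0, 3 + dur_s + 2, by = dt)
  i <- rep(baseline, length(t))
  i[t >= 3 & t < 3 + dur_s] <- baseline - depth_pA
  list(time = t, i = i, caff = 3)
}

test_that("SR content from a known charge matches the analytic value", {
  tr <- square_caffeine_trace(100, 1)
  geom <- cell_geometry(59.6, 5.06)
  res <- integrate_ncx_sr_content(tr$time, tr$i, tr$caff, geom)
  expect_equal(res$ncx_charge, 100, tolerance = 0.01)
  # 100 pC / F = 1.036e-15 mol in 11.78 pl -> 88.0 umol/l
  expect_equal(res$sr_content, 88.0, tolerance = 0.1)
  expect_equal(res$pmca_correction_factor, 1)
  expect_equal(res$baseline_current, 0)
})

test_that("zero deflection flags and returns zero content; negative errors", {
  tr <- square_caffeine_trace(0, 1)
  geom <- cell_geometry(59.6, 5.06)
  res <- integrate_ncx_sr_content(tr$time, tr$i, tr$caff, geom)
  expect_true(res$flagged)
  expect_equal(res$sr_content, 0)
  out <- square_caffeine_trace(-50, 1)  # outward deflection
  expect_error(integrate_ncx_sr_content(out$time, out$i, out$caff, geom),
               "negative integrated charge")
})

test_that("SR content is invariant to uniform baseline shifts", {
  tr <- square_caffeine_trace(80, 2)
  geom <- cell_geometry(59.6, 5.06)
  a <- integrate_ncx_sr_content(tr$time, tr$i, tr$caff, geom)
  b <- integrate_ncx_sr_content(tr$time, tr$i - 137.5, tr$caff, geom)
  expect_equal(a$sr_content, b$sr_content, tolerance = 1e-10)
  expect_equal(b$baseline_current, -137.5)
})

test_that("volumetric quantities are intensive: scaling cm and volume
          together changes nothing", {
  tr <- square_caffeine_trace(100, 1)
  g1 <- cell_geometry(59.6, 5.06)
  g2 <- cell_geometry(2 * 59.6, 5.06)  # double cell, double current
  a <- integrate_ncx_sr_content(tr$time, tr$i, tr$caff, g1)
  b <- integrate_ncx_sr_content(tr$time, 2 * tr$i, tr$caff, g2)
  expect_equal(a$sr_content, b$sr_content, tolerance = 1e-10)
  expect_equal(integrate_cal_entry(tr$time, tr$i, c(3, 4), g1),
               integrate_cal_entry(tr$time, 2 * tr$i, c(3, 4), g2),
               tolerance = 1e-10)
})

test_that("simulated SR content recovers ground truth with and without PMCA", {
  # no PMCA: the NCX integral alone captures the whole store
  p0 <- atriaflux:::preset_from_targets(
    amplitude_nM = 83, beta = 565, sr_umol = 83.9, k_sys = 8.99,
    k_caff = 0.745, pmca_share = 0, peak_density = 2.27, k_inact = 404,
    cm = 59.6, sa_to_vol = 5.06, ca_rest = 60.7)
  out <- simulate_myocyte(p0, protocol("caffeine"))
  sc <- attr(out, "schedule")
  geom <- cell_geometry(p0$cm, p0$sa_to_vol)
  sr_truth <- out$ca_sr_uM[max(which(out$time_s < sc$caffeine_time))]
  res <- integrate_ncx_sr_content(out$time_s, out$i_total_pA,
                                  sc$caffeine_time, geom)
  expect_equal(res$sr_content, sr_truth, tolerance = 0.01)
  # with PMCA active, the rate-constant correction restores the content
  p1 <- control_preset()   # pmca share 0.15
  out1 <- simulate_myocyte(p1, protocol("caffeine"))
  sc1 <- attr(out1, "schedule")
  sr_truth1 <- out1$ca_sr_uM[max(which(out1$time_s < sc1$caffeine_time))]
  res_un <- integrate_ncx_sr_content(out1$time_s, out1$i_total_pA,
                                     sc1$caffeine_time, geom)
  expect_lt(res_un$sr_content, 0.9 * sr_truth1)  # uncorrected underestimates
  res_cor <- integrate_ncx_sr_content(
    out1$time_s, out1$i_total_pA, sc1$caffeine_time, geom,
    k_caff = caffeine_decay_rate(p1), k_pmca = p1$k_pmca_flux)
  expect_equal(res_cor$sr_content, sr_truth1, tolerance = 0.02)
})

test_that("integrated L-type entry matches analytic and simulator values", {
  geom <- cell_geometry(59.6, 5.06)
  t <- seq(0, 1, by = 1e-4)
  i <- ifelse(t >= 0.2 & t < 0.3, -2 * 59.6, 0)   # 2 pA/pF for 100 ms
  expect_equal(integrate_cal_entry(t, i, c(0.2, 0.3), geom), 5.24,
               tolerance = 0.01)
  expect_equal(integrate_cal_entry(t, rep(0, length(t)), c(0.2, 0.3), geom),
               0)
  expect_error(integrate_cal_entry(t, i, c(0.9, 1.5), geom), "window")
  # simulator step: integral of the recorded current equals the analytic
  # per-beat entry
  rec <- clean_control_record()
  tr <- rec$traces$systolic
  pm <- rec$protocols$systolic
  s <- tail(pm$stim_times, 1)
  entry <- integrate_cal_entry(tr$time_s, tr$i_cal_pA,
                               c(s, s + pm$step_dur_s),
                               cell_geometry(rec$geometry$cm,
                                             rec$geometry$sa_to_vol))
  expect_equal(entry, rec$truth_summary$entry_umol, tolerance = 0.01)
})

test_that("buffering power is recovered from caffeine transients", {
  for (rec in list(clean_control_record(), clean_hf_record())) {
    tr <- rec$traces$caffeine
    pm <- rec$protocols$caffeine
    geom <- cell_geometry(rec$geometry$cm, rec$geometry$sa_to_vol)
    buf <- buffer_power_fit(tr$time_s, tr$ca_free_nM, tr$i_total_pA,
                            pm$caffeine_time, geom,
                            k_caff = rec$truth_summary$k_caff,
                            k_pmca = rec$truth_summary$k_pmca)
    expect_false(buf$flagged)
    expect_equal(buf$beta, rec$truth$beta, tolerance = 0.02)
    expect_gt(buf$r_squared, 0.99)
  }
})

test_that("a constant free-Ca trace makes the buffer regression degenerate", {
  tr <- square_caffeine_trace(100, 1)
  geom <- cell_geometry(59.6, 5.06)
  buf <- buffer_power_fit(tr$time, rep(60.7, length(tr$time)), tr$i,
                          tr$caff, geom)
  expect_true(buf$flagged)
  expect_match(paste(buf$flags, collapse = " "), "degenerate|constant")
  expect_true(is.na(buf$beta))
})

test_that("NCX current-density slope recovers the generating coefficient", {
  rec <- clean_control_record()
  tr <- rec$traces$caffeine
  pm <- rec$protocols$caffeine
  fit <- ncx_ca_slope(tr$time_s, tr$ca_free_nM, tr$i_total_pA,
                      pm$caffeine_time, cm = rec$geometry$cm)
  expect_equal(fit$slope, rec$truth$g_ncx, tolerance = 0.01)
  expect_gt(fit$r_squared, 0.999)
  # exactly linear current-Ca relation: r^2 = 1
  t <- seq(0, 5, by = 0.01)
  ca <- 60 + 140 * exp(-0.7 * pmax(0, t - 2.5))
  i <- -0.007 * 59.6 * (ca - 60)
  fit2 <- ncx_ca_slope(t, ca, i, caffeine_time = 2.5, cm = 59.6)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit2$slope, 0.007, tolerance = 1e-6)
  expect_error(ncx_ca_slope(t[1:255], ca[1:255], i[1:255], 2.5, 59.6),
               "10 paired samples")
})

test_that("a simulated NCX down-regulation is recovered as the same percent
          contrast", {
  p_ref <- control_preset()
  p_dn <- unclass(p_ref)
  p_dn$g_ncx <- p_ref$g_ncx * (1 - 0.249)
  p_dn <- do.call(sim_params, p_dn)
  slopes <- vapply(list(p_ref, p_dn), function(p) {
    out <- simulate_myocyte(p, protocol("caffeine"))
    sc <- attr(out, "schedule")
    ncx_ca_slope(out$time_s, out$ca_free_nM, out$i_total_pA,
                 sc$caffeine_time, cm = p$cm)$slope
  }, numeric(1))
  contrast <- percent_change(slopes[1], slopes[2])
  expect_equal(contrast, 24.9, tolerance = 3 / 24.9)
})

test_that("buffer fit and NCX integral tell one consistent total-Ca story", {
  rec <- clean_control_record()
  tr <- rec$traces$caffeine
  pm <- rec$protocols$caffeine
  geom <- cell_geometry(rec$geometry$cm, rec$geometry$sa_to_vol)
  kc <- rec$truth_summary$k_caff
  kp <- rec$truth_summary$k_pmca
  src <- integrate_ncx_sr_content(tr$time_s, tr$i_total_pA, pm$caffeine_time,
                                  geom, k_caff = kc, k_pmca = kp)
  buf <- buffer_power_fit(tr$time_s, tr$ca_free_nM, tr$i_total_pA,
                          pm$caffeine_time, geom, k_caff = kc, k_pmca = kp)
  win <- tr$time_s >= pm$caffeine_time
  ca_peak <- max(tr$ca_free_nM[win])
  ca_end <- tail(tr$ca_free_nM[win], 1)
  # total Ca at decay start ~ beta * (peak - end) in umol/l
  expect_equal(src$sr_content, buf$beta * (ca_peak - ca_end) * 1e-3,
               tolerance = 0.02)
})
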