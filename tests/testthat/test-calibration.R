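test_that("fura ratio inversion: half-saturation identity and zero-Ca limit", {
  cal <- fura_calibration(r_min = 0.5, r_max = 2.5, k_eff = 1200)
  mid <- cal$r_min + (cal$r_max - cal$r_min) / 2
  expect_equal(as.numeric(fura_ratio_to_ca(mid, cal)), cal$k_eff)
  near_min <- cal$r_min + 1e-9
  expect_lt(as.numeric(fura_ratio_to_ca(near_min, cal)), 1e-5)
})

test_that("fura calibration masks or rejects out-of-range ratios", {
  cal <- fura_calibration()
  r <- c(0.5, cal$r_min - 0.01, 1.2, cal$r_max + 0.1)
  expect_error(fura_ratio_to_ca(r, cal, out_of_range = "error"), "index 2")
  expect_warning(ca <- fura_ratio_to_ca(r, cal), "masked 2")
  expect_true(all(is.na(ca[c(2, 4)])))
  expect_true(all(is.finite(ca[c(1, 3)])))
  expect_identical(attr(ca, "flagged"), c(2L, 4L))
})

test_that("self-ratio calibration: resting identity and hand-checked value", {
  cal <- fluo_selfratio_calibration(kd = 1035, ca_rest = 60.7, f_rest = 10)
  expect_identical(as.numeric(fluo_selfratio_to_ca(10, cal)), 60.7)
  # R = 2: ca = 1035*2 / (1035/60.7 + 1 - 2)
  expect_equal(as.numeric(fluo_selfratio_to_ca(20, cal)),
               2070 / (1035 / 60.7 - 1), tolerance = 1e-12)
  expect_equal(as.numeric(fluo_selfratio_to_ca(20, cal)), 129.0,
               tolerance = 1e-3)
})

test_that("self-ratio calibration is strictly monotone below saturation", {
  cal <- fluo_selfratio_calibration(kd = 1035, ca_rest = 60.7, f_rest = 1)
  r_sat <- cal$kd / cal$ca_rest + 1
  r <- seq(0.1, r_sat - 0.05, length.out = 200)
  ca <- as.numeric(fluo_selfratio_to_ca(r, cal))
  expect_true(all(diff(ca) > 0))
})

test_that("saturated self-ratio samples error by default and mask on request", {
  cal <- fluo_selfratio_calibration(kd = 1035, ca_rest = 60.7, f_rest = 1)
  r_sat <- cal$kd / cal$ca_rest + 1
  f <- c(1, 2, r_sat + 0.1, 3)
  expect_error(fluo_selfratio_to_ca(f, cal), "index 3")
  expect_warning(ca <- fluo_selfratio_to_ca(f, cal, saturated = "mask"),
                 "masked 1")
  expect_true(is.na(ca[3]) && all(is.finite(ca[-3])))
})

test_that("emission and calibration are exact inverses over 20-2000 nmol/l", {
  ca <- seq(20, 2000, length.out = 500)
  # single-wavelength self-ratio round trip
  dye <- fluo5f_dye()
  ca_rest <- 60.7
  f <- emit_fluorescence(ca, dye)
  f_rest <- emit_fluorescence(ca_rest, dye)
  cal <- fluo_selfratio_calibration(kd = dye$kd, ca_rest = ca_rest,
                                    f_rest = f_rest)
  back <- as.numeric(fluo_selfratio_to_ca(f, cal))
  expect_lt(max(abs(back / ca - 1)), 1e-3)
  # ratiometric round trip
  r <- emit_fluorescence(ca, fura2_dye())
  back2 <- as.numeric(fura_ratio_to_ca(r, fura_calibration()))
  expect_lt(max(abs(back2 / ca - 1)), 1e-3)
})

test_that("calibration constructors validate their constants", {
  expect_error(fura_calibration(r_min = 2, r_max = 1), "r_max > r_min")
  expect_error(fura_calibration(k_eff = -5), "k_eff")
  expect_error(fluo_selfratio_calibration(kd = 0, ca_rest = 60, f_rest = 1),
               "kd")
  expect_error(fluo_selfratio_calibration(ca_rest = -1, f_rest = 1),
               "ca_rest")
})
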