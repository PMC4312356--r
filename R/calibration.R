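#' Calibration constants for the two dye methods
#'
#' `fura_calibration()` holds the ratiometric constants (ratio at zero Ca,
#' ratio at saturating Ca, effective dissociation constant); the defaults
#' match [fura2_dye()] so that simulated ratios invert exactly.
#' `fluo_selfratio_calibration()` holds the single-wavelength self-ratio
#' constants: the dye Kd (default 1035 nmol/l), the resting-Ca anchor
#' (obtained in practice from ratiometric measurements in sister cells) and
#' the resting fluorescence of the trace being calibrated.
#'
#' @param r_min,r_max,k_eff ratiometric constants (r_max > r_min > 0,
#'   k_eff > 0 nmol/l).
#' @param kd dye dissociation constant, nmol/l.
#' @param ca_rest resting free Ca anchor, nmol/l.
#' @param f_rest resting fluorescence, a.u.
#' @return a calibration object.
#' @export
fura_calibration <- function(r_min = 0.30, r_max = 3.00, k_eff = 1100) {
  if (!(r_max > r_min && r_min > 0))
    stop("fura_calibration: need r_max > r_min > 0")
  if (k_eff <= 0) stop("fura_calibration: k_eff must be > 0")
  structure(list(r_min = r_min, r_max = r_max, k_eff = k_eff),
            class = "fura_calibration")
}

#' @rdname fura_calibration
#' @export
fluo_selfratio_calibration <- function(kd = 1035, ca_rest, f_rest) {
  if (kd <= 0) stop("fluo_selfratio_calibration: kd must be > 0")
  if (ca_rest <= 0) stop("fluo_selfratio_calibration: ca_rest must be > 0")
  if (f_rest <= 0) stop("fluo_selfratio_calibration: f_rest must be > 0")
  structure(list(kd = kd, ca_rest = ca_rest, f_rest = f_rest),
            class = "fluo_selfratio_calibration")
}

#' Convert a Fura-2 excitation ratio series to free Ca
#'
#' Standard ratiometric inversion ca = k_eff * (R - r_min) / (r_max - R),
#' strictly increasing on (r_min, r_max). Samples at or outside the bounds
#' cannot be inverted; they are either masked to `NA` (with their indices
#' reported in the `"flagged"` attribute and a warning) or raise an error.
#'
#' @param ratio ratio series.
#' @param calib a [fura_calibration()].
#' @param out_of_range `"mask"` (default) or `"error"`.
#' @return free Ca series, nmol/l, with attribute `flagged` giving the
#'   indices of unusable samples.
#' @export
fura_ratio_to_ca <- function(ratio, calib, out_of_range = c("mask", "error")) {
  stopifnot(inherits(calib, "fura_calibration"))
  out_of_range <- match.arg(out_of_range)
  bad <- which(!is.finite(ratio) | ratio <= calib$r_min |
                 ratio >= calib$r_max)
  if (length(bad) && out_of_range == "error")
    stop(sprintf("fura_ratio_to_ca: %d sample(s) outside (r_min, r_max); first at index %d",
                 length(bad), bad[1L]))
  ca <- calib$k_eff * (ratio - calib$r_min) / (calib$r_max - ratio)
  if (length(bad)) {
    ca[bad] <- NA_real_
    warning(sprintf("fura_ratio_to_ca: masked %d out-of-range sample(s)",
                    length(bad)))
  }
  structure(ca, flagged = bad)
}

#' Convert a single-wavelength fluorescence series to free Ca (self-ratio)
#'
#' Self-ratio calibration anchored at rest: with R = f / f_rest,
#' ca = kd * R / (kd / ca_rest + 1 - R). R = 1 maps exactly to `ca_rest` and
#' the mapping is strictly increasing below the saturation bound
#' R < kd / ca_rest + 1. Saturated samples (denominator <= 0) raise an error
#' naming the first offending index, or are masked to `NA` when
#' `saturated = "mask"` (downstream fits ignore masked samples).
#'
#' @param f fluorescence series, a.u.
#' @param calib a [fluo_selfratio_calibration()].
#' @param saturated `"error"` (default) or `"mask"`.
#' @return free Ca series, nmol/l, with attribute `flagged`.
#' @export
fluo_selfratio_to_ca <- function(f, calib, saturated = c("error", "mask")) {
  stopifnot(inherits(calib, "fluo_selfratio_calibration"))
  saturated <- match.arg(saturated)
  r <- f / calib$f_rest
  denom <- calib$kd / calib$ca_rest + 1 - r
  bad <- which(!is.finite(r) | denom <= 0 | r <= 0)
  if (length(bad) && saturated == "error")
    stop(sprintf("fluo_selfratio_to_ca: saturated sample at index %d (of %d flagged)",
                 bad[1L], length(bad)))
  ca <- calib$kd * r / denom
  if (length(bad)) {
    ca[bad] <- NA_real_
    warning(sprintf("fluo_selfratio_to_ca: masked %d saturated sample(s)",
                    length(bad)))
  }
  structure(ca, flagged = bad)
}
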