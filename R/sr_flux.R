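#' Cell geometry from membrane capacitance and surface-to-volume ratio
#'
#' Cell volume is capacitance divided by the capacitance-to-volume
#' (surface-area-to-volume) ratio; all integrated sarcolemmal Ca fluxes and
#' SR contents are expressed per litre of total cell volume through it.
#'
#' @param cm membrane capacitance, pF (> 0).
#' @param sa_to_vol surface-area-to-volume ratio, pF/pl (> 0).
#' @return a `cell_geometry` object with fields `cm`, `sa_to_vol`, `volume`
#'   (pl).
#' @export
cell_geometry <- function(cm, sa_to_vol) {
  v <- cell_volume_from_capacitance(cm, sa_to_vol)
  structure(list(cm = cm, sa_to_vol = sa_to_vol, volume = v),
            class = "cell_geometry")
}

#' @rdname cell_geometry
#' @export
cell_volume_from_capacitance <- function(cm, sa_to_vol) {
  if (!is.numeric(cm) || any(cm <= 0))
    stop("cell_volume_from_capacitance: cm must be > 0")
  if (!is.numeric(sa_to_vol) || any(sa_to_vol <= 0))
    stop("cell_volume_from_capacitance: sa_to_vol must be > 0")
  cm / sa_to_vol
}

# umol/l of cell volume per pC of charge at z elementary charges per Ca ion
charge_to_umol <- function(charge_pC, volume_pl, z = 1) {
  charge_pC * 1e6 / (z * FARADAY * volume_pl)
}

#' SR Ca content from the integrated caffeine-evoked NCX current
#'
#' Rapid caffeine empties the SR; the released Ca leaves the cell mainly on
#' NCX, which carries one net inward elementary charge per extruded Ca
#' (3 Na : 1 Ca). Integrating the inward current deflection below the
#' pre-caffeine baseline therefore counts the extruded Ca:
#' charge / F gives moles, divided by cell volume gives umol/l. Extrusion by
#' PMCA carries no NCX charge, so the NCX-derived content is multiplied by a
#' correction factor >= 1: k_caff / (k_caff - k_pmca) when both rate
#' constants are supplied, 1 / (1 - pmca_share) when a share is configured,
#' and 1 otherwise.
#'
#' The baseline is the median current over `baseline_s` seconds before
#' caffeine, and the deflection is integrated over the full window from
#' caffeine onset to `window_end` (default: end of trace). Noise integrates
#' to approximately zero over the window; a smoothed return-to-baseline check
#' (within 2 SD of the pre-caffeine noise) is used only to flag traces whose
#' decay is incomplete, and a flag is also raised when the peak deflection is
#' below `snr_min` noise SDs.
#'
#' @param time time vector, s.
#' @param i_current recorded membrane current, pA (inward negative); during
#'   the caffeine window this is NCX-dominated.
#' @param caffeine_time caffeine onset, s.
#' @param geometry a [cell_geometry()].
#' @param k_caff,k_pmca measured decay rate constants used for the PMCA
#'   correction, 1/s (optional).
#' @param pmca_share alternative correction: assumed PMCA fraction of
#'   sarcolemmal extrusion, in [0, 1).
#' @param baseline_s pre-caffeine baseline window, s.
#' @param window_end end of the integration window, s.
#' @param snr_min minimum peak deflection in units of the baseline noise SD.
#' @param smooth_width samples in the running-mean smoother used for the
#'   flags.
#' @return list with `sr_content` (umol/l), `ncx_charge` (pC),
#'   `pmca_correction_factor`, `baseline_current` (pA), `noise_sd` (pA),
#'   `flagged`, `flags`.
#' @export
integrate_ncx_sr_content <- function(time, i_current, caffeine_time, geometry,
                                     k_caff = NULL, k_pmca = NULL,
                                     pmca_share = NULL,
                                     baseline_s = 2, window_end = max(time),
                                     snr_min = 5, smooth_width = 51L) {
  stopifnot(inherits(geometry, "cell_geometry"))
  if (caffeine_time <= min(time) || caffeine_time >= max(time))
    stop("integrate_ncx_sr_content: caffeine_time outside trace")
  pre <- which(time >= caffeine_time - baseline_s & time < caffeine_time)
  if (length(pre) < 10L)
    stop("integrate_ncx_sr_content: too few pre-caffeine baseline samples")
  baseline <- median(i_current[pre])
  noise_sd <- mad(i_current[pre])
  win <- which(time >= caffeine_time & time <= window_end)
  defl <- baseline - i_current[win]            # inward deflection positive
  flags <- character(0)
  sm <- running_mean(defl, smooth_width)
  peak_defl <- max(sm)
  if (noise_sd > 0 && peak_defl < snr_min * noise_sd)
    flags <- c(flags, sprintf("deflection %.3g pA below %g x noise SD",
                              peak_defl, snr_min))
  sm_sd <- noise_sd / sqrt(smooth_width)
  if (tail(sm, 1L) > max(2 * sm_sd, 0.002 * peak_defl))
    flags <- c(flags, "current has not returned to baseline by window end")
  charge <- trapz(time[win], defl)
  # a negative charge beyond what noise alone could produce is a sign error
  dt <- median(diff(time[win]))
  charge_tol <- 2 * noise_sd * sqrt(length(win)) * dt + 1e-9
  if (charge < -charge_tol)
    stop("integrate_ncx_sr_content: negative integrated charge")
  if (peak_defl <= 0) {
    flags <- c(flags, "no inward deflection")
    charge <- max(charge, 0)
  }
  cf <- pmca_correction_factor(k_caff, k_pmca, pmca_share)
  list(sr_content = charge_to_umol(charge, geometry$volume, z = 1) * cf,
       ncx_charge = charge, pmca_correction_factor = cf,
       baseline_current = baseline, noise_sd = noise_sd,
       flagged = length(flags) > 0L, flags = flags)
}

pmca_correction_factor <- function(k_caff = NULL, k_pmca = NULL,
                                   pmca_share = NULL) {
  cf <- 1
  if (!is.null(k_caff) && !is.null(k_pmca) &&
      is.finite(k_caff) && is.finite(k_pmca)) {
    if (k_pmca >= k_caff)
      stop("pmca correction: k_pmca must be < k_caff")
    cf <- k_caff / (k_caff - k_pmca)
  } else if (!is.null(pmca_share) && is.finite(pmca_share)) {
    if (pmca_share < 0 || pmca_share >= 1)
      stop("pmca correction: pmca_share must be in [0, 1)")
    cf <- 1 / (1 - pmca_share)
  }
  if (cf < 1) stop("pmca correction factor < 1")
  cf
}

#' Integrated L-type Ca entry over a depolarizing step
#'
#' Integrates the leak-subtracted L-type current over the step window and
#' converts to umol/l of cell volume with 2 elementary charges per Ca ion.
#'
#' @param time time vector, s.
#' @param i_cal leak-subtracted L-type current, pA (inward negative).
#' @param step_window `c(t_start, t_end)` of the depolarizing step, s.
#' @param geometry a [cell_geometry()].
#' @return Ca entry, umol/l of cell volume.
#' @export
integrate_cal_entry <- function(time, i_cal, step_window, geometry) {
  stopifnot(inherits(geometry, "cell_geometry"))
  if (step_window[1L] < min(time) || step_window[2L] > max(time) ||
      step_window[2L] <= step_window[1L])
    stop("integrate_cal_entry: step window outside trace")
  win <- which(time >= step_window[1L] & time <= step_window[2L])
  charge <- trapz(time[win], -i_cal[win])   # inward charge positive
  charge_to_umol(charge, geometry$volume, z = 2)
}

#' Cytosolic Ca buffering power from a caffeine transient
#'
#' During the caffeine-evoked transient the SR is empty and every change of
#' cytosolic total Ca is a sarcolemmal extrusion, so the total Ca remaining
#' at time t is the (PMCA-corrected) extrusion-current integral from t to the
#' end of the decay. Plotting that total against the simultaneous free Ca and
#' fitting a straight line over the central part of the decay gives the
#' buffering power beta = delta total / delta free as the slope (Ca in
#' matching concentration units; free Ca is converted from nmol/l to umol/l
#' so the slope is dimensionless).
#'
#' @inheritParams integrate_ncx_sr_content
#' @param ca_free calibrated free Ca, nmol/l (same sampling as the current).
#' @param range_frac fraction of the transient's free-Ca range excluded at
#'   each end of the regression (avoids release and plateau artifacts).
#' @param min_points minimum regression points.
#' @param r2_floor fits with r-squared below this are flagged.
#' @return list with `beta`, `intercept` (umol/l), `r_squared`,
#'   `ca_range_used` (nmol/l), `n_points`, `correction_factor`, `flagged`,
#'   `flags`.
#' @export
buffer_power_fit <- function(time, ca_free, i_current, caffeine_time,
                             geometry, k_caff = NULL, k_pmca = NULL,
                             pmca_share = NULL, baseline_s = 2,
                             window_end = max(time), range_frac = 0.1,
                             min_points = 10L, r2_floor = 0.9) {
  stopifnot(inherits(geometry, "cell_geometry"))
  pre <- which(time >= caffeine_time - baseline_s & time < caffeine_time)
  if (length(pre) < 10L)
    stop("buffer_power_fit: too few pre-caffeine baseline samples")
  baseline <- median(i_current[pre])
  cf <- pmca_correction_factor(k_caff, k_pmca, pmca_share)
  win <- which(time >= caffeine_time & time <= window_end)
  tw <- time[win]
  defl <- baseline - i_current[win]
  total <- charge_to_umol(rev_cumtrapz(tw, defl), geometry$volume, z = 1) * cf
  free <- ca_free[win]
  out <- list(beta = NA_real_, intercept = NA_real_, r_squared = NA_real_,
              ca_range_used = c(NA_real_, NA_real_), n_points = 0L,
              correction_factor = cf, flagged = TRUE, flags = character(0))
  ok <- !is.na(free)
  if (!any(ok)) {
    out$flags <- "no calibrated samples in caffeine window"
    return(out)
  }
  pk_i <- which.max(ifelse(ok, free, -Inf))
  decay <- seq.int(pk_i, length(win))
  f_end <- min(free[decay], na.rm = TRUE)
  f_pk <- free[pk_i]
  if (!is.finite(f_pk - f_end) || f_pk - f_end <= 0) {
    out$flags <- "degenerate: free Ca constant over caffeine window"
    return(out)
  }
  lo <- f_end + range_frac * (f_pk - f_end)
  hi <- f_pk - range_frac * (f_pk - f_end)
  sel <- decay[which(free[decay] >= lo & free[decay] <= hi &
                       !is.na(free[decay]))]
  if (length(sel) < min_points) {
    out$flags <- sprintf("only %d regression points, need >= %d",
                         length(sel), min_points)
    return(out)
  }
  free_umol <- free[sel] * 1e-3
  fit <- lm(total[sel] ~ free_umol)
  out$beta <- unname(coef(fit)[2L])
  out$intercept <- unname(coef(fit)[1L])
  out$r_squared <- suppressWarnings(summary(fit)$r.squared)
  out$ca_range_used <- c(lo, hi)
  out$n_points <- length(sel)
  out$flags <- character(0)
  if (out$beta < 1) out$flags <- c(out$flags, "beta < 1")
  if (is.finite(out$r_squared) && out$r_squared < r2_floor)
    out$flags <- c(out$flags, sprintf("r_squared %.3f below %.2f",
                                      out$r_squared, r2_floor))
  out$flagged <- length(out$flags) > 0L
  out
}

#' Slope of the NCX current-density vs free-Ca relationship
#'
#' Ordinary least-squares regression of the inward NCX current density on the
#' simultaneous free Ca over the decay phase of a caffeine transient. The
#' inward deflection below the pre-caffeine baseline is taken positive, so
#' the returned slope is the NCX coefficient in pA/pF per nmol/l.
#'
#' @inheritParams buffer_power_fit
#' @param cm membrane capacitance, pF (used to express current as density).
#' @return list with `slope` (pA/pF per nmol/l), `intercept` (pA/pF),
#'   `r_squared`, `n_points`.
#' @export
ncx_ca_slope <- function(time, ca_free, i_current, caffeine_time, cm,
                         baseline_s = 2, window_end = max(time)) {
  pre <- which(time >= caffeine_time - baseline_s & time < caffeine_time)
  if (length(pre) < 10L)
    stop("ncx_ca_slope: too few pre-caffeine baseline samples")
  baseline <- median(i_current[pre])
  win <- which(time >= caffeine_time & time <= window_end)
  free <- ca_free[win]
  ok <- !is.na(free)
  pk_i <- which.max(ifelse(ok, free, -Inf))
  sel <- win[seq.int(pk_i, length(win))]
  sel <- sel[!is.na(ca_free[sel])]
  if (length(sel) < 10L) stop("ncx_ca_slope: fewer than 10 paired samples")
  dens <- (baseline - i_current[sel]) / cm
  fit <- lm(dens ~ ca_free[sel])
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n_points = length(sel))
}
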