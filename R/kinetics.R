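#' Fit a mono-exponential decay A * exp(-k * (t - t0)) + C
#'
#' Least-squares fit of a single exponential to the decay phase of a
#' transient, the standard description of cytosolic Ca removal. Initial
#' values come from a log-linear regression; the fit is refined by
#' Levenberg-Marquardt ([minpack.lm::nlsLM]). Fits with k <= 0, with RMSE
#' above `max_rmse_frac` of the fitted amplitude, or that fail to converge
#' are returned flagged (`accepted = FALSE`) rather than dropped, so the
#' caller can report them.
#'
#' @param time time vector, s.
#' @param y signal (calibrated Ca, current deflection, ...), decreasing
#'   overall; `NA` samples are ignored.
#' @param window `c(t_start, t_end)` fit window, s (default: whole trace).
#' @param max_rmse_frac acceptance threshold on RMSE as a fraction of the
#'   fitted amplitude.
#' @param min_samples minimum samples required in the window.
#' @return list with `k` (1/s), `amplitude` (signal units, at the window
#'   start), `offset`, `rmse`, `fit_window`, `accepted`, `reason`.
#' @examples
#' t <- seq(0, 1, by = 0.002)
#' f <- fit_mono_exponential_decay(t, 50 * exp(-8.99 * t) + 60)
#' f$k  # 8.99
#' @export
fit_mono_exponential_decay <- function(time, y, window = range(time),
                                       max_rmse_frac = 0.1,
                                       min_samples = 20L) {
  keep <- which(time >= window[1L] & time <= window[2L] & !is.na(y))
  if (length(keep) < min_samples)
    stop(sprintf("fit_mono_exponential_decay: %d samples in window, need >= %d",
                 length(keep), min_samples))
  t <- time[keep] - time[keep[1L]]
  z <- y[keep]
  out <- list(k = NA_real_, amplitude = NA_real_, offset = NA_real_,
              rmse = NA_real_, fit_window = c(time[keep[1L]],
                                              time[keep[length(keep)]]),
              accepted = FALSE, reason = "")
  rng <- diff(range(z))
  if (rng <= .Machine$double.eps * max(1, abs(z[1L]))) {
    out$reason <- "degenerate: constant signal"
    return(out)
  }
  # log-linear start values with a small offset guard
  c0 <- min(z) - 0.05 * rng
  pos <- z - c0
  init <- tryCatch(unname(coef(lm(log(pos) ~ t))), error = function(e) NULL)
  if (is.null(init) || !is.finite(init[2L]) || init[2L] >= 0)
    init <- c(log(rng), -1 / max(t[length(t)], 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(z ~ A * exp(-k * t) + C,
                      start = list(A = exp(init[1L]), k = -init[2L], C = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out$reason <- paste("non-convergence:", conditionMessage(fit))
    return(out)
  }
  cf <- coef(fit)
  out$k <- unname(cf["k"])
  out$amplitude <- unname(cf["A"])
  out$offset <- unname(cf["C"])
  out$rmse <- sqrt(mean(residuals(fit)^2))
  if (!is.finite(out$k) || out$k <= 0) {
    out$reason <- "k <= 0"
  } else if (out$rmse > max_rmse_frac * abs(out$amplitude)) {
    out$reason <- sprintf("rmse %.3g above %.3g x amplitude",
                          out$rmse, max_rmse_frac)
  } else {
    out$accepted <- TRUE
  }
  out
}

#' @importFrom stats residuals
NULL

#' Per-beat transient metrics: diastolic level, peak, amplitude, decay rate
#'
#' For each stimulus: the diastolic level is the mean over a pre-stimulus
#' window, the peak is the maximum within a post-stimulus window, amplitude
#' their difference. The decay rate constant comes from a mono-exponential
#' fit between the samples where the signal has fallen to `fit_start_frac`
#' and `fit_end_frac` of the amplitude above diastole; the fit start is
#' additionally deferred to `fit_after` seconds past the stimulus (use the
#' depolarizing-step duration, so that ongoing L-type entry does not
#' contaminate the removal fit).
#'
#' @param time time vector, s.
#' @param ca calibrated free-Ca series, nmol/l (`NA` allowed).
#' @param stim_times stimulus onset times, s (each inside the trace).
#' @param pre_window_s diastolic averaging window before the stimulus, s.
#' @param post_window_s peak search window after the stimulus, s.
#' @param fit_start_frac,fit_end_frac decay-fit bounds as fractions of the
#'   amplitude remaining above diastole.
#' @param fit_after defer the decay-fit start to this long after the
#'   stimulus, s (default 0).
#' @param max_rmse_frac passed to [fit_mono_exponential_decay()].
#' @return data.frame with one row per stimulus: `beat`, `stim_time`,
#'   `diastolic_ca`, `peak_ca`, `amplitude`, `t_peak`, `k_decay`, `fit_rmse`,
#'   `fit_start`, `fit_end`, `accepted`, `reason`.
#' @export
transient_metrics <- function(time, ca, stim_times,
                              pre_window_s = 0.2, post_window_s = 0.3,
                              fit_start_frac = 0.9, fit_end_frac = 0.1,
                              fit_after = 0, max_rmse_frac = 0.1) {
  if (length(stim_times) < 1L) stop("transient_metrics: need >= 1 stimulus")
  if (any(stim_times < min(time) | stim_times > max(time)))
    stop("transient_metrics: stimulus outside trace")
  rows <- lapply(seq_along(stim_times), function(b) {
    s <- stim_times[b]
    pre <- ca[time >= s - pre_window_s & time < s]
    dia <- mean(pre, na.rm = TRUE)
    post_idx <- which(time >= s & time <= s + post_window_s)
    seg <- ca[post_idx]
    if (!length(seg) || all(is.na(seg)))
      return(data.frame(beat = b, stim_time = s, diastolic_ca = dia,
                        peak_ca = NA_real_, amplitude = NA_real_,
                        t_peak = NA_real_, k_decay = NA_real_,
                        fit_rmse = NA_real_, fit_start = NA_real_,
                        fit_end = NA_real_, accepted = FALSE,
                        reason = "no samples after stimulus"))
    pk_i <- post_idx[which.max(seg)]
    peak <- ca[pk_i]
    amp <- peak - dia
    t_peak <- time[pk_i]
    # decay window: threshold crossings after the peak
    lim <- max(time)
    nxt <- stim_times[stim_times > s]
    if (length(nxt)) lim <- min(lim, nxt[1L])
    decay_idx <- which(time > t_peak & time < lim & !is.na(ca))
    fit <- list(k = NA_real_, rmse = NA_real_, accepted = FALSE,
                reason = "no decay samples",
                fit_window = c(NA_real_, NA_real_))
    if (length(decay_idx) && amp > 0) {
      td <- time[decay_idx]; cd <- ca[decay_idx]
      hi <- td[cd <= dia + fit_start_frac * amp]
      t_start <- if (length(hi)) hi[1L] else td[1L]
      t_start <- max(t_start, s + fit_after)
      lo <- td[cd <= dia + fit_end_frac * amp & td > t_start]
      t_end <- if (length(lo)) lo[1L] else td[length(td)]
      fit <- tryCatch(
        fit_mono_exponential_decay(time, ca, window = c(t_start, t_end),
                                   max_rmse_frac = max_rmse_frac),
        error = function(e) list(k = NA_real_, rmse = NA_real_,
                                 accepted = FALSE,
                                 reason = conditionMessage(e),
                                 fit_window = c(t_start, t_end)))
    }
    data.frame(beat = b, stim_time = s, diastolic_ca = dia, peak_ca = peak,
               amplitude = amp, t_peak = t_peak, k_decay = fit$k,
               fit_rmse = fit$rmse, fit_start = fit$fit_window[1L],
               fit_end = fit$fit_window[2L], accepted = fit$accepted,
               reason = fit$reason)
  })
  do.call(rbind, rows)
}

#' Decompose removal rate constants into SR and sarcolemmal components
#'
#' The SR-dependent removal rate is the difference between the systolic and
#' caffeine decay rate constants, k_sr = k_sys - k_caff (SERCA competes with
#' sarcolemmal extrusion during a twitch but is futile during caffeine).
#' A negative k_sr is reported as-is and flagged, never clamped.
#'
#' @param k_sys systolic decay rate constant, 1/s.
#' @param k_caff caffeine decay rate constant, 1/s.
#' @param k_pmca optional PMCA-only rate constant (NCX blocked), 1/s.
#' @return list with `k_sys`, `k_caff`, `k_sr`, `k_pmca`, `flagged`.
#' @export
decompose_rates <- function(k_sys, k_caff, k_pmca = NA_real_) {
  k_sr <- k_sys - k_caff
  flagged <- character(0)
  if (is.finite(k_sr) && k_sr < 0) flagged <- c(flagged, "k_sr < 0")
  if (is.finite(k_pmca) && is.finite(k_caff) && k_pmca > k_caff)
    flagged <- c(flagged, "k_pmca > k_caff")
  list(k_sys = k_sys, k_caff = k_caff, k_sr = k_sr, k_pmca = k_pmca,
       flagged = flagged)
}

#' Action-potential duration at a fractional repolarization level
#'
#' Measures the time from the point of maximum upstroke velocity (max dV/dt)
#' to the first crossing of peak - fraction * (peak - baseline), with linear
#' interpolation between samples. The baseline is the mean potential over the
#' samples preceding the upstroke.
#'
#' @param time time vector, s.
#' @param vm membrane potential, mV; must contain one AP (upstroke then
#'   repolarization).
#' @param fraction repolarization fraction in (0, 1); 0.9 gives APD90.
#' @return duration, ms.
#' @export
apd <- function(time, vm, fraction = 0.9) {
  if (fraction <= 0 || fraction >= 1) stop("apd: fraction must be in (0, 1)")
  if (length(vm) < 3L) stop("apd: trace too short")
  dv <- diff(vm) / diff(time)
  i_up <- which.max(dv)
  t_up <- time[i_up]
  baseline <- if (i_up > 1L) mean(vm[seq_len(i_up)]) else vm[1L]
  after <- seq.int(i_up, length(vm))
  pk_rel <- which.max(vm[after])
  i_pk <- after[pk_rel]
  peak <- vm[i_pk]
  level <- peak - fraction * (peak - baseline)
  below <- which(vm <= level & seq_along(vm) > i_pk)
  if (!length(below))
    stop(sprintf("apd: trace never repolarizes to the %.0f%% level",
                 100 * fraction))
  j <- below[1L]
  # linear interpolation between j-1 and j
  t_cross <- time[j - 1L] +
    (level - vm[j - 1L]) / (vm[j] - vm[j - 1L]) * (time[j] - time[j - 1L])
  1000 * (t_cross - t_up)
}
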