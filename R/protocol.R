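#' Stimulation protocols for the myocyte simulator
#'
#' Builds a validated protocol description. Modes:
#' \describe{
#'   \item{`voltage_step`}{regular square depolarizing steps (default
#'     -40 mV holding, +50 mV step of 100 ms at 0.5 Hz).}
#'   \item{`ap_clamp`}{a user-supplied command action-potential waveform
#'     replayed at the stimulation frequency.}
#'   \item{`caffeine`}{steady-state pacing followed by rapid application of
#'     caffeine, which empties the SR and keeps its release channels open so
#'     SERCA uptake is futile; the recorded inward NCX current tail is the
#'     basis of the SR-content assay.}
#'   \item{`caffeine_ni`}{as `caffeine` but with NCX blocked (Ni2+) from the
#'     moment of caffeine application, isolating PMCA-mediated removal.}
#' }
#' The first stimulus is delivered after half a pacing period of rest so every
#' trace starts with a diastolic baseline; caffeine is applied
#' `pre_caffeine_s` after the post-pacing rest period.
#'
#' @param mode one of `"voltage_step"`, `"ap_clamp"`, `"caffeine"`,
#'   `"caffeine_ni"`.
#' @param hold_mV holding potential, mV.
#' @param step_mV step amplitude, mV (voltage_step and caffeine modes).
#' @param step_dur_s step duration, s.
#' @param freq_hz stimulation frequency, Hz.
#' @param n_beats number of stimuli before readout (>= 1).
#' @param waveform data.frame with columns `time_s`, `vm_mV`: the command AP
#'   for `ap_clamp` (required there, forbidden elsewhere).
#' @param condition condition label passed to [apply_condition()].
#' @param pre_caffeine_s rest between the end of pacing and caffeine onset, s.
#' @param record_caffeine_s recording time after caffeine onset, s.
#' @return an object of class `protocol`.
#' @export
protocol <- function(mode = c("voltage_step", "ap_clamp", "caffeine",
                              "caffeine_ni"),
                     hold_mV = -40, step_mV = 50, step_dur_s = 0.1,
                     freq_hz = 0.5, n_beats = 10, waveform = NULL,
                     condition = "none",
                     pre_caffeine_s = 1, record_caffeine_s = 12) {
  mode <- match.arg(mode)
  if (n_beats < 1) stop("protocol: n_beats must be >= 1")
  if (mode != "ap_clamp" && step_dur_s <= 0)
    stop("protocol: step_dur_s must be > 0")
  if (freq_hz <= 0) stop("protocol: freq_hz must be > 0")
  if (mode == "ap_clamp") {
    if (is.null(waveform))
      stop("protocol: ap_clamp requires a command waveform")
    if (!all(c("time_s", "vm_mV") %in% names(waveform)))
      stop("protocol: waveform needs columns time_s, vm_mV")
    if (max(waveform$time_s) > 1 / freq_hz)
      stop("protocol: waveform longer than the pacing period")
  } else if (!is.null(waveform)) {
    stop("protocol: waveform is only valid for ap_clamp")
  }
  structure(list(mode = mode, hold_mV = hold_mV, step_mV = step_mV,
                 step_dur_s = step_dur_s, freq_hz = freq_hz,
                 n_beats = as.integer(n_beats), waveform = waveform,
                 condition = condition, pre_caffeine_s = pre_caffeine_s,
                 record_caffeine_s = record_caffeine_s),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol> %s: %d beats at %g Hz, condition %s\n",
              x$mode, x$n_beats, x$freq_hz, x$condition))
  invisible(x)
}

# event times implied by a protocol (shared by simulate_myocyte and tests)
protocol_schedule <- function(protocol) {
  period <- 1 / protocol$freq_hz
  t0 <- period / 2
  stim <- t0 + (seq_len(protocol$n_beats) - 1L) * period
  caff <- if (protocol$mode %in% c("caffeine", "caffeine_ni"))
    stim[length(stim)] + period + protocol$pre_caffeine_s else Inf
  t_end <- if (is.finite(caff)) caff + protocol$record_caffeine_s
    else stim[length(stim)] + period
  list(stim_times = stim, caffeine_time = caff, t_end = t_end)
}

#' Synthetic action-potential command waveform
#'
#' Builds a smooth atrial-like command AP: a 1-ms upstroke followed by a
#' quadratic repolarization scaled so that the 90% repolarization time equals
#' `apd90_ms`. Intended for `ap_clamp` protocols and for testing APD
#' measurement; it is a geometric template, not a mechanistic AP model.
#'
#' @param apd90_ms target APD90, ms.
#' @param rest_mV resting potential, mV.
#' @param peak_mV peak potential, mV.
#' @param dt_s sample interval, s.
#' @return data.frame with columns `time_s`, `vm_mV`.
#' @export
make_ap_template <- function(apd90_ms = 357, rest_mV = -75, peak_mV = 25,
                             dt_s = 1e-3) {
  # repolarization profile r(s) = 1 - s^2 crosses 10% of the range at
  # s = sqrt(0.9); scaled so APD90 measured from the upstroke equals apd90_ms
  up_s <- 1e-3
  rep_s <- (apd90_ms / 1000 - up_s) / sqrt(0.9)
  t <- seq(0, up_s + rep_s, by = dt_s)
  vm <- ifelse(t <= up_s,
               rest_mV + (peak_mV - rest_mV) * t / up_s,
               rest_mV + (peak_mV - rest_mV) *
                 pmax(0, 1 - ((t - up_s) / rep_s)^2))
  data.frame(time_s = t, vm_mV = vm)
}
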