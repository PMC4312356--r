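#' Cellular Ca economy arithmetic
#'
#' The per-cell Ca-economy quantities derived from four measured primaries:
#' systolic free-Ca amplitude, buffering power, integrated L-type entry and
#' SR content.
#' \describe{
#'   \item{`total_ca_transient(beta, d_sys_ca)`}{total cytosolic Ca needed to
#'     produce the free-Ca rise: beta * amplitude, converted nmol/l to
#'     umol/l.}
#'   \item{`delta_sr_systole(total, entry)`}{SR Ca released per beat: the
#'     total transient minus the L-type entry.}
#'   \item{`fractional_release(d_sr, sr_content)`}{fraction of the SR content
#'     released per beat.}
#'   \item{`ec_gain(d_sr, entry)`}{excitation-contraction coupling gain: SR
#'     Ca released per unit trigger entry.}
#' }
#'
#' @param beta buffering power (dimensionless, > 0).
#' @param d_sys_ca systolic free-Ca amplitude, nmol/l (>= 0).
#' @return `total_ca_transient`: umol/l.
#' @examples
#' total_ca_transient(565, 83)                  # 46.9 umol/l
#' ec_gain(delta_sr_systole(46.9, 0.74), 0.74)  # 62.4
#' @export
total_ca_transient <- function(beta, d_sys_ca) {
  stopifnot(beta > 0, d_sys_ca >= 0)
  beta * d_sys_ca * 1e-3
}

#' @rdname total_ca_transient
#' @param total_transient total Ca transient, umol/l.
#' @param int_ical integrated L-type Ca entry, umol/l.
#' @return `delta_sr_systole`: umol/l (negative values indicate entry
#'   exceeding the total transient and are the caller's cue to flag the
#'   cell).
#' @export
delta_sr_systole <- function(total_transient, int_ical) {
  total_transient - int_ical
}

#' @rdname total_ca_transient
#' @param d_sr_systole SR Ca released during systole, umol/l.
#' @param sr_content SR Ca content, umol/l (> 0).
#' @return `fractional_release`: dimensionless (expected in [0, 1]).
#' @export
fractional_release <- function(d_sr_systole, sr_content) {
  if (!is.numeric(sr_content) || any(sr_content <= 0))
    stop("fractional_release: sr_content must be > 0")
  d_sr_systole / sr_content
}

#' @rdname total_ca_transient
#' @return `ec_gain`: dimensionless.
#' @export
ec_gain <- function(d_sr_systole, int_ical) {
  if (!is.numeric(int_ical) || any(int_ical <= 0))
    stop("ec_gain: int_ical must be > 0")
  d_sr_systole / int_ical
}

#' Percent change of a comparison mean relative to a reference mean
#'
#' Arithmetic contrast 100 * (reference - comparison) / reference: positive
#' for a reduction, negative for an increase (an increase of x% is returned
#' as -x). The sign convention is deliberate so that "reduced by 28%" is the
#' number 28.
#'
#' @param reference_mean reference (e.g. control) group mean, nonzero.
#' @param comparison_mean comparison (e.g. disease) group mean.
#' @return signed percent change.
#' @examples
#' percent_change(565, 318)  # 43.7 (a 43.7% reduction)
#' @export
percent_change <- function(reference_mean, comparison_mean) {
  if (!is.numeric(reference_mean) || any(reference_mean == 0))
    stop("percent_change: reference mean must be nonzero")
  100 * (reference_mean - comparison_mean) / reference_mean
}

#' Assemble the per-cell Ca-economy table
#'
#' Computes every derived economy quantity from the four measured primaries
#' and checks the exact identities that tie them together. Also exposes the
#' post-release SR content (`sr_content_post_release`, the SR content minus
#' the systolic release), an alternative bookkeeping of the same numbers.
#'
#' @param d_sys_ca systolic free-Ca amplitude, nmol/l.
#' @param beta buffering power.
#' @param int_ical integrated L-type entry, umol/l.
#' @param sr_content SR Ca content, umol/l.
#' @return list with `d_sys_ca`, `beta`, `total_transient`, `int_ical`,
#'   `sr_content`, `d_sr_systole`, `sr_content_post_release`,
#'   `fractional_release`, `ec_gain`, `flags`.
#' @export
economy_table <- function(d_sys_ca, beta, int_ical, sr_content) {
  total <- total_ca_transient(beta, d_sys_ca)
  d_sr <- delta_sr_systole(total, int_ical)
  fr <- fractional_release(d_sr, sr_content)
  gain <- ec_gain(d_sr, int_ical)
  flags <- character(0)
  if (d_sr < 0) flags <- c(flags, "entry exceeds total transient")
  if (fr < 0 || fr > 1) flags <- c(flags, "fractional release outside [0, 1]")
  list(d_sys_ca = d_sys_ca, beta = beta, total_transient = total,
       int_ical = int_ical, sr_content = sr_content, d_sr_systole = d_sr,
       sr_content_post_release = sr_content - d_sr,
       fractional_release = fr, ec_gain = gain, flags = flags)
}
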