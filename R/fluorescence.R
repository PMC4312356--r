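#' Fluorescent dye models
#'
#' `fluo5f_dye()` is a single-wavelength saturation model,
#' F = f_max * ca / (ca + kd), with the Ca2+ dissociation constant defaulting
#' to 1035 nmol/l. `fura2_dye()` is the standard two-wavelength ratiometric
#' saturation form R = (r_min * k_eff + r_max * ca) / (k_eff + ca). The Fura-2
#' constants are instrument-specific; the defaults are plausible in-vitro
#' values, not published ones, and place the control resting ratio at
#' ~0.44 for 60.7 nmol/l resting Ca.
#'
#' @param kd single-wavelength dye dissociation constant, nmol/l.
#' @param f_max saturating fluorescence, arbitrary units.
#' @param r_min,r_max ratio at zero and saturating Ca.
#' @param k_eff effective dissociation constant (Kd times the free/bound
#'   long-wavelength sensitivity ratio), nmol/l.
#' @return a dye model object (class `dye_model`).
#' @export
fluo5f_dye <- function(kd = 1035, f_max = 100) {
  stopifnot(kd > 0, f_max > 0)
  structure(list(type = "fluo5f", kd = kd, f_max = f_max),
            class = "dye_model")
}

#' @rdname fluo5f_dye
#' @export
fura2_dye <- function(r_min = 0.30, r_max = 3.00, k_eff = 1100) {
  if (!(r_max > r_min && r_min > 0)) stop("fura2_dye: need r_max > r_min > 0")
  if (k_eff <= 0) stop("fura2_dye: k_eff must be > 0")
  structure(list(type = "fura2", r_min = r_min, r_max = r_max, k_eff = k_eff),
            class = "dye_model")
}

#' Emit a fluorescence signal from a free-Ca time series
#'
#' Applies the dye's saturation curve and optional additive Gaussian noise.
#' The noiseless emission composed with the matching calibration
#' ([fluo_selfratio_to_ca()] or [fura_ratio_to_ca()]) returns the input Ca
#' exactly (round-trip identity, up to floating point).
#'
#' @param ca_free free Ca series, nmol/l (> 0).
#' @param dye a [fluo5f_dye()] or [fura2_dye()] model.
#' @param noise_sd Gaussian noise SD as a fraction of the resting signal.
#' @param ca_rest resting Ca used to scale the noise, nmol/l; defaults to the
#'   first sample.
#' @param seed optional integer seed applied before drawing noise.
#' @return numeric signal series (a.u. for fluo, dimensionless for fura).
#' @export
emit_fluorescence <- function(ca_free, dye, noise_sd = 0,
                              ca_rest = ca_free[1L], seed = NULL) {
  if (any(!is.finite(ca_free)) || any(ca_free <= 0))
    stop("emit_fluorescence: ca_free must be finite and > 0")
  if (!inherits(dye, "dye_model")) stop("emit_fluorescence: not a dye_model")
  f <- if (dye$type == "fluo5f") {
    dye$f_max * ca_free / (ca_free + dye$kd)
  } else {
    (dye$r_min * dye$k_eff + dye$r_max * ca_free) / (dye$k_eff + ca_free)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    rest <- if (dye$type == "fluo5f") {
      dye$f_max * ca_rest / (ca_rest + dye$kd)
    } else {
      (dye$r_min * dye$k_eff + dye$r_max * ca_rest) / (dye$k_eff + ca_rest)
    }
    f <- f + rnorm(length(f), 0, noise_sd * rest)
  }
  f
}
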