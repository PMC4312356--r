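#' Analysis configuration
#'
#' One object holding every tunable of the per-cell analysis. Defaults
#' follow the protocols the traces are recorded under: 0.5 Hz pacing with
#' 100 ms steps, rapid caffeine after steady-state stimulation.
#'
#' @param dye_kd single-wavelength dye dissociation constant, nmol/l.
#' @param fura a [fura_calibration()] used to anchor resting Ca.
#' @param anchor `"fura"` to measure each cell's resting Ca from its resting
#'   Fura-2 ratio (the trace column `fura_ratio`), or a fixed resting-Ca
#'   value in nmol/l.
#' @param n_beats_avg number of final beats averaged for the systolic
#'   metrics.
#' @param pre_window_s,post_window_s diastolic and peak windows around each
#'   stimulus, s.
#' @param fit_start_frac,fit_end_frac decay-fit bounds (fractions of
#'   amplitude).
#' @param max_rmse_frac decay-fit acceptance threshold.
#' @param caffeine_peak_window_s peak search window after caffeine onset, s.
#' @param baseline_s pre-caffeine current baseline window, s.
#' @param pmca_share PMCA share used for the SR-content correction when no
#'   NCX-blocked (caffeine_ni) trace is available; `NULL` disables the
#'   correction.
#' @param peak_smooth samples in the running mean applied to the L-type
#'   current before peak detection; the default (1) uses the raw samples,
#'   because smoothing clips a fast-inactivating peak, while the max-of-noise
#'   bias at realistic current noise is small.
#' @param buffer_range_frac regression trimming fraction for
#'   [buffer_power_fit()].
#' @param r2_floor buffering-fit r-squared flag threshold.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(dye_kd = 1035, fura = fura_calibration(),
                            anchor = "fura", n_beats_avg = 3,
                            pre_window_s = 0.2, post_window_s = 0.3,
                            fit_start_frac = 0.9, fit_end_frac = 0.1,
                            max_rmse_frac = 0.1,
                            caffeine_peak_window_s = 2,
                            baseline_s = 2, pmca_share = NULL,
                            peak_smooth = 1L, buffer_range_frac = 0.1,
                            r2_floor = 0.9) {
  structure(list(dye_kd = dye_kd, fura = fura, anchor = anchor,
                 n_beats_avg = n_beats_avg, pre_window_s = pre_window_s,
                 post_window_s = post_window_s,
                 fit_start_frac = fit_start_frac,
                 fit_end_frac = fit_end_frac, max_rmse_frac = max_rmse_frac,
                 caffeine_peak_window_s = caffeine_peak_window_s,
                 baseline_s = baseline_s, pmca_share = pmca_share,
                 peak_smooth = as.integer(peak_smooth),
                 buffer_range_frac = buffer_range_frac,
                 r2_floor = r2_floor),
            class = "analysis_config")
}

# calibrate one trace's fluorescence to free Ca, anchoring resting Ca either
# on the resting Fura-2 ratio of the same cell or on a configured value
calibrate_trace <- function(trace, rest_end_s, config) {
  rest <- trace$time_s < rest_end_s
  if (!any(rest)) stop("calibrate_trace: no resting samples before stimulus")
  f_rest <- mean(trace$fluo_au[rest])
  if (identical(config$anchor, "fura") && "fura_ratio" %in% names(trace)) {
    r_rest <- mean(trace$fura_ratio[rest])
    ca_rest <- as.numeric(fura_ratio_to_ca(r_rest, config$fura))
  } else if (is.numeric(config$anchor)) {
    ca_rest <- config$anchor
  } else {
    stop("calibrate_trace: no fura_ratio column and no numeric anchor")
  }
  calib <- fluo_selfratio_calibration(kd = config$dye_kd, ca_rest = ca_rest,
                                      f_rest = f_rest)
  ca <- suppressWarnings(fluo_selfratio_to_ca(trace$fluo_au, calib,
                                              saturated = "mask"))
  list(ca = as.numeric(ca), n_saturated = length(attr(ca, "flagged")),
       ca_rest_anchor = ca_rest, f_rest = f_rest)
}

#' Analyze one cell record
#'
#' Runs the full per-cell analysis: self-ratio calibration of each
#' fluorescence trace (resting Ca anchored per cell on the Fura-2 ratio),
#' systolic transient metrics and decay rate over the final beats, caffeine
#' transient decay (and PMCA-only decay when an NCX-blocked trace exists),
#' SR content from the integrated caffeine current, buffering power, NCX
#' slope, peak and integrated L-type current, and the economy table.
#'
#' @param record a [cell_record()] with a `systolic` trace and, for the
#'   flux measurements, a `caffeine` trace (optional `caffeine_ni`).
#' @param config an [analysis_config()].
#' @return list of per-cell results with all intermediates and a `flags`
#'   character vector.
#' @export
analyze_cell <- function(record, config = analysis_config()) {
  stopifnot(inherits(record, "cell_record"))
  geom <- record$geometry
  flags <- character(0)
  res <- list(cell_id = record$cell_id, animal_id = record$animal_id,
              group = record$group, condition = record$condition,
              cm = geom$cm, sa_to_vol = geom$sa_to_vol, volume = geom$volume)

  ## systolic trace ---------------------------------------------------------
  if (is.null(record$traces$systolic)) stop("record lacks a systolic trace")
  tr <- record$traces$systolic
  pm <- record$protocols$systolic
  stim <- pm$stim_times
  cal <- calibrate_trace(tr, rest_end_s = stim[1L], config)
  if (cal$n_saturated > 0)
    flags <- c(flags, sprintf("systolic: %d saturated samples masked",
                              cal$n_saturated))
  res$ca_rest_anchor <- cal$ca_rest_anchor
  last_stims <- tail(stim, config$n_beats_avg)
  tm <- transient_metrics(tr$time_s, cal$ca, last_stims,
                          pre_window_s = config$pre_window_s,
                          post_window_s = config$post_window_s,
                          fit_start_frac = config$fit_start_frac,
                          fit_end_frac = config$fit_end_frac,
                          fit_after = pm$step_dur_s,
                          max_rmse_frac = config$max_rmse_frac)
  res$diastolic_ca <- mean(tm$diastolic_ca)
  res$amplitude <- mean(tm$amplitude)
  acc <- tm$accepted
  if (!any(acc)) {
    flags <- c(flags, "systolic: no accepted decay fit")
    res$k_sys <- NA_real_
  } else {
    res$k_sys <- mean(tm$k_decay[acc])
    if (!all(acc))
      flags <- c(flags, sprintf("systolic: %d/%d decay fits rejected",
                                sum(!acc), length(acc)))
  }

  # L-type current: peak density from the lightly smoothed trace, entry from
  # the baseline-subtracted integral over the step, averaged over last beats
  ical_base <- median(tr$i_cal_pA[tr$time_s < stim[1L]])
  sm <- running_mean(tr$i_cal_pA, config$peak_smooth)
  peaks <- entries <- numeric(length(last_stims))
  for (i in seq_along(last_stims)) {
    s <- last_stims[i]
    win <- tr$time_s >= s & tr$time_s <= s + pm$step_dur_s
    peaks[i] <- max(ical_base - sm[win]) / geom$cm
    entries[i] <- integrate_cal_entry(tr$time_s, tr$i_cal_pA - ical_base,
                                      c(s, s + pm$step_dur_s), geom)
  }
  res$peak_ical_density <- mean(peaks)
  res$int_ical <- mean(entries)

  ## caffeine trace ---------------------------------------------------------
  if (!is.null(record$traces$caffeine)) {
    trc <- record$traces$caffeine
    pmc <- record$protocols$caffeine
    t_caff <- pmc$caffeine_time
    calc <- calibrate_trace(trc, rest_end_s = pmc$stim_times[1L], config)
    if (calc$n_saturated > 0)
      flags <- c(flags, sprintf("caffeine: %d saturated samples masked",
                                calc$n_saturated))
    tmc <- transient_metrics(trc$time_s, calc$ca, t_caff,
                             pre_window_s = config$pre_window_s,
                             post_window_s = config$caffeine_peak_window_s,
                             fit_start_frac = config$fit_start_frac,
                             fit_end_frac = config$fit_end_frac,
                             max_rmse_frac = config$max_rmse_frac)
    res$caffeine_amplitude <- tmc$amplitude[1L]
    res$k_caff <- if (tmc$accepted[1L]) tmc$k_decay[1L] else NA_real_
    if (!tmc$accepted[1L])
      flags <- c(flags, paste("caffeine: decay fit rejected:", tmc$reason[1L]))

    res$k_pmca <- NA_real_
    if (!is.null(record$traces$caffeine_ni)) {
      trn <- record$traces$caffeine_ni
      pmn <- record$protocols$caffeine_ni
      caln <- calibrate_trace(trn, rest_end_s = pmn$stim_times[1L], config)
      tmn <- transient_metrics(trn$time_s, caln$ca, pmn$caffeine_time,
                               pre_window_s = config$pre_window_s,
                               post_window_s = config$caffeine_peak_window_s,
                               fit_start_frac = config$fit_start_frac,
                               fit_end_frac = config$fit_end_frac,
                               max_rmse_frac = config$max_rmse_frac)
      if (tmn$accepted[1L]) res$k_pmca <- tmn$k_decay[1L]
      else flags <- c(flags, "caffeine_ni: decay fit rejected")
    }

    dec <- decompose_rates(res$k_sys, res$k_caff, res$k_pmca)
    res$k_sr <- dec$k_sr
    flags <- c(flags, dec$flagged)

    use_kp <- if (is.finite(res$k_pmca)) res$k_pmca else NULL
    use_share <- if (is.finite(res$k_pmca)) NULL else config$pmca_share
    src <- integrate_ncx_sr_content(trc$time_s, trc$i_total_pA, t_caff, geom,
                                    k_caff = res$k_caff, k_pmca = use_kp,
                                    pmca_share = use_share,
                                    baseline_s = config$baseline_s)
    res$sr_content <- src$sr_content
    res$ncx_charge <- src$ncx_charge
    res$pmca_correction_factor <- src$pmca_correction_factor
    if (src$flagged) flags <- c(flags, paste("sr_content:", src$flags))

    buf <- buffer_power_fit(trc$time_s, calc$ca, trc$i_total_pA, t_caff,
                            geom, k_caff = res$k_caff, k_pmca = use_kp,
                            pmca_share = use_share,
                            baseline_s = config$baseline_s,
                            range_frac = config$buffer_range_frac,
                            r2_floor = config$r2_floor)
    res$beta <- buf$beta
    res$beta_r_squared <- buf$r_squared
    if (buf$flagged) flags <- c(flags, paste("buffering:", buf$flags))

    slp <- tryCatch(
      ncx_ca_slope(trc$time_s, calc$ca, trc$i_total_pA, t_caff,
                   cm = geom$cm, baseline_s = config$baseline_s),
      error = function(e) {
        flags <<- c(flags, paste("ncx_slope:", conditionMessage(e)))
        list(slope = NA_real_, r_squared = NA_real_)
      })
    res$ncx_slope <- slp$slope
    res$ncx_slope_r_squared <- slp$r_squared
  }

  ## economy ---------------------------------------------------------------
  if (!is.null(res$beta) && is.finite(res$beta) &&
      is.finite(res$amplitude) && is.finite(res$int_ical) &&
      !is.null(res$sr_content) && is.finite(res$sr_content) &&
      res$int_ical > 0 && res$sr_content > 0 && res$beta > 0) {
    eco <- economy_table(res$amplitude, res$beta, res$int_ical,
                         res$sr_content)
    res$total_transient <- eco$total_transient
    res$d_sr_systole <- eco$d_sr_systole
    res$fractional_release <- eco$fractional_release
    res$ec_gain <- eco$ec_gain
    flags <- c(flags, eco$flags)
  } else {
    res[c("total_transient", "d_sr_systole", "fractional_release",
          "ec_gain")] <- NA_real_
    flags <- c(flags, "economy: missing inputs")
  }
  res$flags <- flags
  res
}

#' Run the full analysis pipeline over a cohort
#'
#' Applies [analyze_cell()] to every record. Per-cell failures are isolated:
#' a failing cell contributes an error entry and the pipeline continues.
#' Results are deterministic given the inputs and configuration.
#'
#' @param cohort list of [cell_record()]s, or a directory written by
#'   [write_cell_record()].
#' @param config an [analysis_config()].
#' @param out_json optional path: write the full results as JSON.
#' @return list with `cells` (per-cell results), `table` (per-cell
#'   data.frame of the scalar measurements), `errors` and `flags`.
#' @export
run_pipeline <- function(cohort, config = analysis_config(),
                         out_json = NULL) {
  if (is.character(cohort)) {
    dir <- cohort
    ids <- sub("\\.json$", "", basename(Sys.glob(file.path(dir, "*.json"))))
    cohort <- lapply(ids, function(id) read_cell_record(dir, id))
  }
  cells <- list()
  errors <- list()
  for (rec in cohort) {
    r <- tryCatch(analyze_cell(rec, config), error = function(e)
      structure(list(cell_id = rec$cell_id, error = conditionMessage(e)),
                class = "cell_error"))
    if (inherits(r, "cell_error")) errors[[rec$cell_id]] <- r$error
    else cells[[rec$cell_id]] <- r
  }
  tab <- results_table(cells)
  out <- list(cells = cells, table = tab, errors = errors,
              flags = setNames(lapply(cells, `[[`, "flags"), names(cells)))
  if (!is.null(out_json))
    jsonlite::write_json(out[c("cells", "errors")], out_json,
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  out
}

scalar_fields <- c("cm", "sa_to_vol", "volume", "ca_rest_anchor",
                   "diastolic_ca", "amplitude", "k_sys", "k_caff", "k_pmca",
                   "k_sr", "peak_ical_density", "int_ical",
                   "caffeine_amplitude", "sr_content", "ncx_charge",
                   "pmca_correction_factor", "beta", "ncx_slope",
                   "total_transient", "d_sr_systole", "fractional_release",
                   "ec_gain")

#' Flatten per-cell results into a data.frame
#' @param cells list of [analyze_cell()] results.
#' @return data.frame, one row per cell.
#' @export
results_table <- function(cells) {
  if (!length(cells)) return(data.frame())
  rows <- lapply(cells, function(r) {
    vals <- lapply(scalar_fields, function(f)
      if (is.null(r[[f]]) || !length(r[[f]])) NA_real_ else as.numeric(r[[f]]))
    cbind(data.frame(cell_id = r$cell_id, animal_id = r$animal_id,
                     group = r$group, condition = r$condition,
                     n_flags = length(r$flags)),
          setNames(as.data.frame(vals), scalar_fields))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group summary of a per-cell variable, cell-level and animal-nested
#'
#' Returns for each group the cell-level mean and SEM (n = cells) and the
#' animal-nested mean and SEM (mean of per-animal means, n = animals).
#' Optionally summarizes on the log10 scale, the standard variance-
#' stabilizing transform for strictly positive cellular measurements.
#'
#' @param results a [run_pipeline()] result, or its `table`.
#' @param variable column name to summarize.
#' @param log10_transform summarize log10-transformed values.
#' @return data.frame, one row per group: `group`, `n_cells`, `n_animals`,
#'   `cell_mean`, `cell_sem`, `animal_mean`, `animal_sem`,
#'   `log10_transformed`.
#' @export
group_summary <- function(results, variable, log10_transform = FALSE) {
  tab <- if (is.data.frame(results)) results else results$table
  if (!variable %in% names(tab))
    stop("group_summary: unknown variable ", variable)
  sem <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0
  rows <- lapply(split(tab, tab$group), function(g) {
    x <- g[[variable]]
    keep <- is.finite(x)
    x <- x[keep]
    if (length(x) < 2L) stop("group_summary: fewer than 2 cells in group ",
                             g$group[1L])
    if (log10_transform) {
      if (any(x <= 0)) stop("group_summary: log10 needs positive values")
      x <- log10(x)
    }
    am <- vapply(split(x, g$animal_id[keep]), mean, numeric(1))
    data.frame(group = g$group[1L], n_cells = length(x),
               n_animals = length(am), cell_mean = mean(x),
               cell_sem = sem(x), animal_mean = mean(am),
               animal_sem = sem(am), log10_transformed = log10_transform)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
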