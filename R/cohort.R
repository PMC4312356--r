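#' Simulate a two-group cohort of cells with animal-nested variability
#'
#' Generates `n_animals` animals per group (control and heart failure), each
#' contributing `cells_per_animal` cells. Cell parameters are perturbed from
#' the group preset by a two-level mean-preserving lognormal scheme: one
#' multiplicative factor per animal (CV `cv_animal`) and one per cell
#' (CV `cv_cell`), applied to the biological parameters (peak I_CaL density,
#' SERCA rate, NCX coefficient, PMCA rate, release fraction, buffering power,
#' resting Ca and capacitance). The surface-area-to-volume ratio is held at
#' the preset value and each cell's initial SR content is set to its own
#' analytic pacing steady state, so traces start on the limit cycle.
#'
#' Each cell is simulated under every protocol in `protocols` (by default a
#' steady-state voltage-step run, a caffeine application and a caffeine
#' application with NCX blocked). Ground-truth parameters and truth-level
#' summaries (SR content at caffeine onset, amplitude, per-beat entry, decay
#' rate constants) are stored in every record.
#'
#' @param control_params,hf_params group base parameter sets
#'   ([sim_params()]); pass `hf_params = NULL` for a single-group cohort.
#' @param n_animals animals per group.
#' @param cells_per_animal cells per animal.
#' @param cv_animal,cv_cell coefficients of variation of the two lognormal
#'   levels (>= 0).
#' @param seed integer master seed; all animal, cell and trace noise draws
#'   derive from it.
#' @param protocols named list of [protocol()] objects simulated per cell.
#' @param out_dt,dt passed to [simulate_myocyte()].
#' @return list of `cell_record` objects (see [run_pipeline()]).
#' @export
make_cohort <- function(control_params, hf_params = NULL,
                        n_animals = 6, cells_per_animal = 4,
                        cv_animal = 0.1, cv_cell = 0.05, seed = 1L,
                        protocols = default_protocols(),
                        out_dt = 1e-3, dt = 1e-4) {
  stopifnot(n_animals >= 1, cells_per_animal >= 1,
            cv_animal >= 0, cv_cell >= 0)
  groups <- list(control = control_params)
  if (!is.null(hf_params)) groups$hf <- hf_params
  perturbed <- c("g_cal_peak", "k_serca", "g_ncx", "k_pmca_flux",
                 "frac_release", "beta", "ca_rest", "cm")
  records <- list()
  cell_no <- 0L
  set.seed(as.integer(seed))
  for (g in names(groups)) {
    base <- groups[[g]]
    for (a in seq_len(n_animals)) {
      animal_id <- sprintf("%s_animal%02d", g, a)
      a_fac <- lognormal_factors(length(perturbed), cv_animal)
      for (cidx in seq_len(cells_per_animal)) {
        cell_no <- cell_no + 1L
        c_fac <- lognormal_factors(length(perturbed), cv_cell)
        p <- unclass(base)
        for (k in seq_along(perturbed))
          p[[perturbed[k]]] <- p[[perturbed[k]]] * a_fac[k] * c_fac[k]
        p$seed <- as.integer(seed) + cell_no
        pars <- do.call(sim_params, p)
        pars$sr_init <- steady_state_sr(pars)
        records[[cell_no]] <- simulate_cell_record(
          pars, protocols,
          cell_id = sprintf("%s_cell%03d", g, cell_no),
          animal_id = animal_id, group = g, out_dt = out_dt, dt = dt)
      }
    }
  }
  records
}

default_protocols <- function(n_beats = 10) {
  list(systolic = protocol("voltage_step", n_beats = n_beats),
       caffeine = protocol("caffeine", n_beats = n_beats),
       caffeine_ni = protocol("caffeine_ni", n_beats = n_beats))
}

# mean-preserving lognormal multiplicative factors with coefficient of
# variation cv (exactly 1 when cv = 0)
lognormal_factors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

# run every protocol for one cell and package the results with ground truth
simulate_cell_record <- function(params, protocols, cell_id, animal_id,
                                 group = "control", out_dt = 1e-3, dt = 1e-4) {
  traces <- list()
  truth_summary <- list()
  for (nm in names(protocols)) {
    out <- simulate_myocyte(params, protocols[[nm]], out_dt = out_dt, dt = dt)
    traces[[nm]] <- as.data.frame(out)
    sched <- attr(out, "schedule")
    truth <- attr(out, "truth")
    if (protocols[[nm]]$mode %in% c("caffeine", "caffeine_ni")) {
      pre <- max(which(out$time_s < sched$caffeine_time))
      truth_summary[[paste0("sr_at_caffeine_", nm)]] <- out$ca_sr_uM[pre]
    }
    if (nm == "systolic") {
      last <- sched$stim_times[length(sched$stim_times)]
      seg <- out$ca_free_nM[out$time_s >= last]
      truth_summary$amplitude_nM <- max(seg) - truth$ca_rest
      truth_summary$entry_umol <-
        cal_entry_per_beat(truth, protocols[[nm]]$step_dur_s)
    }
  }
  truth <- apply_condition(params, "none")
  truth_summary$k_sys <- systolic_decay_rate(truth)
  truth_summary$k_caff <- caffeine_decay_rate(truth)
  truth_summary$k_pmca <- truth$k_pmca_flux
  truth_summary$beta <- truth$beta
  truth_summary$g_ncx <- truth$g_ncx
  truth_summary$peak_density <- truth$g_cal_peak
  cell_record(cell_id = cell_id, animal_id = animal_id, group = group,
              condition = protocols[[1L]]$condition,
              geometry = cell_geometry(truth$cm, truth$sa_to_vol),
              traces = traces,
              protocols = lapply(protocols, protocol_metadata),
              truth = unclass(truth), truth_summary = truth_summary,
              seed = truth$seed)
}

protocol_metadata <- function(pr) {
  sched <- protocol_schedule(pr)
  list(mode = pr$mode, hold_mV = pr$hold_mV, step_mV = pr$step_mV,
       step_dur_s = pr$step_dur_s, freq_hz = pr$freq_hz,
       n_beats = pr$n_beats, condition = pr$condition,
       stim_times = sched$stim_times, caffeine_time = sched$caffeine_time)
}

#' Per-cell record of traces plus metadata
#'
#' The container consumed by [run_pipeline()]: traces (named data.frames
#' sharing the trace-CSV schema), geometry, protocol metadata and optional
#' simulator ground truth.
#'
#' @param cell_id,animal_id identifiers; `animal_id` is required (group
#'   summaries are animal-nested).
#' @param group group label, e.g. `"control"` or `"hf"`.
#' @param condition condition label.
#' @param geometry a [cell_geometry()] object.
#' @param traces named list of trace data.frames.
#' @param protocols named list of protocol metadata (one per trace), each with
#'   at least `stim_times`, `step_dur_s` and (for caffeine runs)
#'   `caffeine_time`.
#' @param truth,truth_summary optional simulator ground truth.
#' @param seed seed used to generate the record, if simulated.
#' @return an object of class `cell_record`.
#' @export
cell_record <- function(cell_id, animal_id, group = "control",
                        condition = "none", geometry, traces, protocols,
                        truth = NULL, truth_summary = NULL, seed = NA_integer_) {
  if (is.null(animal_id) || !nzchar(animal_id))
    stop("cell_record: animal_id is required")
  dts <- vapply(traces, function(tr) median(diff(tr$time_s)), numeric(1))
  if (length(dts) > 1L && diff(range(dts)) > 1e-6)
    stop("cell_record: traces must share one sampling rate")
  structure(list(cell_id = cell_id, animal_id = animal_id, group = group,
                 condition = condition, geometry = geometry, traces = traces,
                 protocols = protocols, truth = truth,
                 truth_summary = truth_summary, seed = seed),
            class = "cell_record")
}

#' @export
print.cell_record <- function(x, ...) {
  cat(sprintf("<cell_record> %s (%s, %s): traces %s\n", x$cell_id,
              x$animal_id, x$group, paste(names(x$traces), collapse = ", ")))
  invisible(x)
}
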