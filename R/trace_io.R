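#' Read and write trace CSV files
#'
#' The trace schema is one row per sample with a `time_s` column (uniform
#' step, strictly increasing) and any subset of the signal columns
#' `vm_mV`, `i_total_pA`, `i_ncx_pA`, `i_cal_pA`, `fluo_au`, `fura_ratio`,
#' `ca_free_nM`, `ca_sr_uM`. Unknown extra columns are preserved. Writing
#' then reading a trace reproduces the values to full double precision.
#'
#' @param path CSV file path.
#' @param trace data.frame following the schema.
#' @param dt_tol tolerated deviation of the time step from uniformity, s.
#' @return `read_trace_csv`: the trace data.frame.
#' @export
read_trace_csv <- function(path, dt_tol = 1e-6) {
  tr <- read.csv(path, check.names = FALSE)
  tr[] <- lapply(tr, function(x) if (is.integer(x)) as.numeric(x) else x)
  if (!"time_s" %in% names(tr))
    stop("read_trace_csv: missing required column time_s in ", path)
  if (nrow(tr) >= 2L) {
    dts <- diff(tr$time_s)
    if (any(dts <= 0))
      stop("read_trace_csv: time_s is not strictly increasing in ", path)
    if (diff(range(dts)) > dt_tol)
      stop("read_trace_csv: non-uniform time step in ", path)
  }
  sig <- setdiff(names(tr), "time_s")
  if (!length(sig))
    stop("read_trace_csv: no signal columns in ", path)
  tr
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  if (!"time_s" %in% names(trace))
    stop("write_trace_csv: trace lacks a time_s column")
  df <- as.data.frame(trace)
  # full precision so the round trip is lossless
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- formatC(df[[nm]], digits = 17,
                                                  format = "g")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a cell record as CSV traces plus a JSON sidecar
#'
#' Each trace is written as `<cell_id>_<trace>.csv` and the metadata
#' (identifiers, geometry, protocols, seed and any simulator ground truth)
#' as `<cell_id>.json`.
#'
#' @param record a [cell_record()].
#' @param dir output directory (created if needed).
#' @param cell_id record identifier (JSON file stem).
#' @return `read_cell_record`: the reconstructed [cell_record()].
#' @export
write_cell_record <- function(record, dir) {
  stopifnot(inherits(record, "cell_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(record$traces))
    write_trace_csv(record$traces[[nm]],
                    file.path(dir, paste0(record$cell_id, "_", nm, ".csv")))
  meta <- record[setdiff(names(record), "traces")]
  meta$geometry <- unclass(meta$geometry)
  meta$trace_names <- names(record$traces)
  jsonlite::write_json(meta, file.path(dir, paste0(record$cell_id, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file.path(dir, paste0(record$cell_id, ".json")))
}

#' @rdname write_cell_record
#' @export
read_cell_record <- function(dir, cell_id) {
  meta <- jsonlite::read_json(file.path(dir, paste0(cell_id, ".json")),
                              simplifyVector = TRUE)
  traces <- lapply(setNames(meta$trace_names, meta$trace_names),
                   function(nm)
                     read_trace_csv(file.path(dir,
                                              paste0(cell_id, "_", nm, ".csv"))))
  cell_record(cell_id = meta$cell_id, animal_id = meta$animal_id,
              group = meta$group, condition = meta$condition,
              geometry = cell_geometry(meta$geometry$cm,
                                       meta$geometry$sa_to_vol),
              traces = traces, protocols = meta$protocols,
              truth = meta$truth, truth_summary = meta$truth_summary,
              seed = meta$seed)
}
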