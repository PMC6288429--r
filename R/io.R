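provenance_header <- function(config, extra = character()) {
  p <- build_parms(config)
  c("# cardiomd run provenance",
    sprintf("# package_version: %s",
            as.character(utils::packageVersion("cardiomd"))),
    sprintf("# %s: %s", names(p), format(p, digits = 15, trim = TRUE)),
    sprintf("# rtol: %g  atol: %g  dt_record: %g", config$solver$rtol,
            config$solver$atol, config$solver$dt_record),
    extra)
}

#' Write a trace as tidy long-format CSV with a provenance header
#'
#' Columns: `time_ms`, `quantity`, `value`. The header comment block echoes
#' every model parameter and the solver tolerances so that the run can be
#' reproduced from the file alone.
#'
#' @param trace wide data.frame with a `time` column.
#' @param config the [model_config()] that produced it.
#' @param path output path.
#' @param quantities columns to keep (default: all non-time columns).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, config, path, quantities = NULL) {
  preflight_writable(path)
  quantities <- quantities %||% setdiff(names(trace), "time")
  long <- do.call(rbind, lapply(quantities, function(q)
    data.frame(time_ms = trace$time, quantity = q, value = trace[[q]],
               stringsAsFactors = FALSE)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  write.csv(long, con, row.names = FALSE)
  invisible(path)
}

#' Write per-beat metrics as CSV with a provenance header
#'
#' @param metrics data.frame from [classify_beats()]; may be empty
#'   (header-only output).
#' @param config the producing [model_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, config, path) {
  preflight_writable(path)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  write.csv(metrics, con, row.names = FALSE)
  invisible(path)
}

#' Write a sweep table as CSV and JSON
#'
#' @param sweep data.frame from [sweep_heatmap()].
#' @param path_csv,path_json output paths (either may be `NULL`).
#' @param meta named list echoed into the JSON (protocol settings etc.).
#' @return invisibly, the paths written.
#' @export
write_sweep <- function(sweep, path_csv = NULL, path_json = NULL,
                        meta = list()) {
  if (!is.null(path_csv)) {
    preflight_writable(path_csv)
    con <- file(path_csv, "w")
    writeLines(c("# cardiomd sweep result",
                 sprintf("# %s: %s", names(meta),
                         vapply(meta, format, character(1)))), con)
    write.csv(sweep, con, row.names = FALSE)
    close(con)
  }
  if (!is.null(path_json)) {
    preflight_writable(path_json)
    jsonlite::write_json(list(meta = meta, grid = sweep), path_json,
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(c(path_csv, path_json))
}

preflight_writable <- function(path) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("output directory does not exist: ", dir, call. = FALSE)
  if (file.access(dir, 2) != 0)
    stop("output directory is not writable: ", dir, call. = FALSE)
  invisible(TRUE)
}
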