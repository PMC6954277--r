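# Plain-text I/O for the tabular formats the pipeline consumes and emits.

#' Read a regional timeseries TSV
#'
#' Expects a header row of node labels and one row per frame. Repetition
#' time and module labels come from the sidecar JSON (keys `tr`,
#' `modules`) or from the arguments.
#'
#' @param path TSV file path.
#' @param sidecar Optional path to a JSON sidecar.
#' @param tr,modules Used when no sidecar is given.
#' @return A [regional_timeseries()] object.
#' @export
read_timeseries_tsv <- function(path, sidecar = NULL, tr = NULL, modules = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!is.null(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    tr <- tr %||% meta$tr
    modules <- modules %||% meta$modules
  }
  if (is.null(tr)) stop_config("`tr` must come from the sidecar or the argument.")
  regional_timeseries(as.matrix(df), labels = names(df), tr = tr,
                      modules = modules)
}

#' Write a regional timeseries TSV (plus sidecar)
#'
#' @param ts A `regional_ts`.
#' @param path Output TSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "regional_ts"))
  readr::write_tsv(as.data.frame(ts$signal), path)
  jsonlite::write_json(list(tr = ts$tr, modules = ts$modules),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a 6-column motion-parameter file
#'
#' Whitespace- or tab-delimited, one row per frame, no header; rotations
#' (radians) then translations (mm) by default.
#'
#' @param path File path.
#' @param col_order `"rot_first"` (default) or `"trans_first"`.
#' @return Frames x 6 numeric matrix with canonical column names.
#' @export
read_motion_params <- function(path, col_order = "rot_first") {
  df <- readr::read_table(path, col_names = FALSE, show_col_types = FALSE)
  as_motion_matrix(as.matrix(df), col_order = col_order)
}

#' Read a long QST trial table
#'
#' CSV with columns `subject_id`, `modality`, `trial_index`, `value` (and
#' optionally `unit`), one row per trial.
#'
#' @param path CSV file path.
#' @return A tibble suitable for [qst_thresholds()].
#' @export
read_qst_trials <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read QST reference statistics from JSON
#'
#' Expects keys `hpt_mu`, `hpt_sd`, `cpt_mu`, `cpt_sd`, `mpt_mu`, `mpt_sd`
#' and optionally `source`.
#'
#' @param path JSON file path.
#' @return A [qst_reference()] object.
#' @export
read_qst_reference_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  qst_reference(j$hpt_mu, j$hpt_sd, j$cpt_mu, j$cpt_sd, j$mpt_mu, j$mpt_sd,
                source = j$source %||% path)
}

#' Read normative QST bounds from JSON
#'
#' Expects keys `hpt`, `cpt`, `mpt`, each `[lower, upper]`; a template with
#' placeholder values ships in
#' `system.file("extdata", "normative_bounds_template.json", package = "rpnsig")`.
#' Screening refuses to run until real values are filled in.
#'
#' @param path JSON file path.
#' @return A [qst_bounds()] object.
#' @export
read_qst_bounds_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (isTRUE(j$placeholder)) {
    stop_config(paste0(
      "the bounds file is the placeholder template; fill in the normative ",
      "95% percentile values from the QST reference literature first."))
  }
  qst_bounds(j$hpt, j$cpt, j$mpt, source = j$source %||% path)
}

#' Write / read a connectivity matrix TSV
#'
#' Square matrix with node labels as header and first column.
#'
#' @param conn A `conn_matrix`.
#' @param path File path.
#' @return `path` (write) or a `conn_matrix` (read).
#' @export
write_conn_tsv <- function(conn, path) {
  df <- as.data.frame(unclass(conn))
  df <- cbind(node = rownames(conn), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_conn_tsv
#' @export
read_conn_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  labels <- df[[1]]
  m <- as.matrix(df[, -1])
  new_conn_matrix(unname(m), labels, estimator = "file")
}
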