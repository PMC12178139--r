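# Tabular IO: ROI time series, network atlas, cohort clinical scores,
# metric reports. All tables are UTF-8, tab-delimited, header mandatory.

YEO7 <- c("VN", "SMN", "DAN", "VAN", "LN", "FPN", "DMN")
TIMEPOINTS <- c("pre", "post")
GROUPS <- c("unknown", "responder", "nonresponder")

#' Construct an ROI time-series table
#'
#' Frames x ROIs BOLD matrix with repetition time, the substrate of the CAP
#' stage.
#'
#' @param data numeric matrix, frames x ROIs.
#' @param tr repetition time in seconds (> 0).
#' @param roi_ids unique ROI identifiers, one per column.
#' @param subject_id,timepoint optional metadata.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, tr, roi_ids = NULL,
                           subject_id = NA_character_, timepoint = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(roi_ids)) roi_ids <- paste0("roi", seq_len(ncol(data)))
  if (!all(is.finite(data)))
    ns_stop("neurostate_error_nonfinite", "ROI table contains non-finite values")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    ns_stop("neurostate_error_bad_tr", "tr must be a single value > 0")
  if (nrow(data) < 2L)
    ns_stop("neurostate_error_too_few_frames", "ROI table needs >= 2 frames")
  if (length(roi_ids) != ncol(data) || anyDuplicated(roi_ids))
    ns_stop("neurostate_error_bad_roi_ids", "roi_ids must be unique, one per column")
  colnames(data) <- roi_ids
  structure(list(data = data, tr = tr, roi_ids = roi_ids,
                 subject_id = subject_id, timepoint = timepoint),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d frames x %d ROIs, TR = %g s\n",
              nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Read an ROI time-series TSV
#'
#' Tab-separated, header row of ROI ids, one row per frame.
#'
#' @param path TSV path.
#' @param tr repetition time (s); not stored in the TSV.
#' @param atlas optional atlas (from [read_atlas()]) to cross-check ROI ids.
#' @inheritParams roi_timeseries
#' @return A [roi_timeseries()].
#' @export
read_roi_table <- function(path, tr, atlas = NULL,
                           subject_id = NA_character_, timepoint = NA_character_) {
  df <- utils::read.delim(path, check.names = FALSE)
  mat <- as.matrix(df)
  if (!is.numeric(mat))
    ns_stop("neurostate_error_nonnumeric", "non-numeric cells in ROI table %s", path)
  tab <- roi_timeseries(mat, tr = tr, roi_ids = colnames(df),
                        subject_id = subject_id, timepoint = timepoint)
  if (!is.null(atlas)) {
    missing <- setdiff(tab$roi_ids, names(atlas))
    if (length(missing))
      ns_stop("neurostate_error_roi_not_in_atlas",
              "ROIs absent from atlas: %s", paste(missing, collapse = ", "))
  }
  tab
}

#' @rdname read_roi_table
#' @param table a [roi_timeseries()] to write.
#' @export
write_roi_table <- function(table, path) {
  utils::write.table(table$data, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a ROI-to-network atlas TSV
#'
#' Two columns `roi_id` and `network`; every network label must be one of the
#' seven canonical resting-state networks (VN, SMN, DAN, VAN, LN, FPN, DMN).
#'
#' @param path TSV path.
#' @return A named character vector mapping roi_id to network label, with
#'   class `atlas_map`.
#' @export
read_atlas <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("roi_id", "network") %in% names(df)))
    ns_stop("neurostate_error_atlas_columns", "atlas needs columns roi_id, network")
  bad <- setdiff(unique(df$network), YEO7)
  if (length(bad))
    ns_stop("neurostate_error_unknown_network",
            "unknown network label(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(df$roi_id))
    ns_stop("neurostate_error_duplicate_roi", "duplicate roi_id in atlas")
  structure(stats::setNames(df$network, df$roi_id), class = "atlas_map")
}

#' @rdname read_atlas
#' @param atlas named character vector (roi_id -> network) to write.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(data.frame(roi_id = names(atlas), network = as.character(atlas)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

cohort_score_cols <- c("mds_updrs3_total", "tremor", "bradykinesia",
                       "rigidity", "axial", "pdq39")

validate_cohort <- function(df) {
  need <- c("subject_id", "group", "timepoint", cohort_score_cols)
  missing <- setdiff(need, names(df))
  if (length(missing))
    ns_stop("neurostate_error_cohort_columns",
            "cohort table lacks column(s): %s", paste(missing, collapse = ", "))
  if (!all(df$timepoint %in% TIMEPOINTS))
    ns_stop("neurostate_error_bad_timepoint", "timepoint must be pre|post")
  if (!all(df$group %in% GROUPS))
    ns_stop("neurostate_error_bad_group", "group must be unknown|responder|nonresponder")
  if (anyDuplicated(df[, c("subject_id", "timepoint")]))
    ns_stop("neurostate_error_duplicate_row",
            "duplicate (subject_id, timepoint) rows")
  sc <- as.matrix(df[, cohort_score_cols])
  if (any(sc < 0, na.rm = TRUE))
    ns_stop("neurostate_error_negative_score", "clinical scores must be >= 0")
  for (col in c("tremor", "bradykinesia", "rigidity", "axial")) {
    over <- !is.na(df[[col]]) & !is.na(df$mds_updrs3_total) &
      df[[col]] > df$mds_updrs3_total
    if (any(over))
      ns_stop("neurostate_error_subscale_exceeds_total",
              "subscale '%s' exceeds the MDS-UPDRS III total", col)
  }
  df
}

#' Read / write a cohort clinical-score table
#'
#' Long format: one row per subject x timepoint with columns `subject_id`,
#' `group` (unknown | responder | nonresponder), `timepoint` (pre | post),
#' `mds_updrs3_total`, `tremor`, `bradykinesia`, `rigidity`, `axial`,
#' `pdq39`.
#'
#' @param path TSV path.
#' @return A validated `data.frame`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, colClasses = c(subject_id = "character"))
  validate_cohort(df)
}

#' @rdname read_cohort
#' @param cohort the cohort `data.frame` to write.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

REPORT_SCHEMA_VERSION <- "1.0"

#' Write / read a metrics report
#'
#' JSON reports carry a `schema_version` string and round-trip losslessly
#' for numeric and character content; `write_metrics_tsv` flattens a
#' data.frame of per-subject metrics to TSV.
#'
#' @param metrics a named list (JSON) or data.frame (TSV).
#' @param path output path.
#' @return `path` invisibly (writers); the restored list (reader).
#' @export
write_report <- function(metrics, path) {
  jsonlite::write_json(list(schema_version = REPORT_SCHEMA_VERSION,
                            metrics = metrics),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version))
    ns_stop("neurostate_error_report_schema", "report lacks schema_version")
  obj$metrics
}

#' @rdname write_report
#' @export
write_metrics_tsv <- function(metrics, path) {
  stopifnot(is.data.frame(metrics))
  utils::write.table(metrics, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
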