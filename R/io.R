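# Plain-text readers/writers for the pipeline's artifacts. Everything is
# TSV/CSV/JSON with explicit headers; no binary formats.

#' Write / read an ROI timecourse as wide TSV
#'
#' Wide format: one column per ROI (header = ROI labels), one row per TR.
#' Censor masks are not stored in the timecourse file; they are derived from
#' the motion trace.
#'
#' @param tc A `roi_tc`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timecourse_tsv <- function(tc, path) {
  stopifnot(inherits(tc, "roi_tc"))
  write.table(format(tc$values, digits = 15, scientific = TRUE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse_tsv
#' @param network_of Named character vector mapping ROI label to network.
#' @param tr_seconds Sampling interval.
#' @export
read_timecourse_tsv <- function(path, network_of, tr_seconds) {
  v <- as.matrix(read.delim(path, check.names = FALSE))
  roi_timecourse_set(v, network_of, tr_seconds)
}

#' Write / read a realignment trace as 6-column TSV
#'
#' Columns `trans_x`, `trans_y`, `trans_z` (mm) and `rot_x`, `rot_y`, `rot_z`
#' (radians), the confounds-style convention.
#'
#' @param trace A `motion_trace`.
#' @param path File path.
#' @return `path`, invisibly (writer); a `motion_trace` (reader).
#' @export
write_motion_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "motion_trace"))
  write.table(format(trace$values, digits = 15, scientific = TRUE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @param tr_seconds Sampling interval.
#' @export
read_motion_tsv <- function(path, tr_seconds) {
  v <- as.matrix(read.delim(path, check.names = FALSE))
  cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (!all(cols %in% colnames(v)))
    stop("motion TSV must have columns ", paste(cols, collapse = ", "))
  out <- list(values = v[, cols, drop = FALSE], tr_seconds = tr_seconds,
              artifact_tr = integer(0))
  class(out) <- "motion_trace"
  out
}

#' Read an ROI-to-network atlas map
#'
#' Two-column TSV with header `roi`, `network`.
#'
#' @param path File path.
#' @return Named character vector (ROI -> network).
#' @export
read_atlas_tsv <- function(path) {
  a <- read.delim(path, stringsAsFactors = FALSE)
  setNames(a$network, a$roi)
}

#' Read an event table
#'
#' Three-column TSV with header `label`, `start_tr`, `end_tr` (1-based,
#' inclusive).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_event_tsv <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("label", "start_tr", "end_tr") %in% names(ev)))
    stop("event TSV must have columns label, start_tr, end_tr")
  ev
}
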