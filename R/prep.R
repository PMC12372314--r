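# Temporal denoising of ROI timecourses. Fixed pipeline order:
# interpolate censored artifacts -> high-pass -> z-score; censoring itself is
# applied afterwards, inside the correlational analyses.

#' Interpolate censored artifact timepoints
#'
#' Replaces censored samples by linear interpolation between the flanking
#' uncensored samples; censored runs at either edge are held at the nearest
#' uncensored value. The censor mask is retained so downstream analyses can
#' still exclude these TRs — interpolation only prevents artifacts from
#' leaking through the temporal filter.
#'
#' @param tc A `roi_tc` (see [roi_timecourse_set()]) with its censor mask set.
#' @return A `roi_tc` with censored samples replaced.
#' @export
interpolate_artifacts <- function(tc) {
  stopifnot(inherits(tc, "roi_tc"))
  cens <- tc$censored
  if (!any(cens)) return(tc)
  good <- which(!cens)
  if (length(good) < 2L)
    stop("fewer than 2 uncensored timepoints; subject unusable")
  T <- nrow(tc$values)
  tc$values <- apply(tc$values, 2L, function(y) {
    approx(x = good, y = y[good], xout = seq_len(T), rule = 2)$y
  })
  tc
}

#' High-pass filter ROI timecourses
#'
#' Zero-phase Butterworth high-pass (default order 5, applied
#' forward-backward) at `1/cutoff_s` Hz, applied per ROI. Run after
#' [interpolate_artifacts()] so censored spikes do not ring through the
#' filter.
#'
#' @param tc A `roi_tc`.
#' @param cutoff_s Cutoff period in seconds (default 100). Must exceed twice
#'   the sampling interval.
#' @param order Butterworth order (doubled by the forward-backward pass).
#' @return Filtered `roi_tc` (mean removed: a high-pass passes no DC).
#' @export
highpass <- function(tc, cutoff_s = 100, order = 5L) {
  stopifnot(inherits(tc, "roi_tc"))
  if (cutoff_s <= 2 * tc$tr_seconds)
    stop("cutoff period must exceed twice the sampling interval")
  nyq <- 1 / (2 * tc$tr_seconds)
  hp <- signal::butter(order, (1 / cutoff_s) / nyq, type = "high")
  tc$values <- apply(tc$values, 2L,
                     function(x) zero_phase_filter(hp, x, keep_mean = FALSE))
  tc
}

#' Z-score ROI timecourses
#'
#' Each ROI column is centered and scaled to unit SD over all T timepoints,
#' censored included: censoring is applied subsequently within analyses, so
#' normalization precedes exclusion.
#'
#' @param tc A `roi_tc`.
#' @return Z-scored `roi_tc`.
#' @export
zscore_timecourses <- function(tc) {
  stopifnot(inherits(tc, "roi_tc"))
  sds <- apply(tc$values, 2L, sd)
  if (any(!is.finite(sds) | sds <= 0))
    stop("zero-variance ROI column; degenerate input")
  tc$values <- scale(tc$values)[, , drop = FALSE]
  attr(tc$values, "scaled:center") <- NULL
  attr(tc$values, "scaled:scale") <- NULL
  tc
}

#' Full temporal preparation pipeline
#'
#' Applies, in fixed order: artifact interpolation, high-pass filtering,
#' z-scoring. The order matters (permuting it changes the output) and is the
#' package's canonical preprocessing path.
#'
#' @param tc A `roi_tc` with censor mask set.
#' @param cutoff_s High-pass cutoff period (seconds).
#' @param order High-pass Butterworth order.
#' @return Prepared `roi_tc`.
#' @export
prep_timecourses <- function(tc, cutoff_s = 100, order = 5L) {
  zscore_timecourses(highpass(interpolate_artifacts(tc), cutoff_s, order))
}

#' Average ROI timecourses within a network
#'
#' Unweighted mean across the network's ROI columns at each timepoint; the
#' subject's censor mask is inherited.
#'
#' @param tc A `roi_tc`.
#' @param network Network label present in `tc$network_of`.
#' @return Object of class `network_tc`: list with `values` (length-T),
#'   `network`, `tr_seconds`, `censored`.
#' @export
network_average <- function(tc, network) {
  stopifnot(inherits(tc, "roi_tc"))
  cols <- names(tc$network_of)[tc$network_of == network]
  if (!length(cols)) stop(sprintf("unknown network label '%s'", network))
  out <- list(values = rowMeans(tc$values[, cols, drop = FALSE]),
              network = network, tr_seconds = tc$tr_seconds,
              censored = tc$censored)
  class(out) <- "network_tc"
  out
}

#' @export
print.network_tc <- function(x, ...) {
  cat(sprintf("Network timecourse (%s): %d TRs, %d censored\n",
              x$network, length(x$values), sum(x$censored)))
  invisible(x)
}
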