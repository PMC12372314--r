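# Motion quality control: filtered framewise displacement, artifact
# detection/censoring, subject exclusion, group matching.

#' Filtered framewise displacement over four timepoints (FDfilt4)
#'
#' Computes framewise displacement from a 6-parameter realignment trace after
#' band-stop ("notch") filtering each parameter to remove pseudo-respiratory
#' frequencies, the convention appropriate for fast multiband acquisitions
#' where respiration aliases into the realignment estimates. Displacement at
#' TR `t` is the sum over parameters of the absolute lag-4 backward
#' difference, `fd[t] = sum_j |p_j[t] - p_j[t-4]|`, with rotations converted
#' to arc displacement on a sphere of radius `radius_mm`. The first 4 entries
#' are defined as 0 (not missing), so the mean is taken over all TRs.
#'
#' The lag-4 reading of "backward differences over four timepoints" (rather
#' than a sum of four lag-1 differences) follows the filtered-FD literature
#' for multiband data; switch via `lag` if another convention is needed.
#'
#' @param trace A `motion_trace` or a numeric T x 6 matrix
#'   (translations in mm, rotations in radians). T must be >= 8.
#' @param tr_seconds Sampling interval; taken from the trace object when
#'   available.
#' @param band_hz Length-2 numeric, the respiratory stop-band (Hz). Must lie
#'   strictly inside (0, Nyquist).
#' @param radius_mm Sphere radius for rotation-to-mm conversion (default 50,
#'   the standard convention).
#' @param bypass_filter If `TRUE`, skip the band-stop filter (useful for slow
#'   acquisitions where the band exceeds Nyquist, and for analytic tests).
#' @param filter_order Butterworth order of the band-stop (applied
#'   forward-backward, so effective order is doubled).
#' @param lag Backward-difference lag (default 4).
#' @return Object of class `fd_series`: list with `fd_mm` (length-T,
#'   first `lag` entries 0), `mean_fd` (mean over all T), `tr_seconds`.
#' @examples
#' tr <- matrix(0, 64, 6)
#' tr[33:64, 1] <- 1  # 1 mm step in trans_x
#' fd <- compute_fd_filt4(tr, tr_seconds = 0.72, bypass_filter = TRUE)
#' which(fd$fd_mm > 0)  # the four lag-covered TRs: 33..36
#' @export
compute_fd_filt4 <- function(trace, tr_seconds = NULL,
                             band_hz = c(0.31, 0.43), radius_mm = 50,
                             bypass_filter = FALSE, filter_order = 10L,
                             lag = 4L) {
  if (inherits(trace, "motion_trace")) {
    tr_seconds <- tr_seconds %||% trace$tr_seconds
    trace <- trace$values
  }
  trace <- as.matrix(trace)
  if (ncol(trace) != 6L) stop("realignment trace must have 6 columns")
  T <- nrow(trace)
  if (T < 8L) stop("need at least 8 timepoints (lag-4 differencing)")
  if (!all(is.finite(trace))) stop("non-finite values in realignment trace")
  stopifnot_scalar(radius_mm, "radius_mm", min = 0, strict_min = TRUE)
  p <- trace
  p[, 4:6] <- p[, 4:6] * radius_mm
  if (!bypass_filter) {
    if (is.null(tr_seconds))
      stop("'tr_seconds' required when filtering")
    nyq <- 1 / (2 * tr_seconds)
    if (!(band_hz[1] > 0 && band_hz[1] < band_hz[2] && band_hz[2] < nyq))
      stop(sprintf("stop-band must satisfy 0 < low < high < Nyquist (%.3g Hz)", nyq))
    bs <- signal::butter(filter_order, band_hz / nyq, type = "stop")
    p <- apply(p, 2L, function(x) zero_phase_filter(bs, x, keep_mean = TRUE))
  }
  fd <- rep(0, T)
  idx <- (lag + 1L):T
  fd[idx] <- rowSums(abs(p[idx, , drop = FALSE] - p[idx - lag, , drop = FALSE]))
  out <- list(fd_mm = fd, mean_fd = mean(fd), tr_seconds = tr_seconds)
  class(out) <- "fd_series"
  out
}

#' @export
print.fd_series <- function(x, ...) {
  cat(sprintf("FD series: %d TRs, mean FD %.4g mm, max %.4g mm\n",
              length(x$fd_mm), x$mean_fd, max(x$fd_mm)))
  invisible(x)
}

#' Detect motion artifact timepoints
#'
#' Flags every TR whose framewise displacement exceeds `threshold_mm`, plus
#' the `pad` TRs before and after each exceedance (clipped to the series);
#' overlapping pads merge. Censored TRs are treated as missing data in all
#' downstream correlational analyses.
#'
#' @param fd An `fd_series` from [compute_fd_filt4()], or a numeric FD vector.
#' @param threshold_mm Exceedance threshold (default 0.5 mm).
#' @param pad Number of TRs padded on each side of an exceedance (default 2).
#' @return Object of class `censor_mask`: list with `censored` (logical
#'   length-T), `n_censored`, `frac_censored`.
#' @export
detect_artifacts <- function(fd, threshold_mm = 0.5, pad = 2L) {
  if (inherits(fd, "fd_series")) fd <- fd$fd_mm
  stopifnot_scalar(threshold_mm, "threshold_mm", min = 0, strict_min = TRUE)
  if (pad < 0) stop("'pad' must be >= 0")
  T <- length(fd)
  censored <- rep(FALSE, T)
  for (t in which(fd > threshold_mm)) {
    censored[max(1L, t - pad):min(T, t + pad)] <- TRUE
  }
  out <- list(censored = censored, n_censored = sum(censored),
              frac_censored = sum(censored) / T)
  class(out) <- "censor_mask"
  out
}

#' @export
print.censor_mask <- function(x, ...) {
  cat(sprintf("Censor mask: %d / %d TRs censored (%.1f%%)\n",
              x$n_censored, length(x$censored), 100 * x$frac_censored))
  invisible(x)
}

#' Subject-level motion exclusion
#'
#' Flags subjects whose mean FD exceeds the per-site median plus 1.5 times the
#' IQR of mean FD (`iqr_outlier`), and subjects whose censored fraction
#' exceeds one third of the scan (`over_one_third`). Per-site thresholds can
#' be supplied (`fixed_thresholds`) when they were derived on a larger
#' reference sample; otherwise they are computed on the input sample, which
#' requires at least two subjects per site.
#'
#' @param qc Data frame with columns `subject_id`, `site`, `mean_fd`,
#'   `frac_censored`.
#' @param fixed_thresholds Optional named numeric vector of per-site mean-FD
#'   thresholds, e.g. `c(IU = 0.4808, CAL = 0.5625)`; honored verbatim.
#' @param iqr_mult Multiplier on the IQR (default 1.5).
#' @param max_frac Maximum tolerated censored fraction (default 1/3).
#' @return `qc` with logical columns `iqr_outlier`, `over_one_third`,
#'   `excluded` (their union) appended; per-site thresholds in
#'   `attr(, "thresholds")`.
#' @export
exclude_subjects <- function(qc, fixed_thresholds = NULL, iqr_mult = 1.5,
                             max_frac = 1 / 3) {
  need <- c("subject_id", "site", "mean_fd", "frac_censored")
  if (!all(need %in% names(qc)))
    stop("qc table needs columns: ", paste(need, collapse = ", "))
  sites <- unique(qc$site)
  thr <- setNames(numeric(length(sites)), sites)
  for (s in sites) {
    if (!is.null(fixed_thresholds) && s %in% names(fixed_thresholds)) {
      thr[s] <- fixed_thresholds[[s]]
    } else {
      x <- qc$mean_fd[qc$site == s]
      if (length(x) < 2L)
        stop(sprintf("site '%s' has a single subject and no fixed threshold", s))
      thr[s] <- median(x) + iqr_mult * IQR(x)
    }
  }
  qc$iqr_outlier <- qc$mean_fd > thr[qc$site]
  qc$over_one_third <- qc$frac_censored > max_frac
  qc$excluded <- qc$iqr_outlier | qc$over_one_third
  attr(qc, "thresholds") <- thr
  qc
}

# Welch p-value that degrades gracefully: constant or too-small groups give
# p = 1 (no evidence of a difference).
safe_t_p <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) return(1)
  p <- tryCatch(t.test(x, y)$p.value, error = function(e) 1)
  if (!is.finite(p)) 1 else p
}

#' Match groups on motion by iterative extreme-subject removal
#'
#' While any listed motion metric differs between the two groups at
#' `p < alpha` (Welch two-sample t-test), removes one subject per iteration:
#' among the candidate extremes (the maximum of the higher-mean group and the
#' minimum of the lower-mean group, for each significantly different metric),
#' the subject whose removal most increases the minimum p-value across all
#' metrics. Ties break by subject-identifier order. The procedure aims to
#' retain as many subjects as possible while equalizing motion.
#'
#' @param qc Data frame with `subject_id`, `group`, and the metric columns.
#' @param metrics Character vector of metric column names
#'   (default `c("mean_fd", "n_censored")`).
#' @param alpha Significance level for the group difference (default 0.05);
#'   `alpha = 0` never removes anyone.
#' @param min_n Minimum group size below which matching fails (default 3).
#' @return Character vector of removed subject ids, in removal order
#'   (possibly empty).
#' @export
match_groups_on_motion <- function(qc, metrics = c("mean_fd", "n_censored"),
                                   alpha = 0.05, min_n = 3L) {
  groups <- unique(qc$group)
  if (length(groups) != 2L) stop("need exactly two groups")
  if (!all(metrics %in% names(qc)))
    stop("missing metric columns: ",
         paste(setdiff(metrics, names(qc)), collapse = ", "))
  if (any(table(qc$group) < min_n)) stop("each group needs n >= min_n")
  cur <- qc[order(qc$subject_id), , drop = FALSE]
  removed <- character(0)
  min_p <- function(d) {
    min(vapply(metrics, function(m) {
      safe_t_p(d[[m]][d$group == groups[1]], d[[m]][d$group == groups[2]])
    }, numeric(1)))
  }
  repeat {
    ps <- vapply(metrics, function(m) {
      safe_t_p(cur[[m]][cur$group == groups[1]], cur[[m]][cur$group == groups[2]])
    }, numeric(1))
    if (all(ps >= alpha) || alpha <= 0) break
    cand <- character(0)
    for (m in metrics[ps < alpha]) {
      mu <- tapply(cur[[m]], cur$group, mean)
      hi <- names(mu)[which.max(mu)]; lo <- names(mu)[which.min(mu)]
      hi_rows <- cur[cur$group == hi, ]
      lo_rows <- cur[cur$group == lo, ]
      cand <- c(cand,
                hi_rows$subject_id[which.max(hi_rows[[m]])],
                lo_rows$subject_id[which.min(lo_rows[[m]])])
    }
    cand <- sort(unique(cand))
    # a candidate may not shrink a group below min_n
    ok <- vapply(cand, function(id) {
      g <- cur$group[cur$subject_id == id]
      sum(cur$group == g) > min_n
    }, logical(1))
    cand <- cand[ok]
    if (!length(cand))
      stop("motion matching impossible before a group reaches the minimum size")
    gain <- vapply(cand, function(id) {
      min_p(cur[cur$subject_id != id, , drop = FALSE])
    }, numeric(1))
    best <- cand[which.max(gain)]  # which.max takes the first (id-sorted) tie
    removed <- c(removed, best)
    cur <- cur[cur$subject_id != best, , drop = FALSE]
  }
  removed
}
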