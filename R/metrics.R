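# Dependent variables: inter-region correlation (IRC), similarity to a
# reference-group average, within/across-group pairwise similarity (ISC),
# and event response magnitude. All summaries are means of Fisher-z values
# (not the z of mean r).

#' Fisher z-transform of a correlation
#'
#' `z = atanh(r)`, with `|r|` clipped to `1 - 1e-7` first so perfect
#' correlations map to a large finite value instead of overflowing.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @param cap Clipping bound on `|r|`.
#' @return Fisher z value(s).
#' @examples
#' fisher_z(0.5)  # 0.5493
#' @export
fisher_z <- function(r, cap = 1 - 1e-7) {
  if (any(!is.finite(r) & !is.na(r))) stop("non-finite correlation")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  atanh(pmin(pmax(r, -cap), cap))
}

#' Pearson correlation under union censoring
#'
#' Correlates two series over the timepoints valid in both censor masks (the
#' union of censored indices is excluded — censored TRs are treated as missing
#' data). Errors if fewer than `min_points` joint timepoints remain.
#'
#' @param x,y Numeric series of equal length.
#' @param mask_x,mask_y Censor masks (logical vectors or `censor_mask`
#'   objects; `TRUE` = censored). `NULL` means no censoring.
#' @param min_points Minimum joint valid timepoints (default 10).
#' @return Pearson r (scalar).
#' @export
pairwise_correlation <- function(x, y, mask_x = NULL, mask_y = NULL,
                                 min_points = 10L) {
  if (length(x) != length(y)) stop("series lengths differ")
  cx <- censor_logical(mask_x, length(x))
  cy <- censor_logical(mask_y, length(y))
  keep <- !(cx | cy) & is.finite(x) & is.finite(y)
  if (sum(keep) < min_points)
    stop(sprintf("only %d joint valid timepoints (< %d); unusable pair",
                 sum(keep), min_points))
  cor(x[keep], y[keep])
}

#' Within- and across-network inter-region correlation summary
#'
#' Correlates all ROI pairs over the subject's own uncensored TRs, applies the
#' Fisher transform per pair, and averages z over (i) within-network pairs of
#' the first network, (ii) within-network pairs of the second, and (iii) all
#' cross-network pairs. Under the default 13-ROI atlas (6 ToM + 7 Pain) these
#' are means over exactly 15, 21 and 42 pairs.
#'
#' @param tc A `roi_tc` (normally prepared via [prep_timecourses()]) with its
#'   censor mask set.
#' @param min_points Minimum uncensored timepoints (default 10).
#' @return List with `within_tom_z`, `within_pain_z`, `across_z` (Fisher-z
#'   scalars; named after the first/second network of the atlas) and
#'   `n_pairs` (integer vector of the three pair counts).
#' @export
irc_summary <- function(tc, min_points = 10L) {
  stopifnot(inherits(tc, "roi_tc"))
  keep <- !tc$censored
  if (sum(keep) < min_points)
    stop("too few uncensored timepoints for IRC")
  Z <- fisher_z(cor(tc$values[keep, , drop = FALSE]))
  nets <- unname(tc$network_of)
  uniq <- unique(nets)
  if (length(uniq) != 2L) stop("IRC summary expects exactly two networks")
  i1 <- which(nets == uniq[1L]); i2 <- which(nets == uniq[2L])
  pair_mean <- function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    sub <- Z[idx, idx, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }
  list(within_tom_z = pair_mean(i1),
       within_pain_z = pair_mean(i2),
       across_z = mean(Z[i1, i2]),
       n_pairs = c(within_tom = choose(length(i1), 2),
                   within_pain = choose(length(i2), 2),
                   across = length(i1) * length(i2)))
}

#' Similarity of a network timecourse to a reference-group average
#'
#' Correlates a subject's network timecourse with the average timecourse of a
#' reference group. The reference average at each timepoint is taken over the
#' reference subjects with valid (uncensored) data there; timepoints with no
#' valid reference subject, and the subject's own censored TRs, are excluded
#' from the correlation. When the subject belongs to the reference group, pass
#' their index as `leave_out` for the leave-one-out average; subjects outside
#' the reference group use the full-group average.
#'
#' @param subject_tc A `network_tc` (see [network_average()]).
#' @param reference_tcs List of `network_tc` for the reference group.
#' @param leave_out Integer index into `reference_tcs` to drop (leave-one-out),
#'   or `NULL`.
#' @param min_points Minimum joint valid timepoints (default 10).
#' @return Fisher-z similarity (scalar).
#' @export
similarity_to_reference <- function(subject_tc, reference_tcs, leave_out = NULL,
                                    min_points = 10L) {
  stopifnot(inherits(subject_tc, "network_tc"))
  if (!is.null(leave_out)) {
    if (length(reference_tcs) < 2L)
      stop("leave-one-out requires a reference group of >= 2")
    reference_tcs <- reference_tcs[-leave_out]
  }
  if (!length(reference_tcs)) stop("empty reference group")
  refmat <- vapply(reference_tcs, function(r) {
    v <- r$values; v[r$censored] <- NA_real_; v
  }, numeric(length(subject_tc$values)))
  nvalid <- rowSums(!is.na(refmat))
  avg <- rowMeans(refmat, na.rm = TRUE)
  avg[nvalid == 0L] <- NA_real_
  x <- subject_tc$values
  x[subject_tc$censored] <- NA_real_
  keep <- !is.na(x) & !is.na(avg)
  if (sum(keep) < min_points)
    stop("too few joint valid timepoints against the reference average")
  fisher_z(cor(x[keep], avg[keep]))
}

#' Within- and across-group pairwise timecourse similarity
#'
#' Computes the full symmetric pairwise Fisher-z similarity matrix across
#' subjects' network timecourses (each pair correlated over the union of the
#' two subjects' uncensored TRs) and, per subject, the mean z to own-group
#' others (`within_group_z`) and to all other-group subjects
#' (`across_group_z`).
#'
#' @param tcs List of `network_tc`, one per subject.
#' @param groups Character/factor vector of group labels, same length.
#' @param min_points Minimum joint valid timepoints per pair.
#' @return Data frame with `within_group_z`, `across_group_z` per subject;
#'   the pairwise z matrix is in `attr(, "z_matrix")`.
#' @export
group_similarity_summary <- function(tcs, groups, min_points = 10L) {
  n <- length(tcs)
  if (length(groups) != n) stop("groups length must match subject count")
  if (any(table(groups) < 2L)) stop("need >= 2 subjects per group")
  T <- length(tcs[[1L]]$values)
  mat <- vapply(tcs, function(s) {
    v <- s$values; v[s$censored] <- NA_real_; v
  }, numeric(T))
  R <- cor(mat, use = "pairwise.complete.obs")
  npair <- crossprod(!is.na(mat))
  R[npair < min_points] <- NA_real_
  Z <- fisher_z(R)
  diag(Z) <- NA_real_
  groups <- as.character(groups)
  within <- vapply(seq_len(n), function(i)
    mean(Z[i, groups == groups[i]], na.rm = TRUE), numeric(1))
  across <- vapply(seq_len(n), function(i)
    mean(Z[i, groups != groups[i]], na.rm = TRUE), numeric(1))
  out <- data.frame(within_group_z = within, across_group_z = across)
  attr(out, "z_matrix") <- Z
  out
}

#' Event response magnitude
#'
#' Mean of a (z-scored) network timecourse over the uncensored TRs of an event
#' window — used for the final mental-state event ("T04"), whose peak spans
#' multiple TRs at fast sampling. A fully censored window yields `NA`, to be
#' excluded listwise downstream.
#'
#' @param tc A `network_tc`.
#' @param event_window Integer length-2, `(start_tr, end_tr)` inclusive,
#'   1-based.
#' @return Scalar magnitude in the timecourse's (z-scored) units, or `NA`.
#' @export
event_magnitude <- function(tc, event_window) {
  stopifnot(inherits(tc, "network_tc"), length(event_window) == 2L)
  T <- length(tc$values)
  if (event_window[1L] < 1L || event_window[2L] > T ||
      event_window[1L] > event_window[2L])
    stop("event window outside the series")
  idx <- event_window[1L]:event_window[2L]
  idx <- idx[!tc$censored[idx]]
  if (!length(idx)) return(NA_real_)
  mean(tc$values[idx])
}

#' Per-subject metric table for a cohort
#'
#' Assembles the full dependent-variable table: IRC summaries, similarity to
#' the (leave-one-out) reference-group average per network, within/across-group
#' pairwise similarity per network, and the event response magnitude for the
#' final mental-state event.
#'
#' @param tcs Named list of prepared `roi_tc`, one per subject (censor masks
#'   set; see [prep_timecourses()]).
#' @param groups Group labels, same order as `tcs`.
#' @param reference_group Group whose average is the similarity reference
#'   (default `"NT"`); its members are compared leave-one-out, others against
#'   the full reference average.
#' @param event_window `(start_tr, end_tr)` for the event magnitude, or `NULL`
#'   to skip.
#' @param event_network Network whose average timecourse the event magnitude
#'   is read from (default `"ToM"`).
#' @param min_points Minimum joint valid timepoints for any correlation.
#' @return Data frame, one row per subject: `subject_id`, `within_tom_z`,
#'   `within_pain_z`, `across_z`, `sim_nt_tom_z`, `sim_nt_pain_z`,
#'   `within_group_tom_z`, `across_group_tom_z`, `within_group_pain_z`,
#'   `across_group_pain_z`, `t04_magnitude`.
#' @export
cohort_metrics <- function(tcs, groups, reference_group = "NT",
                           event_window = NULL, event_network = "ToM",
                           min_points = 10L) {
  n <- length(tcs)
  ids <- names(tcs) %||% sprintf("sub-%03d", seq_len(n))
  groups <- as.character(groups)
  if (!reference_group %in% groups)
    stop(sprintf("reference group '%s' absent from cohort", reference_group))
  nets <- unique(unname(tcs[[1L]]$network_of))
  irc <- lapply(tcs, irc_summary, min_points = min_points)
  net_tcs <- lapply(nets, function(nw) lapply(tcs, network_average, network = nw))
  names(net_tcs) <- nets
  ref_idx <- which(groups == reference_group)
  sim_ref <- sapply(nets, function(nw) {
    refs <- net_tcs[[nw]][ref_idx]
    vapply(seq_len(n), function(i) {
      lo <- match(i, ref_idx)
      similarity_to_reference(net_tcs[[nw]][[i]], refs,
                              leave_out = if (!is.na(lo)) lo else NULL,
                              min_points = min_points)
    }, numeric(1))
  })
  gs <- lapply(nets, function(nw)
    group_similarity_summary(net_tcs[[nw]], groups, min_points = min_points))
  names(gs) <- nets
  t04 <- if (is.null(event_window)) rep(NA_real_, n) else
    vapply(net_tcs[[event_network]], event_magnitude,
           numeric(1), event_window = event_window)
  data.frame(
    subject_id = ids,
    within_tom_z = vapply(irc, `[[`, numeric(1), "within_tom_z"),
    within_pain_z = vapply(irc, `[[`, numeric(1), "within_pain_z"),
    across_z = vapply(irc, `[[`, numeric(1), "across_z"),
    sim_nt_tom_z = sim_ref[, 1L],
    sim_nt_pain_z = sim_ref[, 2L],
    within_group_tom_z = gs[[1L]]$within_group_z,
    across_group_tom_z = gs[[1L]]$across_group_z,
    within_group_pain_z = gs[[2L]]$within_group_z,
    across_group_pain_z = gs[[2L]]$across_group_z,
    t04_magnitude = t04,
    row.names = NULL, stringsAsFactors = FALSE)
}
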