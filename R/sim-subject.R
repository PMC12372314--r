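# Per-subject synthetic data: ROI timecourses and realignment traces.

# Ground-truth artifact TR placement, shared between generate_motion() and
# generate_subject_timecourses() via a common substream of subject_seed, so
# spikes corrupt the realignment trace and the BOLD series at the same TRs.
artifact_indices <- function(config, subject_seed) {
  with_seed(substream_seed(subject_seed, 3L), {
    which(rbinom(config$n_timepoints, 1L, config$artifact_rate) == 1L)
  })
}

#' Construct an ROI timecourse set
#'
#' Container for a subject's T x R ROI timecourse matrix with its
#' ROI-to-network map, sampling interval, and censor mask.
#'
#' @param values Numeric T x R matrix; column names are ROI labels.
#' @param network_of Named character vector mapping ROI label to network.
#' @param tr_seconds Sampling interval (seconds).
#' @param censor Logical length-T vector (`TRUE` = censored) or a
#'   [detect_artifacts()] censor mask; defaults to no censoring.
#' @return Object of class `roi_tc`.
#' @export
roi_timecourse_set <- function(values, network_of, tr_seconds, censor = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- names(network_of)
  if (!all(colnames(values) %in% names(network_of)))
    stop("every ROI column needs a network assignment")
  if (anyDuplicated(colnames(values))) stop("ROI labels must be unique")
  if (!all(is.finite(values))) stop("non-finite timecourse values")
  censored <- censor_logical(censor, nrow(values))
  out <- list(values = values,
              network_of = network_of[colnames(values)],
              tr_seconds = tr_seconds,
              censored = censored)
  class(out) <- "roi_tc"
  out
}

# Accept a raw logical vector, a censor_mask object, or NULL.
censor_logical <- function(censor, T) {
  if (is.null(censor)) return(rep(FALSE, T))
  if (inherits(censor, "censor_mask")) censor <- censor$censored
  if (!is.logical(censor) || length(censor) != T)
    stop("censor mask must be a logical vector matching the series length")
  censor
}

#' @export
print.roi_tc <- function(x, ...) {
  cat(sprintf("ROI timecourse set: %d TRs x %d ROIs (TR %.3g s), %d censored\n",
              nrow(x$values), ncol(x$values), x$tr_seconds, sum(x$censored)))
  invisible(x)
}

#' Generate one subject's ROI timecourses
#'
#' Each ROI `r` in network `N` receives
#' `c[group, N] * f_N + leak * f_N' + a * s + idio_sd * u + noise_sd * eps_r`,
#' where `u` is one idiosyncratic series shared across all of the subject's
#' ROIs and `eps_r` is ROI-specific white noise. When `include_artifacts` is
#' `TRUE` (default), additive spikes of amplitude `config$artifact_bold`
#' (random sign per spike, identical across ROIs) are injected at the
#' subject's ground-truth artifact TRs — the same TRs at which
#' [generate_motion()] spikes the realignment trace. Setting
#' `include_artifacts = FALSE` with the same `subject_seed` yields the
#' artifact-free ground truth, identical elsewhere.
#'
#' @param config A [sim_config()].
#' @param templates Output of [generate_templates()].
#' @param group Group label; must have loadings in the config.
#' @param subject_seed Integer seed for this subject's streams.
#' @param include_artifacts Inject BOLD artifact spikes at the ground-truth
#'   motion TRs?
#' @return An object of class `roi_tc` with attribute `artifact_tr`
#'   (ground-truth artifact TR indices, 1-based).
#' @export
generate_subject_timecourses <- function(config, templates, group, subject_seed,
                                         include_artifacts = TRUE) {
  stopifnot(inherits(config, "sim_config"),
            inherits(templates, "evoked_templates"))
  if (!group %in% names(config$loading_by_group_network))
    stop(sprintf("unknown group label '%s'", group))
  T <- config$n_timepoints
  rois <- names(config$roi_networks)
  R <- length(rois)
  u <- with_seed(substream_seed(subject_seed, 1L), rnorm(T))
  eps <- with_seed(substream_seed(subject_seed, 2L),
                   matrix(rnorm(T * R), T, R))
  loads <- config$loading_by_group_network[[group]]
  other <- setNames(rev(config$networks), config$networks)
  Y <- matrix(0, T, R, dimnames = list(NULL, rois))
  for (j in seq_len(R)) {
    net <- config$roi_networks[[rois[j]]]
    Y[, j] <- loads[[net]] * templates$f[, net] +
      config$cross_network_leak * templates$f[, other[[net]]] +
      config$shared_scale * templates$shared +
      config$idio_sd * u +
      config$noise_sd * eps[, j]
  }
  art <- artifact_indices(config, subject_seed)
  if (include_artifacts && length(art)) {
    signs <- with_seed(substream_seed(subject_seed, 4L),
                       sample(c(-1, 1), length(art), replace = TRUE))
    Y[art, ] <- Y[art, , drop = FALSE] + config$artifact_bold * signs
  }
  out <- roi_timecourse_set(Y, config$roi_networks, config$tr_seconds)
  attr(out, "artifact_tr") <- art
  out
}

#' Generate one subject's realignment trace
#'
#' Six-parameter trace (`trans_x`, `trans_y`, `trans_z` in mm; `rot_x`,
#' `rot_y`, `rot_z` in radians) composed of a smooth random walk, a
#' pseudo-respiratory sinusoid at `config$resp_freq_hz` (random phase per
#' column; rotation amplitude scaled by 1/50 mm), and single-TR displacement
#' pulses of size `config$artifact_fd_mm` at the subject's ground-truth
#' artifact TRs (cycled across the translation columns).
#'
#' @inheritParams generate_subject_timecourses
#' @return Object of class `motion_trace`: list with `values` (T x 6 matrix),
#'   `tr_seconds`, and `artifact_tr` (ground-truth spike TRs, 1-based).
#' @export
generate_motion <- function(config, subject_seed) {
  stopifnot(inherits(config, "sim_config"))
  T <- config$n_timepoints
  cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  tt <- (seq_len(T) - 1L) * config$tr_seconds
  vals <- with_seed(substream_seed(subject_seed, 5L), {
    step_sd <- c(rep(config$walk_sd_mm, 3), rep(config$walk_sd_rad, 3))
    amp <- c(rep(config$resp_amp_mm, 3), rep(config$resp_amp_mm / 50, 3))
    m <- sapply(seq_len(6L), function(j) {
      walk <- cumsum(rnorm(T, sd = step_sd[j]))
      phase <- runif(1, 0, 2 * pi)
      walk + amp[j] * sin(2 * pi * config$resp_freq_hz * tt + phase)
    })
    colnames(m) <- cols
    m
  })
  art <- artifact_indices(config, subject_seed)
  if (length(art)) {
    for (k in seq_along(art)) {
      j <- ((k - 1L) %% 3L) + 1L  # translation columns only
      vals[art[k], j] <- vals[art[k], j] + config$artifact_fd_mm
    }
  }
  out <- list(values = vals, tr_seconds = config$tr_seconds, artifact_tr = art)
  class(out) <- "motion_trace"
  out
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("Realignment trace: %d TRs x 6 params (TR %.3g s), %d ground-truth spikes\n",
              nrow(x$values), x$tr_seconds, length(x$artifact_tr)))
  invisible(x)
}
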