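#' Default ROI-to-network atlas
#'
#' The 13-region atlas used throughout: six Theory of Mind (ToM) regions
#' (dorsal, middle and ventral medial prefrontal cortex, precuneus, right and
#' left temporoparietal junction) and seven Pain-network regions (anterior
#' mid-cingulate cortex, bilateral insula, bilateral middle frontal gyrus,
#' bilateral secondary somatosensory cortex).
#'
#' @return Named character vector mapping ROI label to network label
#'   (`"ToM"` or `"Pain"`).
#' @export
default_roi_networks <- function() {
  c(dMPFC = "ToM", mMPFC = "ToM", vMPFC = "ToM",
    PC = "ToM", rTPJ = "ToM", lTPJ = "ToM",
    AMCC = "Pain", rIns = "Pain", lIns = "Pain",
    rMFG = "Pain", lMFG = "Pain", rS2 = "Pain", lS2 = "Pain")
}

#' Default behavioral score configuration for the synthetic cohort
#'
#' Group means and SDs for age, full-scale IQ, sex, handedness and the three
#' behavioral scores (MASC mental-state inference accuracy, AQ autistic
#' traits, EQ empathy), plus the brain-behavior coupling: by default MASC is
#' generated with a positive slope against within-ToM inter-region correlation
#' in the NT group only. Score ranges are clipped to their instruments'
#' bounds (MASC 0-45, AQ 0-50, EQ 0-120).
#'
#' @return A list consumed by [sim_config()].
#' @export
default_behavior_config <- function() {
  list(
    age  = list(NT = c(mean = 27.4, sd = 7.2), ASD = c(mean = 27.1, sd = 5.4), min = 18),
    fsiq = list(NT = c(mean = 109.9, sd = 10.7), ASD = c(mean = 112.9, sd = 13.2), min = 80),
    sex_female_prob = c(NT = 0.315, ASD = 0.324),
    hand_right_prob = c(NT = 0.88, ASD = 0.79),
    aq   = list(NT = c(mean = 16.4, sd = 6.8), ASD = c(mean = 27.9, sd = 9.2),
                min = 0, max = 50),
    eq   = list(NT = c(mean = 47.3, sd = 14.1), ASD = c(mean = 33.1, sd = 17.1),
                min = 0, max = 120),
    masc = list(NT = c(mean = 35.5, sd = 3.5), ASD = c(mean = 29.4, sd = 8.8),
                min = 0, max = 45),
    # MASC ~ standardized within-ToM IRC, NT only; residual sd keeps the
    # total NT MASC sd near its configured value (sqrt(3.5^2 - 2^2) ~ 2.87).
    coupling = list(masc = list(metric = "within_tom_z", slope = 2.0,
                                group = "NT", resid_sd = 2.87)),
    missing_rate = c(masc = 0.15, aq = 0.03, eq = 0.05, fsiq = 0.03)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure the generator emulates: two networks of
#' ROIs sharing stimulus-evoked template signals with group-specific loadings,
#' a shared audiovisual component, one idiosyncratic series per subject,
#' cross-network leakage, white ROI noise, and motion traces with injected
#' artifact spikes that corrupt both the realignment parameters and the BOLD
#' series at the same TRs (so censoring is consequential).
#'
#' Each ROI timecourse is generated as
#' \deqn{y_r(t) = c_{g,N} f_N(t) + \lambda f_{N'}(t) + a s(t) +
#'   \sigma_u u_i(t) + \sigma_e \epsilon_r(t)}
#' where \eqn{f_N} is the network's evoked template, \eqn{f_{N'}} the opposite
#' network's, \eqn{s} a shared audiovisual component, \eqn{u_i} a subject-level
#' idiosyncratic series shared across that subject's ROIs, and \eqn{\epsilon_r}
#' ROI-specific white noise.
#'
#' @param n_per_group Named integer vector, subjects per group. Default
#'   `c(ASD = 38, NT = 78)`, the initial two-site cohort size before motion
#'   exclusion.
#' @param n_timepoints Number of TRs (default 548, a plausible ~6.6 min scan at
#'   `tr_seconds = 0.72`; the scan length is configurable because it is not a
#'   fixed property of the design).
#' @param tr_seconds Sampling interval in seconds.
#' @param roi_networks Named character vector mapping ROI label to network
#'   label; must cover exactly two networks. See [default_roi_networks()].
#' @param loading_by_group_network List of named numeric vectors: evoked-signal
#'   loading \eqn{c_{g,N}} per group and network. NT defaults exceed ASD
#'   defaults on both networks, so within-NT > across-group > within-ASD
#'   similarity holds in expectation.
#' @param cross_network_leak Fraction \eqn{\lambda} of the opposite network's
#'   evoked signal bleeding into each ROI.
#' @param shared_scale Loading \eqn{a} of the shared audiovisual component.
#' @param idio_sd Scale \eqn{\sigma_u} of the subject-level idiosyncratic
#'   series.
#' @param noise_sd Scale \eqn{\sigma_e} of ROI-specific white noise.
#' @param artifact_rate Per-TR probability of a motion artifact spike
#'   (expected spikes per subject = `artifact_rate * n_timepoints`).
#' @param artifact_fd_mm Size (mm) of the single-TR displacement pulse injected
#'   into the realignment trace at each artifact TR.
#' @param artifact_bold Amplitude of the additive BOLD spike (same TRs, all
#'   ROIs, random sign per spike), in pre-normalization signal units.
#' @param walk_sd_mm,walk_sd_rad Per-TR step SD of the smooth random-walk
#'   component of the translations (mm) and rotations (radians).
#' @param resp_freq_hz,resp_amp_mm Frequency and amplitude of the
#'   pseudo-respiratory sinusoid contaminating the realignment traces.
#' @param template_fwhm_s Gaussian smoothing kernel FWHM (seconds) used to
#'   build the evoked templates from white noise.
#' @param template_max_r Bound on |cor| between the two network templates.
#' @param behavior Behavioral score configuration; see
#'   [default_behavior_config()].
#' @param sites Character vector of site labels.
#' @param site_prob Probability of assignment to the first site.
#' @param seed Integer PRNG seed; all cohort randomness derives from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [generate_templates()]
#' @export
sim_config <- function(n_per_group = c(ASD = 38, NT = 78),
                       n_timepoints = 548,
                       tr_seconds = 0.72,
                       roi_networks = default_roi_networks(),
                       loading_by_group_network = list(
                         NT = c(ToM = 0.60, Pain = 0.65),
                         ASD = c(ToM = 0.40, Pain = 0.50)),
                       cross_network_leak = 0.1,
                       shared_scale = 0.3,
                       idio_sd = 1.0,
                       noise_sd = 1.5,
                       artifact_rate = 0.005,
                       artifact_fd_mm = 2.0,
                       artifact_bold = 5.0,
                       walk_sd_mm = 0.015,
                       walk_sd_rad = 3e-4,
                       resp_freq_hz = 0.33,
                       resp_amp_mm = 0.15,
                       template_fwhm_s = 10,
                       template_max_r = 0.1,
                       behavior = default_behavior_config(),
                       sites = c("IU", "CAL"),
                       site_prob = 0.6,
                       seed = 1L) {
  # tolerate list-valued inputs (e.g. from YAML/JSON configs)
  if (is.list(n_per_group)) n_per_group <- unlist(n_per_group)
  loading_by_group_network <- lapply(loading_by_group_network,
                                     function(x) if (is.list(x)) unlist(x) else x)
  if (is.list(roi_networks)) roi_networks <- unlist(roi_networks)
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group))))
    stop("'n_per_group' must be a named vector of group sizes")
  if (any(n_per_group < 1)) stop("each group needs at least one subject")
  stopifnot_scalar(n_timepoints, "n_timepoints", min = 8, strict_min = TRUE)
  stopifnot_scalar(tr_seconds, "tr_seconds", min = 0, strict_min = TRUE)
  networks <- unique(unname(roi_networks))
  if (length(networks) != 2L)
    stop("'roi_networks' must cover exactly two networks")
  if (anyDuplicated(names(roi_networks)))
    stop("ROI labels must be unique")
  for (g in names(n_per_group)) {
    ld <- loading_by_group_network[[g]]
    if (is.null(ld) || !all(networks %in% names(ld)))
      stop(sprintf("missing loadings for group '%s'", g))
    if (any(ld < 0)) stop("loadings must be >= 0")
  }
  for (nm in c("cross_network_leak", "shared_scale", "idio_sd", "noise_sd",
               "artifact_rate", "artifact_fd_mm", "artifact_bold",
               "walk_sd_mm", "walk_sd_rad", "resp_amp_mm"))
    stopifnot_scalar(get(nm), nm, min = 0)
  stopifnot_scalar(template_fwhm_s, "template_fwhm_s", min = 0, strict_min = TRUE)
  if (artifact_rate > 1) stop("'artifact_rate' is a per-TR probability (<= 1)")
  cfg <- list(
    n_per_group = n_per_group, n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds, roi_networks = roi_networks,
    networks = networks,
    loading_by_group_network = loading_by_group_network,
    cross_network_leak = cross_network_leak, shared_scale = shared_scale,
    idio_sd = idio_sd, noise_sd = noise_sd,
    artifact_rate = artifact_rate, artifact_fd_mm = artifact_fd_mm,
    artifact_bold = artifact_bold,
    walk_sd_mm = walk_sd_mm, walk_sd_rad = walk_sd_rad,
    resp_freq_hz = resp_freq_hz, resp_amp_mm = resp_amp_mm,
    template_fwhm_s = template_fwhm_s, template_max_r = template_max_r,
    behavior = behavior, sites = sites, site_prob = site_prob,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d)", names(x$n_per_group), x$n_per_group),
                    collapse = ", ")))
  cat(sprintf("  %d TRs at %.3g s; %d ROIs in networks %s\n",
              x$n_timepoints, x$tr_seconds, length(x$roi_networks),
              paste(x$networks, collapse = "/")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
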