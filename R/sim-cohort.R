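# Whole-cohort simulation and plain-text serialization.

#' Simulate a complete synthetic cohort
#'
#' Generates evoked templates, per-subject ROI timecourses and realignment
#' traces, and a cohort table with behavioral scores. The MASC coupling uses
#' each subject's latent (artifact-free) within-ToM inter-region correlation,
#' i.e. the subject's true neural trait; downstream pipeline stages then
#' re-measure IRC from the corrupted data with censoring, so observed
#' brain-behavior associations include realistic measurement attenuation.
#'
#' All randomness derives from `config$seed` through fixed substreams: subject
#' `i` always receives the same data for a given seed regardless of cohort
#' composition.
#'
#' @param config A [sim_config()].
#' @return Object of class `synthetic_cohort`: list with `config`,
#'   `templates`, `cohort` (data frame: subject_id, group, site, demographics,
#'   behavior), `timecourses` (named list of `roi_tc`), `motion` (named list
#'   of `motion_trace`), and `ground_truth` (per-subject seeds and artifact
#'   TRs, group loadings).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  templates <- generate_templates(config)
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(groups)
  ids <- sprintf("sub-%03d", seq_len(n))
  site <- with_seed(substream_seed(config$seed, 6L), {
    ifelse(runif(n) < config$site_prob, config$sites[1L], config$sites[2L])
  })
  sub_seeds <- vapply(seq_len(n), function(i) substream_seed(config$seed, 100L + i),
                      integer(1))
  tcs <- vector("list", n); mots <- vector("list", n)
  latent_irc <- numeric(n)
  for (i in seq_len(n)) {
    tcs[[i]] <- generate_subject_timecourses(config, templates, groups[i],
                                             sub_seeds[i])
    mots[[i]] <- generate_motion(config, sub_seeds[i])
    clean <- generate_subject_timecourses(config, templates, groups[i],
                                          sub_seeds[i], include_artifacts = FALSE)
    latent_irc[i] <- irc_summary(clean)$within_tom_z
  }
  names(tcs) <- ids; names(mots) <- ids
  cohort <- data.frame(subject_id = ids, group = groups, site = site,
                       stringsAsFactors = FALSE)
  cohort <- generate_behavior(config, cohort,
                              data.frame(subject_id = ids,
                                         within_tom_z = latent_irc))
  gt <- list(seed = config$seed,
             subject_seeds = setNames(as.list(sub_seeds), ids),
             artifact_tr = setNames(lapply(mots, `[[`, "artifact_tr"), ids),
             loadings = config$loading_by_group_network,
             latent_within_tom_z = setNames(as.list(latent_irc), ids))
  out <- list(config = config, templates = templates, cohort = cohort,
              timecourses = tcs, motion = mots, ground_truth = gt)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s), %d TRs x %d ROIs\n",
              nrow(x$cohort),
              paste(sprintf("%s n=%d", names(x$config$n_per_group),
                            x$config$n_per_group), collapse = ", "),
              x$config$n_timepoints, length(x$config$roi_networks)))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes per-subject wide TSV timecourses (header = ROI labels), 6-column
#' realignment TSVs (`trans_x` ... `rot_z`; mm and radians), the cohort table
#' as CSV, the event table as TSV, the ROI-to-network atlas as a 2-column TSV,
#' and a ground-truth JSON (seeds, loadings, artifact indices).
#'
#' @param sc A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sc, dir) {
  stopifnot(inherits(sc, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "timecourses"), showWarnings = FALSE)
  dir.create(file.path(dir, "motion"), showWarnings = FALSE)
  for (id in names(sc$timecourses)) {
    write_timecourse_tsv(sc$timecourses[[id]],
                         file.path(dir, "timecourses", paste0(id, "_timecourse.tsv")))
    write_motion_tsv(sc$motion[[id]],
                     file.path(dir, "motion", paste0(id, "_motion.tsv")))
  }
  write.csv(sc$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  write.table(sc$templates$event_table, file.path(dir, "events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  atlas <- data.frame(roi = names(sc$config$roi_networks),
                      network = unname(sc$config$roi_networks))
  write.table(atlas, file.path(dir, "atlas.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sc$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
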