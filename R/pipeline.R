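# End-to-end orchestration: simulate-or-load -> motion QC -> exclusions ->
# group matching -> temporal prep -> metrics -> hypothesis battery.

#' Default run configuration
#'
#' @param seed Integer seed driving all randomness in a synthetic run.
#' @param mode `"synthetic"` (generate a cohort) or `"real"` (load files from
#'   `paths`).
#' @return A nested configuration list; override elements before passing to
#'   [run_pipeline()]. Sections: `sim` ([sim_config()] arguments), `motion`
#'   (`threshold_mm`, `pad`, `band_hz`, `radius_mm`, `filter_order`,
#'   `fixed_thresholds`), `prep` (`cutoff_s`, `order`), `metrics`
#'   (`reference_group`, `min_points`, `event_label`, `event_network`),
#'   `battery` (`prune_alpha`, `standardize`), `paths` (real mode: `cohort_csv`,
#'   `timecourse_dir`, `motion_dir`, `event_tsv`, `atlas_tsv`), `output_dir`.
#' @export
default_run_config <- function(seed = 1L, mode = "synthetic") {
  list(mode = mode, seed = as.integer(seed),
       sim = list(),
       motion = list(threshold_mm = 0.5, pad = 2L, band_hz = c(0.31, 0.43),
                     radius_mm = 50, filter_order = 10L,
                     fixed_thresholds = NULL),
       prep = list(cutoff_s = 100, order = 5L),
       metrics = list(reference_group = "NT", min_points = 10L,
                      event_label = "T04", event_network = "ToM"),
       battery = list(prune_alpha = 0.05, standardize = TRUE),
       paths = list(), output_dir = NULL)
}

#' Read a run configuration from YAML or JSON
#'
#' Values in the file override the defaults from [default_run_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_run_config(seed = cfg$seed %||% 1L, mode = cfg$mode %||% "synthetic")
  modifyList(base, cfg)
}

load_real_cohort <- function(config) {
  p <- config$paths
  for (need in c("cohort_csv", "timecourse_dir", "motion_dir", "atlas_tsv"))
    if (is.null(p[[need]])) stop("real mode requires paths$", need)
  cohort <- read.csv(p$cohort_csv, stringsAsFactors = FALSE)
  atlas <- read_atlas_tsv(p$atlas_tsv)
  trs <- config$tr_seconds %||% 0.72
  tcs <- list(); mots <- list()
  for (id in cohort$subject_id) {
    tcs[[id]] <- read_timecourse_tsv(
      file.path(p$timecourse_dir, paste0(id, "_timecourse.tsv")), atlas, trs)
    mots[[id]] <- read_motion_tsv(
      file.path(p$motion_dir, paste0(id, "_motion.tsv")), trs)
  }
  events <- if (!is.null(p$event_tsv)) read_event_tsv(p$event_tsv) else NULL
  list(cohort = cohort, timecourses = tcs, motion = mots, events = events)
}

#' Run the full analysis pipeline
#'
#' Executes simulate-or-load, motion QC (FDfilt4, artifact censoring),
#' subject exclusion, group matching on motion, temporal preparation,
#' metric computation, and the hypothesis battery, with a run manifest.
#' All randomness flows from `config$seed`; the same configuration always
#' yields identical results.
#'
#' @param config Configuration list from [default_run_config()] /
#'   [read_run_config()], or a path to a YAML/JSON config.
#' @return Object of class `movieisc_run`: list with `manifest` (seed, config
#'   checksum, per-gate subject counts, exclusion report, motion-matching
#'   removals), `cohort` (retained subjects with QC columns), `qc` (full QC
#'   table), `metrics`, `battery`, `event_window`, and in synthetic mode the
#'   `synthetic` cohort object.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$mode)) stop("config$mode missing")
  events <- NULL
  if (config$mode == "synthetic") {
    sc <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    sim <- simulate_cohort(sc)
    cohort <- sim$cohort; tcs <- sim$timecourses; mots <- sim$motion
    events <- sim$templates$event_table
    trs <- sc$tr_seconds
  } else if (config$mode == "real") {
    real <- load_real_cohort(config)
    cohort <- real$cohort; tcs <- real$timecourses; mots <- real$motion
    events <- real$events
    sim <- NULL
    trs <- tcs[[1L]]$tr_seconds
  } else stop("mode must be 'synthetic' or 'real'")
  n0 <- nrow(cohort)

  mo <- config$motion
  fd <- lapply(mots, compute_fd_filt4, band_hz = mo$band_hz,
               radius_mm = mo$radius_mm, filter_order = mo$filter_order)
  masks <- lapply(fd, detect_artifacts, threshold_mm = mo$threshold_mm,
                  pad = mo$pad)
  qc <- data.frame(subject_id = cohort$subject_id,
                   group = cohort$group, site = cohort$site,
                   mean_fd = vapply(fd, `[[`, numeric(1), "mean_fd")[cohort$subject_id],
                   n_censored = vapply(masks, `[[`, numeric(1), "n_censored")[cohort$subject_id],
                   frac_censored = vapply(masks, `[[`, numeric(1), "frac_censored")[cohort$subject_id],
                   stringsAsFactors = FALSE)
  qc <- exclude_subjects(qc, fixed_thresholds = mo$fixed_thresholds)
  keep1 <- qc$subject_id[!qc$excluded]
  n1 <- length(keep1)

  removed <- match_groups_on_motion(qc[qc$subject_id %in% keep1, ])
  keep2 <- setdiff(keep1, removed)
  n2 <- length(keep2)
  if (n2 < 4L) stop("too few subjects survive QC")

  pp <- config$prep
  prepped <- lapply(keep2, function(id) {
    tc <- tcs[[id]]
    tc$censored <- masks[[id]]$censored
    prep_timecourses(tc, cutoff_s = pp$cutoff_s, order = pp$order)
  })
  names(prepped) <- keep2

  me <- config$metrics
  ev_win <- NULL
  if (!is.null(events) && me$event_label %in% events$label) {
    er <- events[events$label == me$event_label, ][1L, ]
    ev_win <- c(er$start_tr, er$end_tr)
  }
  groups2 <- cohort$group[match(keep2, cohort$subject_id)]
  metrics <- cohort_metrics(prepped, groups2,
                            reference_group = me$reference_group,
                            event_window = ev_win,
                            event_network = me$event_network,
                            min_points = me$min_points)

  cohort2 <- merge(cohort[cohort$subject_id %in% keep2, ],
                   qc[, c("subject_id", "mean_fd", "n_censored", "frac_censored")],
                   by = "subject_id")
  ba <- config$battery
  battery <- run_hypothesis_battery(metrics, cohort2,
                                    reference_group = me$reference_group,
                                    prune_alpha = ba$prune_alpha,
                                    standardize = ba$standardize)

  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  manifest <- list(
    package_version = as.character(packageVersion("movieisc")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    tr_seconds = trs,
    subject_counts = c(input = n0, after_exclusion = n1, after_matching = n2),
    exclusion_thresholds = attr(qc, "thresholds"),
    excluded_subjects = qc$subject_id[qc$excluded],
    matching_removed = removed,
    event_window = ev_win)
  unlink(cfg_file)
  out <- list(manifest = manifest, cohort = cohort2, qc = qc,
              metrics = metrics, battery = battery, event_window = ev_win,
              synthetic = sim, config = config)
  class(out) <- "movieisc_run"
  if (!is.null(config$output_dir)) write_run(out, config$output_dir)
  out
}

#' @export
print.movieisc_run <- function(x, ...) {
  m <- x$manifest
  cat("movieisc pipeline run\n")
  cat(sprintf("  seed %d; subjects %d -> %d (exclusion) -> %d (matching)\n",
              m$seed, m$subject_counts["input"],
              m$subject_counts["after_exclusion"],
              m$subject_counts["after_matching"]))
  print(x$battery)
  invisible(x)
}

#' Write pipeline results to plain-text files
#'
#' Writes the metric table and battery term table as TSV, and the QC table and
#' manifest as CSV/JSON, into `dir`.
#'
#' @param run A `movieisc_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(run$metrics, file.path(dir, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(run$battery), file.path(dir, "battery.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(run$qc, file.path(dir, "qc.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Human-readable summary report
#'
#' Builds a demographics/QC table (per-group n, mean and SD of motion and
#' behavioral measures, with Welch group tests) and the term-level results
#' table of the battery.
#'
#' @param run A `movieisc_run`.
#' @return List with `demographics` and `results` data frames.
#' @export
make_report <- function(run) {
  stopifnot(inherits(run, "movieisc_run"))
  co <- run$cohort
  groups <- unique(co$group)
  if (length(groups) < 2L || any(table(co$group) == 0L))
    stop("report requires two non-empty groups")
  vars <- intersect(c("mean_fd", "n_censored", "age", "fsiq", "masc", "aq", "eq"),
                    names(co))
  rows <- lapply(vars, function(v) {
    x <- split(co[[v]], co$group)
    g1 <- groups[1L]; g2 <- groups[2L]
    w <- tryCatch(welch_t(x = x[[g1]], y = x[[g2]]),
                  error = function(e) list(t = NA, p = NA, d = NA))
    df <- data.frame(measure = v, stringsAsFactors = FALSE)
    for (g in groups) {
      df[[paste0("n_", g)]] <- sum(!is.na(x[[g]]))
      df[[paste0("mean_", g)]] <- mean(x[[g]], na.rm = TRUE)
      df[[paste0("sd_", g)]] <- sd(x[[g]], na.rm = TRUE)
    }
    df$t <- w$t; df$p <- w$p; df$d <- w$d
    df
  })
  list(demographics = do.call(rbind, rows),
       results = as.data.frame(run$battery))
}
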