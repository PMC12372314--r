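# Behavioral score generation for the synthetic cohort.

rnorm_clip <- function(n, mean, sd, min = -Inf, max = Inf) {
  pmin(pmax(rnorm(n, mean, sd), min), max)
}

#' Generate behavioral and demographic scores for a synthetic cohort
#'
#' Draws age, full-scale IQ (FSIQ), sex, handedness, AQ, EQ and MASC scores
#' from the group-specific distributions in `config$behavior`. Group mean
#' shifts follow the expected clinical sign pattern (higher AQ, lower MASC and
#' EQ in the ASD group). The MASC is coupled to a neural metric per
#' `config$behavior$coupling`: by default a positive slope against the
#' standardized within-ToM inter-region correlation, in the NT group only.
#' Scores can be missing at random at the configured per-score rates,
#' mimicking incomplete behavioral batteries.
#'
#' Deterministic given `config$seed` (uses its own substream, so results do
#' not depend on how much randomness was consumed elsewhere).
#'
#' @param config A [sim_config()].
#' @param cohort Data frame with at least `subject_id` and `group`.
#' @param neural_metrics Data frame with `subject_id` and the metric columns
#'   referenced by the coupling (default `within_tom_z`), one row per subject.
#' @return `cohort` with columns `age`, `sex`, `hand`, `fsiq`, `aq`, `eq`,
#'   `masc` appended.
#' @export
generate_behavior <- function(config, cohort, neural_metrics) {
  stopifnot(inherits(config, "sim_config"))
  bc <- config$behavior
  for (cp in bc$coupling) {
    if (!cp$metric %in% names(neural_metrics))
      stop(sprintf("coupling references unknown neural metric '%s'", cp$metric))
  }
  if (!all(cohort$subject_id %in% neural_metrics$subject_id))
    stop("neural metrics missing for some subjects")
  nm <- neural_metrics[match(cohort$subject_id, neural_metrics$subject_id), ,
                       drop = FALSE]
  n <- nrow(cohort)
  g <- as.character(cohort$group)
  with_seed(substream_seed(config$seed, 7L), {
    draw2 <- function(spec) {
      out <- numeric(n)
      for (grp in unique(g)) {
        i <- g == grp
        out[i] <- rnorm_clip(sum(i), spec[[grp]]["mean"], spec[[grp]]["sd"],
                             spec$min %||% -Inf, spec$max %||% Inf)
      }
      out
    }
    cohort$age <- round(draw2(bc$age))
    cohort$sex <- ifelse(runif(n) < bc$sex_female_prob[g], "F", "M")
    cohort$hand <- ifelse(runif(n) < bc$hand_right_prob[g], "R", "L")
    cohort$fsiq <- round(draw2(bc$fsiq))
    cohort$aq <- round(draw2(bc$aq))
    cohort$eq <- round(draw2(bc$eq))
    masc <- numeric(n)
    cp <- bc$coupling$masc
    for (grp in unique(g)) {
      i <- g == grp
      spec <- bc$masc[[grp]]
      if (!is.null(cp) && grp %in% cp$group && cp$slope != 0) {
        zstd <- scale(nm[[cp$metric]][i])[, 1L]
        masc[i] <- spec["mean"] + cp$slope * zstd +
          rnorm(sum(i), 0, cp$resid_sd)
      } else {
        masc[i] <- rnorm(sum(i), spec["mean"], spec["sd"])
      }
    }
    cohort$masc <- round(pmin(pmax(masc, bc$masc$min), bc$masc$max))
    for (sc in names(bc$missing_rate)) {
      miss <- runif(n) < bc$missing_rate[[sc]]
      cohort[[sc]][miss] <- NA
    }
    cohort
  })
}
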