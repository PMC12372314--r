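# The preregistration-style hypothesis battery: one model or test per
# hypothesis, assembled into a single typed bundle.

battery_lm_specs <- function() {
  list(
    irc_tom_group     = list(out = "within_tom_z", pred = "group",
                             inter = "group:site", null_hyp = FALSE),
    irc_pain_group    = list(out = "within_pain_z", pred = "group",
                             inter = "group:site", null_hyp = TRUE),
    irc_across_group  = list(out = "across_z", pred = "group",
                             inter = "group:site", null_hyp = FALSE),
    sim_nt_tom_group  = list(out = "sim_nt_tom_z", pred = "group",
                             inter = "group:site", null_hyp = FALSE),
    sim_nt_pain_group = list(out = "sim_nt_pain_z", pred = "group",
                             inter = "group:site", null_hyp = TRUE),
    sim_irc_tom  = list(out = "sim_nt_tom_z",
                        pred = c("within_tom_z", "across_z", "group"),
                        inter = c("group:within_tom_z", "group:across_z",
                                  "group:site"), null_hyp = FALSE),
    sim_irc_pain = list(out = "sim_nt_pain_z",
                        pred = c("within_pain_z", "across_z", "group"),
                        inter = c("group:within_pain_z", "group:across_z",
                                  "group:site"), null_hyp = FALSE),
    bb_masc_tom  = list(out = "within_tom_z", pred = c("masc", "group"),
                        inter = c("group:masc", "group:site"),
                        null_hyp = FALSE, bonferroni_k = 2),
    bb_aq_tom    = list(out = "within_tom_z", pred = c("aq", "group"),
                        inter = c("group:aq", "group:site"),
                        null_hyp = FALSE, bonferroni_k = 2),
    bb_t04_masc  = list(out = "t04_magnitude", pred = c("masc", "group"),
                        inter = c("group:masc", "group:site"), null_hyp = FALSE),
    bb_eq_pain   = list(out = "within_pain_z", pred = c("eq", "group"),
                        inter = c("group:eq", "group:site"), null_hyp = FALSE)
  )
}

#' Run the full hypothesis battery
#'
#' Fits the fixed, preregistration-style analysis set on the joined
#' metric/cohort table:
#'
#' * **Group models** (pruned linear models controlling for head motion, age,
#'   sex, FSIQ and site, with a `group:site` interaction candidate): group
#'   effects on within-ToM, within-Pain and across-network IRC and on
#'   similarity to the reference-group average per network.
#' * **Association models**: similarity to the reference average regressed on
#'   within- and across-network IRC with group interactions.
#' * **Brain-behavior models**: within-ToM IRC on MASC and on AQ (each with a
#'   group interaction; Bonferroni-adjusted threshold for the two tests),
#'   event response magnitude on MASC, within-Pain IRC on EQ.
#' * **Heterogeneity t-tests**: paired within- vs across-group similarity per
#'   network per group; Welch within-group similarity NT vs ASD per network.
#'
#' For models whose preregistered hypothesis is a null group effect (the Pain
#' network models), a BIC-approximate Bayes factor `BF01` for dropping the
#' group term is attached when the group p-value exceeds 0.05.
#'
#' @param metrics Per-subject metric table from [cohort_metrics()].
#' @param cohort Cohort table with `subject_id`, `group`, `site`, covariates
#'   (`mean_fd`, `age`, `sex`, `fsiq`) and behavior scores.
#' @param reference_group Reference level for the group factor (default
#'   `"NT"`), so group coefficients read as other-group minus reference.
#' @param prune_alpha Interaction pruning threshold.
#' @param standardize Report standardized coefficient tables as well?
#' @return Object of class `hypothesis_battery`: list with `models` (named
#'   `pruned_lm_fit`s), `paired` (4 paired-t results), `welch` (2 Welch
#'   results), `bayes` (named BF01 values), `bonferroni_alpha`, `n_tests`.
#' @export
run_hypothesis_battery <- function(metrics, cohort, reference_group = "NT",
                                   prune_alpha = 0.05, standardize = TRUE) {
  tab <- merge(cohort, metrics, by = "subject_id")
  need <- c("within_tom_z", "within_pain_z", "across_z", "sim_nt_tom_z",
            "sim_nt_pain_z", "within_group_tom_z", "across_group_tom_z",
            "within_group_pain_z", "across_group_pain_z")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing metric columns: ", paste(miss, collapse = ", "))
  glv <- unique(as.character(tab$group))
  tab$group <- factor(tab$group,
                      levels = c(reference_group, setdiff(glv, reference_group)))
  covs <- intersect(c("mean_fd", "age", "sex", "fsiq", "site"), names(tab))
  models <- list(); bayes <- list()
  for (nm in names(battery_lm_specs())) {
    sp <- battery_lm_specs()[[nm]]
    if (!all(c(sp$out, setdiff(sp$pred, "group")) %in% names(tab))) next
    if (all(is.na(tab[[sp$out]]))) next  # e.g. no event window supplied
    inter <- sp$inter[vapply(strsplit(sp$inter, ":", fixed = TRUE),
                             function(v) all(v %in% names(tab)), logical(1))]
    fit <- fit_pruned_lm(sp$out, sp$pred, covs, inter, tab,
                         prune_alpha = prune_alpha, standardize = standardize)
    models[[nm]] <- fit
    if (isTRUE(sp$null_hyp)) {
      grp_p <- fit$coef$p[grepl("^group", fit$coef$term)][1L]
      if (is.finite(grp_p) && grp_p > 0.05) {
        # covariates-only null: remove the group term and any interaction
        # involving it
        alt <- fit$model
        labs <- labels(terms(alt))
        keep_labs <- labs[!vapply(strsplit(labs, ":", fixed = TRUE),
                                  function(v) "group" %in% v, logical(1))]
        null <- update(alt, as.formula(paste(". ~", paste(keep_labs, collapse = "+"))),
                       data = fit$model$model)
        bayes[[nm]] <- bf01_null_evidence(null, alt)
      }
    }
  }
  groups2 <- levels(tab$group)
  paired <- list()
  for (g in groups2) {
    sub <- tab[tab$group == g, ]
    paired[[paste0("hetero_tom_", g)]] <-
      paired_t(sub$across_group_tom_z, sub$within_group_tom_z)
    paired[[paste0("hetero_pain_", g)]] <-
      paired_t(sub$across_group_pain_z, sub$within_group_pain_z)
  }
  other <- setdiff(groups2, reference_group)[1L]
  welch <- list(
    within_group_tom = welch_t(
      x = tab$within_group_tom_z[tab$group == reference_group],
      y = tab$within_group_tom_z[tab$group == other]),
    within_group_pain = welch_t(
      x = tab$within_group_pain_z[tab$group == reference_group],
      y = tab$within_group_pain_z[tab$group == other]))
  out <- list(models = models, paired = paired, welch = welch, bayes = bayes,
              bonferroni_alpha = bonferroni_adjust(numeric(0), k = 2)$alpha_adjusted,
              n = nrow(tab),
              n_tests = length(models) + length(paired) + length(welch))
  class(out) <- "hypothesis_battery"
  out
}

#' @export
print.hypothesis_battery <- function(x, ...) {
  cat(sprintf("Hypothesis battery: %d tests on %d subjects\n", x$n_tests, x$n))
  cat(sprintf("  %d linear models, %d paired t-tests, %d Welch tests, %d Bayes factors\n",
              length(x$models), length(x$paired), length(x$welch),
              length(x$bayes)))
  invisible(x)
}

#' Flatten a hypothesis battery into a term-level table
#'
#' @param x A `hypothesis_battery`.
#' @param row.names,optional Unused (S3 signature).
#' @param ... Unused.
#' @return Data frame, one row per model term or test, with columns
#'   `analysis`, `term`, `estimate`, `se`, `t`, `df`, `p`, `d`, `n`, `bf01`.
#' @export
as.data.frame.hypothesis_battery <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  rows <- list()
  for (nm in names(x$models)) {
    f <- x$models[[nm]]
    ct <- f$coef
    rows[[nm]] <- data.frame(analysis = nm, term = ct$term,
                             estimate = ct$estimate, se = ct$se, t = ct$t,
                             df = f$model$df.residual, p = ct$p, d = ct$d,
                             n = f$n,
                             bf01 = if (!is.null(x$bayes[[nm]])) x$bayes[[nm]] else NA_real_,
                             stringsAsFactors = FALSE)
  }
  for (nm in names(x$paired)) {
    r <- x$paired[[nm]]
    rows[[nm]] <- data.frame(analysis = nm, term = "paired_diff",
                             estimate = r$mean_diff, se = NA_real_, t = r$t,
                             df = r$df, p = r$p, d = r$d, n = r$n,
                             bf01 = NA_real_, stringsAsFactors = FALSE)
  }
  for (nm in names(x$welch)) {
    r <- x$welch[[nm]]
    rows[[nm]] <- data.frame(analysis = nm, term = "group_diff",
                             estimate = r$mean_diff, se = r$se, t = r$t,
                             df = r$df, p = r$p, d = r$d, n = r$n1 + r$n2,
                             bf01 = NA_real_, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
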