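# Statistical battery primitives: Welch and paired t-tests with Cohen's d,
# pruned covariate-adjusted linear models, BIC-approximate Bayes factors,
# Bonferroni adjustment.

#' Welch two-sample t-test from raw samples or printed summary statistics
#'
#' Computes the Welch statistic with Satterthwaite degrees of freedom. Accepts
#' either raw samples (`x`, `y`) or summary statistics (mean, SD, n per
#' group), so results printed in papers can be checked directly. The sign
#' convention is `group2 - group1`. Cohen's d uses the pooled SD with
#' `(n - 1)` weights.
#'
#' @param x,y Raw samples (optional; `NA`s dropped).
#' @param m1,sd1,n1,m2,sd2,n2 Summary statistics, used when `x`/`y` are
#'   missing.
#' @return List with `t`, `df`, `p` (two-sided), `d`, `mean_diff`
#'   (`m2 - m1`), `se`, and the group summaries.
#' @examples
#' # heterogeneity comparison from printed group summaries
#' welch_t(m1 = 0.18, sd1 = 0.07, n1 = 73, m2 = 0.12, sd2 = 0.07, n2 = 34)
#' @export
welch_t <- function(x = NULL, y = NULL, m1, sd1, n1, m2, sd2, n2) {
  if (!is.null(x) || !is.null(y)) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    m1 <- mean(x); sd1 <- sd(x); n1 <- length(x)
    m2 <- mean(y); sd2 <- sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (!(sd1 > 0) || !(sd2 > 0)) stop("degenerate (zero) group variance")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  tt <- (m2 - m1) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  sd_pool <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df),
       d = (m2 - m1) / sd_pool, mean_diff = m2 - m1, se = se,
       m1 = m1, sd1 = sd1, n1 = n1, m2 = m2, sd2 = sd2, n2 = n2)
}

#' Paired t-test with effect size
#'
#' Classical paired t on `y - x` with `d = mean(diff) / sd(diff)` and the 95%
#' confidence interval of the mean difference. Zero-variance differences are
#' an error, except the degenerate no-difference case (`y` identical to `x`),
#' which returns `t = 0, d = 0, p = 1`.
#'
#' @param x,y Paired samples; pairs with a missing value are dropped.
#' @return List with `t`, `df`, `p`, `d`, `mean_diff`, `ci95`, `n`.
#' @export
paired_t <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  d <- y[keep] - x[keep]
  n <- length(d)
  if (n < 3L) stop("need at least 3 complete pairs")
  sdd <- sd(d)
  if (sdd == 0) {
    if (all(d == 0))
      return(list(t = 0, df = n - 1, p = 1, d = 0, mean_diff = 0,
                  ci95 = c(0, 0), n = n))
    stop("zero-variance differences")
  }
  se <- sdd / sqrt(n)
  tt <- mean(d) / se
  df <- n - 1
  half <- qt(0.975, df) * se
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df), d = mean(d) / sdd,
       mean_diff = mean(d), ci95 = c(mean(d) - half, mean(d) + half), n = n)
}

# Standardize the numeric columns of a model data frame (0/1 and factor
# columns untouched), so coefficients are on comparable scales.
standardize_columns <- function(data, vars) {
  for (v in vars) {
    x <- data[[v]]
    if (is.numeric(x) && length(unique(x[!is.na(x)])) > 2L)
      data[[v]] <- as.numeric(scale(x))
  }
  data
}

#' Covariate-adjusted linear model with interaction pruning
#'
#' Ordinary least squares with listwise deletion. Interaction terms are fitted
#' first; each is dropped iff its p-value (type-II F test via [drop1()]) is at
#' or above `prune_alpha`, and the model is refitted without the dropped
#' terms. Per-term Cohen's d is computed from the t statistic as
#' `d = 2 t / sqrt(df)` (configurable convention). With `standardize = TRUE`
#' the continuous outcome and predictors are z-scored and the model refitted,
#' so both raw and standardized coefficient tables are reported.
#'
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor column names.
#' @param covariates Character vector of covariate column names.
#' @param interactions Character vector of interaction terms, e.g.
#'   `"group:site"`; candidates for pruning.
#' @param data Data frame holding all columns.
#' @param prune_alpha Pruning threshold in (0, 1) (default 0.05).
#' @param standardize Also fit on z-scored continuous variables?
#' @return Object of class `pruned_lm_fit`: list with `coef` (raw per-term
#'   table: estimate, se, t, p, d), `coef_std` (standardized table or `NULL`),
#'   `model` (the raw `lm`), `model_std`, `n`, `pruned` (dropped interaction
#'   terms), `kept_interactions`, `formula`.
#' @export
fit_pruned_lm <- function(outcome, predictors, covariates = character(0),
                          interactions = character(0), data,
                          prune_alpha = 0.05, standardize = TRUE) {
  if (!(prune_alpha > 0 && prune_alpha < 1)) stop("prune_alpha must be in (0,1)")
  vars <- unique(c(outcome, predictors, covariates,
                   unlist(strsplit(interactions, ":", fixed = TRUE))))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("columns absent from data: ", paste(missing_cols, collapse = ", "))
  d0 <- data[, vars, drop = FALSE]
  for (v in vars) if (is.character(d0[[v]])) d0[[v]] <- factor(d0[[v]])
  d0 <- d0[complete.cases(d0), , drop = FALSE]
  for (v in vars) if (is.factor(d0[[v]])) d0[[v]] <- droplevels(d0[[v]])
  # covariates that are constant in the analysed rows carry no information
  # and break the design matrix; drop them (and interactions touching them)
  degenerate <- vars[vapply(vars, function(v)
    length(unique(d0[[v]])) < 2L, logical(1))]
  if (outcome %in% degenerate) stop("outcome is constant; degenerate input")
  if (any(predictors %in% degenerate))
    stop("predictor constant in the analysed rows: ",
         paste(intersect(predictors, degenerate), collapse = ", "))
  dropped_covariates <- intersect(covariates, degenerate)
  covariates <- setdiff(covariates, dropped_covariates)
  if (length(degenerate))
    interactions <- interactions[!vapply(strsplit(interactions, ":", fixed = TRUE),
                                         function(v) any(v %in% degenerate),
                                         logical(1))]
  rhs <- c(predictors, covariates, interactions)
  form <- as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  n <- nrow(d0)
  n_terms <- length(rhs)
  if (n < n_terms + 2L) stop("too few complete observations for the model")
  fit <- lm(form, data = d0)
  if (qr(fit)$rank < length(coef(fit))) stop("rank-deficient design")
  pruned <- character(0)
  if (length(interactions)) {
    # R canonicalizes interaction labels (a:b may become b:a); match on the
    # unordered variable sets.
    labs <- labels(terms(fit))
    key <- function(v) paste(sort(strsplit(v, ":", fixed = TRUE)[[1L]]),
                             collapse = ":")
    canon <- labs[vapply(labs, key, "") %in% vapply(interactions, key, "")]
    dr <- drop1(fit, test = "F")
    pvals <- setNames(dr[["Pr(>F)"]], rownames(dr))[canon]
    drop_canon <- canon[!is.na(pvals) & pvals >= prune_alpha]
    if (length(drop_canon)) {
      keep_labs <- setdiff(labs, drop_canon)
      form <- as.formula(paste(outcome, "~", paste(keep_labs, collapse = " + ")))
      fit <- lm(form, data = d0)
    }
    pruned <- interactions[vapply(interactions, key, "") %in%
                             vapply(drop_canon, key, "")]
  }
  coef_table <- function(f) {
    s <- summary(f)$coefficients
    dfres <- f$df.residual
    data.frame(term = rownames(s), estimate = s[, 1L], se = s[, 2L],
               t = s[, 3L], p = s[, 4L], d = 2 * s[, 3L] / sqrt(dfres),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  fit_std <- NULL
  if (standardize) {
    ds <- standardize_columns(d0, c(outcome, predictors, covariates))
    fit_std <- lm(form, data = ds)
  }
  out <- list(coef = coef_table(fit),
              coef_std = if (standardize) coef_table(fit_std) else NULL,
              model = fit, model_std = fit_std, n = n, pruned = pruned,
              kept_interactions = setdiff(interactions, pruned),
              dropped_covariates = dropped_covariates,
              formula = form)
  class(out) <- "pruned_lm_fit"
  out
}

#' @export
print.pruned_lm_fit <- function(x, ...) {
  cat("Pruned linear model:", deparse(x$formula), sprintf("(n = %d)\n", x$n))
  if (length(x$pruned))
    cat("  pruned interactions:", paste(x$pruned, collapse = ", "), "\n")
  print(x$coef, digits = 3)
  invisible(x)
}

#' BIC-approximate Bayes factor for the null over the alternative
#'
#' `BF01 = exp((BIC_alt - BIC_null) / 2)`, the BIC (unit-information prior)
#' approximation to the Bayes factor favoring the smaller (null) model. Used
#' to quantify evidence for hypothesized null group effects; it is an
#' approximation, not identical to default-prior Bayesian regression. Models
#' must be nested and fitted to the same observations.
#'
#' @param model_null,model_alt `lm` fits (or `pruned_lm_fit` objects), null
#'   nested in alternative.
#' @return `BF01` (scalar; > 1 favors the null).
#' @export
bf01_null_evidence <- function(model_null, model_alt) {
  if (inherits(model_null, "pruned_lm_fit")) model_null <- model_null$model
  if (inherits(model_alt, "pruned_lm_fit")) model_alt <- model_alt$model
  n0 <- nobs(model_null); n1 <- nobs(model_alt)
  if (n0 != n1) stop("models fitted to different numbers of observations")
  if (n0 < 2L) stop("BIC undefined for n < 2")
  key <- function(v) paste(sort(strsplit(v, ":", fixed = TRUE)[[1L]]),
                           collapse = ":")
  t0 <- vapply(labels(terms(model_null)), key, "")
  t1 <- vapply(labels(terms(model_alt)), key, "")
  if (!all(t0 %in% t1) || length(t1) <= length(t0))
    stop("models must be nested (null within alternative)")
  exp((BIC(model_alt) - BIC(model_null)) / 2)
}

#' Bonferroni adjustment
#'
#' For `k` tests: adjusted significance threshold `alpha / k` and adjusted
#' p-values `min(1, p * k)`.
#'
#' @param p Numeric vector of p-values.
#' @param k Number of tests (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return List with `alpha_adjusted` and `p_adjusted`.
#' @export
bonferroni_adjust <- function(p, k, alpha = 0.05) {
  if (k < 1) stop("k must be >= 1")
  list(alpha_adjusted = alpha / k, p_adjusted = pmin(1, p * k))
}
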