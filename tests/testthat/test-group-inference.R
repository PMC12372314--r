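# Inference battery primitives and assembly.

test_that("welch_t agrees between raw samples, summaries, and stats::t.test", {
  set.seed(41)
  x <- rnorm(30, 0.2, 0.08); y <- rnorm(20, 0.15, 0.06)
  raw <- welch_t(x = x, y = y)
  summ <- welch_t(m1 = mean(x), sd1 = sd(x), n1 = 30,
                  m2 = mean(y), sd2 = sd(y), n2 = 20)
  for (f in c("t", "df", "p", "d", "mean_diff"))
    expect_equal(raw[[f]], summ[[f]], tolerance = 1e-10)
  ref <- t.test(y, x)  # group2 - group1 convention
  expect_equal(raw$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(raw$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(raw$p, ref$p.value, tolerance = 1e-10)
  # equal summaries: t = 0, d = 0
  eq <- welch_t(m1 = 1, sd1 = 0.5, n1 = 10, m2 = 1, sd2 = 0.5, n2 = 12)
  expect_equal(eq$t, 0); expect_equal(eq$d, 0)
  expect_error(welch_t(m1 = 1, sd1 = 0, n1 = 10, m2 = 1, sd2 = 1, n2 = 10),
               "degenerate")
  expect_error(welch_t(m1 = 1, sd1 = 1, n1 = 1, m2 = 1, sd2 = 1, n2 = 10),
               "n >= 2")
})

test_that("paired_t matches the formula oracle and stats::t.test", {
  set.seed(43)
  x <- rnorm(25); y <- x + rnorm(25, 0.3, 0.5)
  out <- paired_t(x, y)
  d <- y - x
  expect_equal(out$t, mean(d) / (sd(d) / sqrt(25)), tolerance = 1e-10)
  expect_equal(out$d, mean(d) / sd(d), tolerance = 1e-10)
  ref <- t.test(y, x, paired = TRUE)
  expect_equal(out$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(out$p, ref$p.value, tolerance = 1e-10)
  expect_equal(out$ci95, unname(ref$conf.int), tolerance = 1e-10,
               ignore_attr = TRUE)
  # y identical to x: degenerate no-difference case
  same <- paired_t(x, x)
  expect_equal(same$t, 0); expect_equal(same$d, 0); expect_equal(same$p, 1)
  # constant nonzero differences are an error
  expect_error(paired_t(1:4, 2:5), "zero-variance")
  expect_error(paired_t(1:2, 2:3), "at least 3")
})

test_that("fit_pruned_lm recovers a unit slope and prunes as instructed", {
  set.seed(47)
  d <- data.frame(x = rnorm(50))
  d$y <- d$x + rnorm(50, 0, 1e-6)
  f <- fit_pruned_lm("y", "x", data = d, standardize = FALSE)
  expect_equal(f$coef$estimate[f$coef$term == "x"], 1, tolerance = 1e-5)
  expect_lt(f$coef$p[f$coef$term == "x"], 1e-10)
  # a strong simulated interaction is retained
  n <- 120
  d2 <- data.frame(g = factor(rep(c("A", "B"), each = n / 2)), x = rnorm(n))
  d2$y <- ifelse(d2$g == "B", 2 * d2$x, 0) + rnorm(n, 0, 0.5)
  f2 <- fit_pruned_lm("y", c("x", "g"), interactions = "g:x", data = d2,
                      standardize = FALSE)
  expect_length(f2$pruned, 0)
  expect_equal(f2$kept_interactions, "g:x")
  # a null interaction is dropped and the model refitted without it
  set.seed(48)
  d3 <- d2; d3$y <- d3$x + rnorm(n, 0, 0.5)
  f3 <- fit_pruned_lm("y", c("x", "g"), interactions = "g:x", data = d3,
                      standardize = FALSE)
  expect_equal(f3$pruned, "g:x")
  expect_false(any(grepl(":", f3$coef$term)))
  # d = 2t/sqrt(df)
  expect_equal(f3$coef$d, 2 * f3$coef$t / sqrt(f3$model$df.residual))
})

test_that("with no covariates the group model matches the two-sample t-test", {
  set.seed(53)
  d <- data.frame(g = factor(rep(c("A", "B"), each = 20)),
                  y = c(rnorm(20, 0), rnorm(20, 0.8)))
  f <- fit_pruned_lm("y", "g", data = d, standardize = FALSE)
  ref <- t.test(y ~ g, data = d, var.equal = TRUE)
  i <- grepl("^g", f$coef$term)
  expect_equal(abs(f$coef$t[i]), abs(unname(ref$statistic)), tolerance = 1e-10)
  expect_equal(f$coef$p[i], ref$p.value, tolerance = 1e-10)
  expect_equal(f$coef$estimate[i],
               mean(d$y[d$g == "B"]) - mean(d$y[d$g == "A"]),
               tolerance = 1e-10)
})

test_that("standardized and raw coefficient tables are consistent", {
  set.seed(59)
  d <- data.frame(x = rnorm(60, 10, 3), z = rnorm(60))
  d$y <- 0.5 * d$x + rnorm(60)
  f <- fit_pruned_lm("y", "x", covariates = "z", data = d, standardize = TRUE)
  # same t and p on both scales; beta rescaled by sd ratio
  ix <- f$coef$term == "x"
  expect_equal(f$coef$t[ix], f$coef_std$t[ix], tolerance = 1e-8)
  expect_equal(f$coef$p[ix], f$coef_std$p[ix], tolerance = 1e-8)
  expect_equal(f$coef_std$estimate[ix],
               f$coef$estimate[ix] * sd(d$x) / sd(d$y), tolerance = 1e-8)
})

test_that("p-values are uniform under the null (KS check)", {
  ps <- vapply(1:500, function(s) {
    set.seed(s)
    d <- data.frame(g = factor(rep(c("A", "B"), each = 25)),
                    site = factor(sample(c("u", "v"), 50, TRUE)),
                    y = rnorm(50))
    f <- fit_pruned_lm("y", "g", covariates = "site",
                       interactions = "g:site", data = d, standardize = FALSE)
    f$coef$p[grepl("^g", f$coef$term) & !grepl(":", f$coef$term)][1]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("BIC Bayes factor gives sqrt(n) per superfluous parameter", {
  set.seed(61)
  n <- 100
  y <- rnorm(n)
  x0 <- rnorm(n)
  # orthogonalize so the extra regressor changes nothing but the penalty
  x <- residuals(lm(x0 ~ y))
  null <- lm(y ~ 1)
  alt <- lm(y ~ x)
  expect_equal(bf01_null_evidence(null, alt), sqrt(n), tolerance = 1e-6)
  # a genuinely predictive regressor flips the evidence
  x2 <- y + rnorm(n, 0, 0.3)
  expect_lt(bf01_null_evidence(null, lm(y ~ x2)), 1)
  # guards
  expect_error(bf01_null_evidence(lm(y ~ x), lm(y ~ 1)), "nested")
  expect_error(bf01_null_evidence(lm(y[1:50] ~ 1), lm(y ~ x)), "different numbers")
})

test_that("bonferroni adjustment is exact for the two-test case", {
  b <- bonferroni_adjust(c(0.03, 0.6), k = 2)
  expect_equal(b$alpha_adjusted, 0.025)
  expect_equal(b$p_adjusted, c(0.06, 1))
  expect_equal(bonferroni_adjust(0.2, k = 1)$p_adjusted, 0.2)
  expect_error(bonferroni_adjust(0.2, k = 0), ">= 1")
})

test_that("the battery contains the fixed preregistration-style analysis set", {
  cfg <- tiny_config(seed = 67, n_timepoints = 200)
  run <- run_pipeline(modifyList(default_run_config(seed = 67),
                                 list(sim = list(n_per_group = c(ASD = 14, NT = 18),
                                                 n_timepoints = 200))))
  b <- run$battery
  expect_s3_class(b, "hypothesis_battery")
  expect_equal(b$n_tests, 17)
  expect_length(b$models, 11)
  expect_length(b$paired, 4)
  expect_length(b$welch, 2)
  expect_equal(b$bonferroni_alpha, 0.025)
  tab <- as.data.frame(b)
  expect_true(all(c("analysis", "term", "estimate", "p", "d") %in% names(tab)))
  expect_true(all(tab$p >= 0 & tab$p <= 1, na.rm = TRUE))
})
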