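# IRC/ISC metrics: Fisher transform, censored correlations, summaries,
# reference similarity, group similarity, event magnitude.

test_that("fisher_z matches the closed form and caps perfect correlations", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  expect_true(is.finite(fisher_z(1)))
  expect_true(is.finite(fisher_z(-1)))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_error(fisher_z(Inf), "non-finite")
  expect_error(fisher_z(1.5), "<= 1")
})

test_that("pairwise correlation excludes the union of censored TRs", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 100)
  my <- c(FALSE, FALSE, FALSE, TRUE)
  expect_equal(pairwise_correlation(x, y, mask_y = my, min_points = 3), 1)
  # perfect linear relation without censoring
  x <- 1:20
  expect_equal(pairwise_correlation(x, 2 * x + 3), 1)
  # union rule: censoring in either series removes the timepoint
  set.seed(5)
  a <- rnorm(40); b <- rnorm(40)
  ma <- rep(FALSE, 40); ma[1:5] <- TRUE
  mb <- rep(FALSE, 40); mb[4:9] <- TRUE
  keep <- !(ma | mb)
  expect_equal(pairwise_correlation(a, b, ma, mb),
               naive_pearson(a, b, keep), tolerance = 1e-12)
  expect_error(pairwise_correlation(a[1:12], b[1:12], rep(TRUE, 12), NULL),
               "unusable pair")
})

test_that("independent series correlate near zero at T = 500", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    if (abs(pairwise_correlation(rnorm(500), rnorm(500))) < 0.15) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("irc_summary matches the naive triple-loop oracle on random fixtures", {
  atlas <- default_roi_networks()
  set.seed(13)
  for (rep in 1:5) {
    v <- matrix(rnorm(80 * 13), 80, 13)
    colnames(v) <- names(atlas)
    cens <- rep(FALSE, 80); cens[sample(80, 8)] <- TRUE
    tc <- roi_timecourse_set(v, atlas, 0.72, cens)
    got <- irc_summary(tc)
    want <- naive_irc(v, cens, atlas)
    expect_equal(got$within_tom_z, want$within_tom_z, tolerance = 1e-12)
    expect_equal(got$within_pain_z, want$within_pain_z, tolerance = 1e-12)
    expect_equal(got$across_z, want$across_z, tolerance = 1e-12)
    expect_equal(unname(got$n_pairs), c(15, 21, 42))
  }
})

test_that("IRC separates exchangeable and network-specific constructions", {
  atlas <- default_roi_networks()
  T <- 400
  set.seed(17)
  shared <- rnorm(T)
  # every ROI = one template + noise: within and across match
  v <- sapply(1:13, function(j) shared + rnorm(T))
  colnames(v) <- names(atlas)
  s <- irc_summary(roi_timecourse_set(v, atlas, 0.72))
  expect_equal(s$within_tom_z, s$across_z, tolerance = 0.1)
  # orthogonal per-network templates: across ~ 0, within > 0
  f1 <- rnorm(T); f2 <- rnorm(T)
  v2 <- sapply(names(atlas), function(roi) {
    f <- if (atlas[[roi]] == "ToM") f1 else f2
    f + rnorm(T)
  })
  s2 <- irc_summary(roi_timecourse_set(v2, atlas, 0.72))
  expect_lt(abs(s2$across_z), 0.1)
  expect_gt(s2$within_tom_z, 0.3)
  expect_gt(s2$within_pain_z, 0.3)
})

test_that("summaries average Fisher z values, not the z of the mean r", {
  # two ToM ROIs + one more, correlations far apart so the conventions differ
  atlas3 <- c(x1 = "ToM", x2 = "ToM", x3 = "ToM", y1 = "Pain", y2 = "Pain")
  set.seed(19)
  base <- rnorm(300)
  v <- cbind(base, base + 0.1 * rnorm(300), rnorm(300),
             rnorm(300), rnorm(300))
  colnames(v) <- names(atlas3)
  s <- irc_summary(roi_timecourse_set(v, atlas3, 0.72))
  C <- cor(v[, 1:3])
  rs <- C[upper.tri(C)]
  mean_of_z <- mean(atanh(rs))
  z_of_mean <- atanh(mean(rs))
  expect_equal(s$within_tom_z, mean_of_z, tolerance = 1e-12)
  expect_gt(abs(mean_of_z - z_of_mean), 0.01)  # the conventions truly differ here
})

test_that("similarity to reference uses LOO for members and full average otherwise", {
  set.seed(23)
  base <- rnorm(100)
  s1 <- toy_net_tc(base + 0.01 * rnorm(100))
  s2 <- toy_net_tc(base + 0.01 * rnorm(100))
  # 2-subject reference, LOO: correlation with the other subject only
  z <- similarity_to_reference(s1, list(s1, s2), leave_out = 1)
  expect_equal(z, fisher_z(cor(s1$values, s2$values)), tolerance = 1e-12)
  # identical series: capped z, finite
  z2 <- similarity_to_reference(s1, list(s1, s1), leave_out = 1)
  expect_equal(z2, atanh(1 - 1e-7))
  # non-member: full average including every reference subject
  probe <- toy_net_tc(rnorm(100))
  zfull <- similarity_to_reference(probe, list(s1, s2))
  avg <- (s1$values + s2$values) / 2
  expect_equal(zfull, fisher_z(cor(probe$values, avg)), tolerance = 1e-12)
  expect_error(similarity_to_reference(s1, list(s1), leave_out = 1), ">= 2")
})

test_that("a pure-noise subject has near-zero reference similarity over seeds", {
  zs <- vapply(1:50, function(s) {
    set.seed(s)
    shared <- rnorm(200)
    refs <- lapply(1:10, function(i) toy_net_tc(shared + 0.3 * rnorm(200)))
    similarity_to_reference(toy_net_tc(rnorm(200)), refs)
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.03)
})

test_that("reference average skips censored reference TRs instead of dropping subjects", {
  base <- sin(seq(0, 6 * pi, length.out = 60))
  c1 <- rep(FALSE, 60); c1[1:20] <- TRUE
  v1 <- base; v1[1:20] <- 999   # corruption confined to the censored TRs
  r1 <- toy_net_tc(v1, censor = c1)
  r2 <- toy_net_tc(base)
  probe <- toy_net_tc(base)
  # at TRs 1..20 the average is r2 alone; censored r1 values never leak in
  z <- similarity_to_reference(probe, list(r1, r2))
  expect_equal(z, atanh(1 - 1e-7))
})

test_that("group similarity matches the naive pairwise oracle and is symmetric", {
  set.seed(29)
  n <- 8
  shared <- rnorm(150)
  series <- lapply(1:n, function(i) shared * runif(1, 0.3, 1) + rnorm(150))
  censors <- lapply(1:n, function(i) {
    c <- rep(FALSE, 150); c[sample(150, 12)] <- TRUE; c
  })
  tcs <- Map(function(v, c) toy_net_tc(v, censor = c), series, censors)
  groups <- rep(c("NT", "ASD"), each = 4)
  out <- group_similarity_summary(tcs, groups)
  Z <- attr(out, "z_matrix")
  expect_identical(Z, t(Z))
  Znaive <- naive_sim_matrix(series, censors)
  expect_equal(Z, Znaive, tolerance = 1e-12, ignore_attr = TRUE)
  for (i in 1:n) {
    expect_equal(out$within_group_z[i],
                 mean(Znaive[i, groups == groups[i]], na.rm = TRUE),
                 tolerance = 1e-12)
    expect_equal(out$across_group_z[i],
                 mean(Znaive[i, groups != groups[i]]), tolerance = 1e-12)
  }
  # grand means of across-group similarity agree (same pair set)
  expect_equal(mean(out$across_group_z[groups == "NT"]),
               mean(out$across_group_z[groups == "ASD"]), tolerance = 1e-12)
  # with 2 per group, within_group_z is the single own-group pair value
  out2 <- group_similarity_summary(tcs[1:4], rep(c("NT", "ASD"), each = 2))
  Z2 <- attr(out2, "z_matrix")
  expect_equal(out2$within_group_z[1], Z2[1, 2])
  expect_equal(out2$within_group_z[3], Z2[3, 4])
})

test_that("event magnitude averages uncensored TRs in the window", {
  v <- rep(0, 30); v[10:12] <- c(0.5, 1.0, 1.5)
  expect_equal(event_magnitude(toy_net_tc(v), c(10, 12)), 1.0)
  cens <- rep(FALSE, 30); cens[11] <- TRUE
  expect_equal(event_magnitude(toy_net_tc(v, censor = cens), c(10, 12)), 1.0)
  censall <- rep(FALSE, 30); censall[10:12] <- TRUE
  expect_true(is.na(event_magnitude(toy_net_tc(v, censor = censall), c(10, 12))))
  expect_error(event_magnitude(toy_net_tc(v), c(29, 31)), "outside")
})

test_that("cohort_metrics assembles the full per-subject table", {
  cfg <- tiny_config(seed = 31)
  sim <- simulate_cohort(cfg)
  tcs <- lapply(sim$timecourses, function(tc) {
    tc$censored <- rep(FALSE, cfg$n_timepoints)
    prep_timecourses(tc)
  })
  ev <- sim$templates$event_table
  win <- unlist(ev[ev$label == "T04", c("start_tr", "end_tr")])
  met <- cohort_metrics(tcs, sim$cohort$group, event_window = win)
  expect_equal(nrow(met), nrow(sim$cohort))
  expect_true(all(c("within_tom_z", "sim_nt_tom_z", "within_group_pain_z",
                    "t04_magnitude") %in% names(met)))
  expect_true(all(is.finite(met$within_tom_z)))
  expect_true(all(is.finite(met$t04_magnitude)))
})
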