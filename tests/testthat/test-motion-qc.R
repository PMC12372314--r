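# Filtered framewise displacement, artifact detection, exclusions, matching.
# Timepoint indices are 1-based throughout.

test_that("FD is zero for a constant trace and invariant to constant offsets", {
  tr <- matrix(0.3, 64, 6)
  fd <- compute_fd_filt4(tr, tr_seconds = 0.72, bypass_filter = TRUE)
  expect_equal(fd$fd_mm, rep(0, 64))
  expect_equal(fd$mean_fd, 0)
  # with the band-stop filter engaged (DC passes a band-stop)
  fdf <- compute_fd_filt4(tr, tr_seconds = 0.72)
  expect_lt(max(abs(fdf$fd_mm)), 1e-8)
  # offset invariance on a random trace
  set.seed(1)
  tr2 <- matrix(rnorm(64 * 6, sd = 0.05), 64, 6)
  tr3 <- sweep(tr2, 2, c(5, -3, 2, 0.1, -0.2, 0.05), `+`)
  f2 <- compute_fd_filt4(tr2, tr_seconds = 0.72, bypass_filter = TRUE)
  f3 <- compute_fd_filt4(tr3, tr_seconds = 0.72, bypass_filter = TRUE)
  expect_equal(f2$fd_mm, f3$fd_mm, tolerance = 1e-12)
})

test_that("lag-4 FD matches hand-computed values for step inputs", {
  # +1 mm step in trans_x starting at TR 11: lag-4 differences are 1 at
  # TRs 11..14 and 0 elsewhere
  tr <- matrix(0, 40, 6)
  tr[11:40, 1] <- 1
  fd <- compute_fd_filt4(tr, tr_seconds = 0.72, bypass_filter = TRUE)
  expected <- rep(0, 40); expected[11:14] <- 1
  expect_equal(fd$fd_mm, expected)
  expect_equal(fd$mean_fd, 4 / 40)
  # rotation step of 0.02 rad on a 50 mm sphere: arc = 1.0 mm
  tr <- matrix(0, 40, 6)
  tr[11:40, 5] <- 0.02
  fd <- compute_fd_filt4(tr, tr_seconds = 0.72, bypass_filter = TRUE,
                         radius_mm = 50)
  expect_equal(fd$fd_mm[11:14], rep(1, 4))
  expect_equal(sum(fd$fd_mm > 0), 4)
})

test_that("vectorized FD equals the naive double-loop oracle", {
  set.seed(42)
  for (rep in 1:5) {
    tr <- matrix(rnorm(80 * 6, sd = 0.1), 80, 6)
    fd <- compute_fd_filt4(tr, tr_seconds = 0.72, bypass_filter = TRUE)
    expect_equal(fd$fd_mm, naive_fd(tr), tolerance = 1e-12)
    expect_equal(fd$mean_fd, mean(naive_fd(tr)), tolerance = 1e-12)
  }
})

test_that("FD input validation catches bad traces and bands", {
  expect_error(compute_fd_filt4(matrix(0, 4, 6), tr_seconds = 0.72), "at least 8")
  tr <- matrix(0, 20, 6); tr[3, 2] <- NA
  expect_error(compute_fd_filt4(tr, tr_seconds = 0.72), "non-finite")
  expect_error(compute_fd_filt4(matrix(0, 20, 6), tr_seconds = 0.72,
                                band_hz = c(0.31, 0.80)), "Nyquist")
})

test_that("artifact detection pads and merges censored windows", {
  fd <- rep(0.1, 60)
  m <- detect_artifacts(fd)
  expect_equal(m$n_censored, 0)
  expect_equal(m$frac_censored, 0)
  # single exceedance at TR 21 -> censored 19..23 (pad 2 each side)
  fd[21] <- 0.7
  m <- detect_artifacts(fd)
  expect_equal(which(m$censored), 19:23)
  # exceedances at TRs 6 and 8 -> merged run 4..10
  fd <- rep(0.1, 60); fd[c(6, 8)] <- 0.9
  m <- detect_artifacts(fd)
  expect_equal(which(m$censored), 4:10)
  # clipping at the series edge
  fd <- rep(0.1, 60); fd[1] <- 0.9
  expect_equal(which(detect_artifacts(fd)$censored), 1:3)
})

test_that("mask grows monotonically as threshold falls or pad rises", {
  set.seed(7)
  for (rep in 1:10) {
    fd <- abs(rnorm(100, 0.2, 0.2))
    m0 <- detect_artifacts(fd, threshold_mm = 0.5, pad = 2)$censored
    m_lo <- detect_artifacts(fd, threshold_mm = 0.3, pad = 2)$censored
    m_pad <- detect_artifacts(fd, threshold_mm = 0.5, pad = 4)$censored
    expect_true(all(m_lo[m0]))   # nothing un-censored by lower threshold
    expect_true(all(m_pad[m0]))  # nor by a wider pad
  }
})

test_that("detection recovers injected ground-truth spikes", {
  hits <- 0L; total <- 0L
  for (s in 1:100) {
    cfg <- sim_config(n_per_group = c(ASD = 1, NT = 1), n_timepoints = 548,
                      artifact_rate = 0.01, seed = s)
    m <- generate_motion(cfg, subject_seed = 5000 + s)
    if (!length(m$artifact_tr)) next
    mask <- detect_artifacts(compute_fd_filt4(m))
    hits <- hits + sum(mask$censored[m$artifact_tr])
    total <- total + length(m$artifact_tr)
  }
  expect_gte(hits / total, 0.9)
})

test_that("subject exclusion honors the one-third rule and fixed thresholds", {
  qc <- data.frame(
    subject_id = sprintf("s%d", 1:8),
    site = rep(c("IU", "CAL"), each = 4),
    mean_fd = c(0.20, 0.21, 0.19, 0.50, 0.20, 0.22, 0.21, 0.50),
    frac_censored = c(0.34, 0.10, 0.05, 0.05, 0.05, 1 / 3, 0.05, 0.05))
  out <- exclude_subjects(qc, fixed_thresholds = c(IU = 0.4808, CAL = 0.5625))
  expect_true(out$over_one_third[1])            # 0.34 > 1/3
  expect_false(out$over_one_third[6])           # exactly 1/3 is not over
  expect_true(out$iqr_outlier[4])               # 0.50 > 0.4808 at IU
  expect_false(out$iqr_outlier[8])              # 0.50 < 0.5625 at CAL
  expect_equal(unname(attr(out, "thresholds")), c(0.4808, 0.5625))
  # sample-computed thresholds: the site-median subject is never an outlier
  out2 <- exclude_subjects(qc)
  med_iu <- which(qc$site == "IU" & qc$mean_fd == median(qc$mean_fd[qc$site == "IU"]))
  if (length(med_iu)) expect_false(any(out2$iqr_outlier[med_iu]))
  # single-subject site without a fixed threshold fails
  expect_error(exclude_subjects(qc[c(1, 5:8), ][1:2, ]), "single subject")
})

test_that("matching removes the brute-force-best extreme until groups align", {
  qc <- data.frame(subject_id = sprintf("s%02d", 1:12),
                   group = rep(c("NT", "ASD"), each = 6),
                   mean_fd = c(1, 2, 3, 4, 5, 6, 4, 5, 6, 7, 8, 9) / 10)
  p0 <- t.test(qc$mean_fd[1:6], qc$mean_fd[7:12])$p.value
  expect_lt(p0, 0.05)
  removed <- match_groups_on_motion(qc, metrics = "mean_fd")
  # oracle: candidates are the lower-mean group's minimum and the higher-mean
  # group's maximum; the one whose removal raises p more goes first
  cand <- c("s01", "s12")
  gain <- sapply(cand, function(id) {
    sub <- qc[qc$subject_id != id, ]
    t.test(sub$mean_fd[sub$group == "NT"], sub$mean_fd[sub$group == "ASD"])$p.value
  })
  expect_equal(removed[1], names(which.max(gain)))
  # removals actually equalize the groups
  final <- qc[!qc$subject_id %in% removed, ]
  expect_gte(t.test(final$mean_fd[final$group == "NT"],
                    final$mean_fd[final$group == "ASD"])$p.value, 0.05)
  expect_true(all(table(final$group) >= 3))
  # identical groups: nothing removed
  qc2 <- qc; qc2$mean_fd <- rep(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), 2)
  expect_length(match_groups_on_motion(qc2, metrics = "mean_fd"), 0)
  # alpha = 0: no difference is ever significant
  expect_length(match_groups_on_motion(qc, metrics = "mean_fd", alpha = 0), 0)
})

test_that("matching fails rather than shrink a group below the minimum", {
  qc <- data.frame(subject_id = sprintf("s%d", 1:6),
                   group = rep(c("NT", "ASD"), each = 3),
                   mean_fd = c(0.1, 0.11, 0.12, 0.5, 0.52, 0.54))
  expect_error(match_groups_on_motion(qc, metrics = "mean_fd"),
               "impossible")
})
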