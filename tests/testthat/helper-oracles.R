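# Independent brute-force oracles and small fixtures shared across tests.
# Oracles are written as plain double/triple loops, independent of the
# package's vectorized implementations.

# Lag-k framewise displacement, unfiltered, by explicit loops.
naive_fd <- function(trace, radius_mm = 50, lag = 4) {
  p <- as.matrix(trace)
  p[, 4:6] <- p[, 4:6] * radius_mm
  T <- nrow(p)
  fd <- rep(0, T)
  for (t in seq_len(T)) {
    if (t > lag) {
      s <- 0
      for (j in 1:6) s <- s + abs(p[t, j] - p[t - lag, j])
      fd[t] <- s
    }
  }
  fd
}

# Pearson r by explicit sums (no stats::cor), over jointly valid indices.
naive_pearson <- function(x, y, keep = rep(TRUE, length(x))) {
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# IRC summary via triple loops: all ROI pairs on the uncensored TRs,
# atanh per pair, arithmetic means over pair classes.
naive_irc <- function(values, censored, network_of) {
  keep <- !censored
  rois <- colnames(values)
  nets <- unname(network_of[rois])
  uniq <- unique(nets)
  zs <- list(w1 = c(), w2 = c(), x = c())
  R <- ncol(values)
  for (i in 1:(R - 1)) for (j in (i + 1):R) {
    r <- naive_pearson(values[, i], values[, j], keep)
    z <- atanh(min(max(r, -(1 - 1e-7)), 1 - 1e-7))
    if (nets[i] == uniq[1] && nets[j] == uniq[1]) zs$w1 <- c(zs$w1, z)
    else if (nets[i] == uniq[2] && nets[j] == uniq[2]) zs$w2 <- c(zs$w2, z)
    else zs$x <- c(zs$x, z)
  }
  list(within_tom_z = mean(zs$w1), within_pain_z = mean(zs$w2),
       across_z = mean(zs$x),
       n_pairs = c(length(zs$w1), length(zs$w2), length(zs$x)))
}

# Pairwise inter-subject similarity matrix by double loop with
# union-censoring, Fisher z per pair.
naive_sim_matrix <- function(series, censors) {
  n <- length(series)
  Z <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    keep <- !(censors[[i]] | censors[[j]])
    r <- naive_pearson(series[[i]], series[[j]], keep)
    Z[i, j] <- atanh(min(max(r, -(1 - 1e-7)), 1 - 1e-7))
  }
  Z
}

# Access to internal generator plumbing used by a few tests.
artifact_indices_for_test <- function(cfg, subject_seed) {
  movieisc:::artifact_indices(cfg, subject_seed)
}
with_seed_for_test <- function(seed, code) movieisc:::with_seed(seed, code)

# Small, fast simulation config for unit tests.
tiny_config <- function(seed = 1, n_timepoints = 120, ...) {
  sim_config(n_per_group = c(ASD = 5, NT = 7), n_timepoints = n_timepoints,
             seed = seed, ...)
}

# A two-network toy atlas with few ROIs.
toy_atlas <- c(a1 = "ToM", a2 = "ToM", a3 = "ToM", b1 = "Pain", b2 = "Pain")

# Build a roi_tc from a matrix with the toy atlas.
toy_tc <- function(values, censor = NULL, atlas = toy_atlas, tr = 0.72) {
  colnames(values) <- names(atlas)[seq_len(ncol(values))]
  roi_timecourse_set(values, atlas[seq_len(ncol(values))], tr, censor)
}

# Make a network_tc directly.
toy_net_tc <- function(values, censor = NULL, network = "ToM", tr = 0.72) {
  out <- list(values = as.numeric(values), network = network, tr_seconds = tr,
              censored = if (is.null(censor)) rep(FALSE, length(values)) else censor)
  class(out) <- "network_tc"
  out
}
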