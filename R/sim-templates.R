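# Evoked-template generation for the synthetic cohort.

# Smoothed Gaussian noise: white noise convolved with a Gaussian kernel.
# Zero-padded convolution, then standardized by the caller.
smooth_noise <- function(n, kernel_sd_tr) {
  x <- rnorm(n + 8L * ceiling(kernel_sd_tr) * 2L)
  half <- 4L * ceiling(kernel_sd_tr)
  k <- exp(-0.5 * ((-half):half / kernel_sd_tr)^2)
  k <- k / sum(k)
  y <- as.numeric(stats::filter(x, k, method = "convolution", sides = 2))
  y <- y[(half + 1L):(half + n)]
  y[is.na(y)] <- 0
  y
}

standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s <= 0) stop("degenerate (zero-variance) series")
  (x - mean(x)) / s
}

# Residualize y on the columns of X, then re-standardize.
orthogonalize <- function(y, X) {
  X <- cbind(1, X)
  beta <- qr.coef(qr(X), y)
  standardize(y - X %*% beta)
}

#' Generate evoked network templates and the event table
#'
#' Builds the stimulus-evoked signals the synthetic cohort shares: one
#' unit-variance template per network and a shared audiovisual component, each
#' smoothed Gaussian noise (kernel FWHM `template_fwhm_s`). The second
#' network's template and the shared component are orthogonalized against the
#' preceding ones, so the two network templates satisfy
#' `|cor| < template_max_r` by construction. An event table is returned with a
#' "T04"-style final mental-state event placed at the largest excursion of the
#' ToM-like (first) network's template, plus the analogous Pain-network peak
#' event; windows are 3 TRs wide and lie fully inside `[1, n_timepoints]`.
#'
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `evoked_templates`: list with `f` (T x 2 matrix,
#'   one column per network), `shared` (length-T vector), `event_table`
#'   (data.frame with `label`, `start_tr`, `end_tr`; 1-based inclusive) and
#'   `tr_seconds`.
#' @export
generate_templates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  T <- config$n_timepoints
  kernel_sd <- (config$template_fwhm_s / 2.355) / config$tr_seconds
  nets <- config$networks
  with_seed(substream_seed(config$seed, 0L), {
    for (attempt in 1:20) {
      ok <- TRUE
      f1 <- tryCatch(standardize(smooth_noise(T, kernel_sd)),
                     error = function(e) {ok <<- FALSE; NULL})
      if (!ok) next
      f2 <- tryCatch(orthogonalize(smooth_noise(T, kernel_sd), cbind(f1)),
                     error = function(e) {ok <<- FALSE; NULL})
      if (!ok) next
      s <- tryCatch(orthogonalize(smooth_noise(T, kernel_sd), cbind(f1, f2)),
                    error = function(e) {ok <<- FALSE; NULL})
      if (ok && abs(cor(f1, f2)) < config$template_max_r) break
      if (attempt == 20)
        stop("template orthogonalization failed repeatedly; degenerate config")
    }
    f <- cbind(f1, f2)
    colnames(f) <- nets
    peak <- function(v) {
      lo <- 5L; hi <- T - 4L
      lo - 1L + which.max(v[lo:hi])
    }
    p_tom <- peak(f[, 1L]); p_pain <- peak(f[, 2L])
    events <- data.frame(
      label = c("T04", "P01"),
      start_tr = c(p_tom - 1L, p_pain - 1L),
      end_tr = c(p_tom + 1L, p_pain + 1L),
      stringsAsFactors = FALSE)
    out <- list(f = f, shared = as.numeric(s), event_table = events,
                tr_seconds = config$tr_seconds)
    class(out) <- "evoked_templates"
    out
  })
}
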