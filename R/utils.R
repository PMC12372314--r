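# Internal helpers: seeding, zero-phase filtering, validation.

# Derive a deterministic substream seed from a parent seed. Keeps results
# stable under subject-set changes: subject i always gets the same stream
# for a given top-level seed, regardless of which other subjects exist.
substream_seed <- function(seed, stream) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 48271 + as.numeric(stream) * 9973 + 1) %% 2147483647)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Zero-phase filtering via signal::filtfilt with demeaning and reflection
# padding. filtfilt alone has no initial-condition handling, so nonzero-mean
# inputs produce large edge transients; padding with reflected, demeaned data
# removes them. keep_mean = TRUE restores the mean afterwards (appropriate for
# band-stop filters, which pass DC); FALSE leaves it removed (high-pass).
zero_phase_filter <- function(filt, x, keep_mean = TRUE) {
  n <- length(x)
  if (n < 8L) stop("series too short to filter (need >= 8 points)")
  np <- min(n - 1L, 60L)
  mu <- mean(x)
  xc <- x - mu
  xp <- c(2 * xc[1L] - rev(xc[2:(np + 1L)]),
          xc,
          2 * xc[n] - rev(xc[(n - np):(n - 1L)]))
  y <- signal::filtfilt(filt, xp)[(np + 1L):(np + n)]
  if (!all(is.finite(y))) stop("filter produced non-finite values")
  if (keep_mean) y + mu else y
}

stopifnot_scalar <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (strict_min && x <= min) stop(sprintf("'%s' must be > %g", name, min))
  if (!strict_min && x < min) stop(sprintf("'%s' must be >= %g", name, min))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
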