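# Internal numerical helpers shared across modules.

# Centered running mean with truncated edges, O(n) via cumulative sums.
# width is in samples; even widths are widened to the next odd number.
rolling_mean <- function(x, width) {
  n <- length(x)
  if (width <= 1L || n == 0L) return(x)
  half <- floor(width / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Centered running sum of x (NA treated as 0) together with the count of
# non-NA samples in each window; used for windowed CW-bias ratios.
rolling_sum_count <- function(x, width) {
  n <- length(x)
  half <- floor(width / 2)
  ok <- !is.na(x)
  xs <- ifelse(ok, x, 0)
  cs <- cumsum(c(0, xs))
  ck <- cumsum(c(0L, as.integer(ok)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  list(sum = cs[hi + 1L] - cs[lo], count = ck[hi + 1L] - ck[lo])
}

# Unwrap a phase series so successive differences lie in (-pi, pi].
unwrap_angle <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  theta[1L] + c(0, cumsum(d))
}

# Run expr under a locally seeded RNG; the caller's RNG state is untouched.
# seed = NULL uses (and advances) the current RNG stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) force(expr) else withr::with_seed(seed, force(expr))
}

# Uniform-grid check: max deviation of frame intervals from their median.
check_uniform_time <- function(t, tol = 1e-9, what = "time") {
  if (length(t) < 2L) return(invisible(TRUE))
  d <- diff(t)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L]
    stop(sprintf("%s must be strictly increasing (violation at row %d)", what, i + 1L),
         call. = FALSE)
  }
  if (max(abs(d - stats::median(d))) > tol) {
    stop(sprintf("%s grid is not uniform within %g s", what, tol), call. = FALSE)
  }
  invisible(TRUE)
}

infer_fps <- function(t) {
  check_uniform_time(t)
  1 / stats::median(diff(t))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
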