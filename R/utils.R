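# Internal numerical helpers shared across modules.

#' @importFrom stats median sd coef lm nls rnorm rpois runif var setNames
#' @importFrom utils head tail
NULL

stop_if_not_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop(sprintf("'%s' must be finite, got: %s", name,
                 paste(utils::head(x[!is.finite(x)], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  stop_if_not_finite(x, name)
  ok <- if (strict) all(x > 0) else all(x >= 0)
  if (!ok) stop(sprintf("'%s' must be %s", name,
                        if (strict) "> 0" else ">= 0"), call. = FALSE)
  invisible(x)
}

# Run expr with a fixed RNG state, restoring the caller's stream afterwards.
# All generator randomness flows through this; sub-stages derive their own
# offsets with split_seed() so changing one stage does not shift another.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Deterministic sub-seed derivation (kept below 2^31 - 1).
split_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 10007 * k) %% 2147483647)
}

# Centred 3-point moving average; endpoints kept as-is.
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  y <- x
  y[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  y
}

# Central-difference derivative, per-ms units given sampling rate in kHz.
central_diff <- function(x, sampling_rate_khz) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d * sampling_rate_khz
}

# Sub-sample peak refinement by a parabola through the discrete maximum and
# its neighbours. Returns fractional index (1-based) and refined value.
quadratic_peak <- function(y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(list(index = i, value = y[i]))
  a <- y[i - 1L]; b <- y[i]; cc <- y[i + 1L]
  den <- a - 2 * b + cc
  if (den >= 0 || !is.finite(den)) return(list(index = i, value = y[i]))
  d <- (a - cc) / (2 * den)
  list(index = i + d, value = b - 0.25 * (a - cc) * d)
}

# First linear-interpolated crossing of `level` by y over index range idx.
# direction "up": y rises through level; "down": falls through it.
first_crossing <- function(y, level, idx, direction = c("up", "down")) {
  direction <- match.arg(direction)
  for (i in idx) {
    y0 <- y[i]; y1 <- y[i + 1L]
    hit <- if (direction == "up") (y0 < level && y1 >= level)
           else (y0 >= level && y1 < level)
    if (hit) return(i + (level - y0) / (y1 - y0))
  }
  NA_real_
}

# index (possibly fractional, 1-based) -> time in ms
index_to_ms <- function(index, sampling_rate_khz) (index - 1) / sampling_rate_khz

ms_to_index <- function(ms, sampling_rate_khz) round(ms * sampling_rate_khz) + 1L
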