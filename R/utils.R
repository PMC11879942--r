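# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# 1 mmHg = 133.322 Pa
PA_PER_MMHG <- 133.322

#' Raised-cosine (Hann) pulse
#'
#' Compact-support pulse used for synthetic transmitral inflow waves:
#' `amp/2 * (1 - cos(2*pi*(t - onset)/duration))` on
#' `[onset, onset + duration]`, exactly zero outside. Compact support is
#' deliberate: two non-overlapping pulses have a genuinely zero valley
#' between them, so "EA-separation" is achievable without thresholding
#' ambiguity.
#'
#' @param t numeric vector (or matrix) of times, ms.
#' @param onset pulse onset, ms.
#' @param duration pulse duration, ms; must be > 0.
#' @param amplitude peak value, m/s.
#' @return numeric object shaped like `t`.
#' @export
hann_pulse <- function(t, onset, duration, amplitude) {
  stopifnot(is.numeric(duration), duration > 0)
  x <- t - onset
  out <- 0.5 * amplitude * (1 - cos(2 * pi * x / duration))
  out[x < 0 | x > duration] <- 0
  out
}

# indices of strict local maxima, plateau-robust (plateau -> its midpoint);
# series endpoints count when greater than the adjacent run
find_local_maxima <- function(y) {
  r <- rle(y)
  v <- r$values
  k <- length(v)
  if (k == 1L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  left <- c(-Inf, v[-k])
  right <- c(v[-1], -Inf)
  is_pk <- v > left & v > right
  as.integer(floor((starts[is_pk] + ends[is_pk]) / 2))
}

# second-order finite differences along columns (dim = 2, d/dt for a
# space x time matrix) or rows (dim = 1, d/ds); 3-point one-sided stencils
# at the boundaries keep the scheme O(h^2) everywhere
fd_derivative <- function(x, h, dim = 2) {
  if (dim == 1) return(t(fd_derivative(t(x), h, dim = 2)))
  n <- ncol(x)
  if (n < 3) stop("need at least 3 samples along the differentiated axis")
  d <- x
  d[, 2:(n - 1)] <- (x[, 3:n, drop = FALSE] - x[, 1:(n - 2), drop = FALSE]) / (2 * h)
  d[, 1] <- (-3 * x[, 1] + 4 * x[, 2] - x[, 3]) / (2 * h)
  d[, n] <- (3 * x[, n] - 4 * x[, n - 1] + x[, n - 2]) / (2 * h)
  d
}

# composite trapezoid weights for a uniform grid of n nodes, spacing h
trapz_weights <- function(n, h) {
  w <- rep(h, n)
  w[c(1, n)] <- h / 2
  w
}
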