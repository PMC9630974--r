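# Internal numeric helpers shared across modules.

# Running mean with the given (odd) window; ends keep the raw values so that
# peak detection near the histogram boundary is not lost to NAs.
running_mean <- function(x, window = 3L) {
  stopifnot(window %% 2L == 1L)
  sm <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  na <- is.na(sm)
  sm[na] <- x[na]
  sm
}

# Indices of (weak) local maxima / minima of a numeric vector.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}

local_minima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] < x[i - 1L] & x[i] <= x[i + 1L]]
}

#' First Wasserstein distance between two empirical distributions
#'
#' Computes the 1-Wasserstein (earth mover's) distance between the empirical
#' distributions of two numeric samples, i.e. the integral of the absolute
#' difference of the two empirical cumulative distribution functions.
#'
#' @param x,y Numeric vectors (need not be the same length).
#' @return A non-negative scalar.
#' @examples
#' wasserstein1(c(1, 2, 3), c(1, 2, 3))      # 0
#' wasserstein1(c(0, 0), c(1, 1))            # 1
#' @export
wasserstein1 <- function(x, y) {
  stopifnot(length(x) > 0L, length(y) > 0L)
  if (anyNA(x) || anyNA(y)) stop("NA values are not allowed")
  breaks <- sort(unique(c(x, y)))
  if (length(breaks) == 1L) return(0)
  fx <- stats::ecdf(x)(breaks)
  fy <- stats::ecdf(y)(breaks)
  k <- length(breaks)
  sum(abs(fx[-k] - fy[-k]) * diff(breaks))
}

# Mode of a sample via Gaussian KDE (Silverman bandwidth) on a fixed grid.
kde_mode <- function(x, from = min(x), to = max(x), n = 512L) {
  d <- stats::density(x, bw = "nrd0", n = n, from = from, to = to)
  d$x[which.max(d$y)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
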