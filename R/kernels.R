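#' Discrete Gaussian averaging kernel
#'
#' Temporal Gaussian averaging "over n points" is realized as a truncated,
#' renormalized Gaussian with support of about `n` samples and standard
#' deviation `n/4` samples. The same convention is shared by the smoothing
#' and derivative kernels so that every convolution feature has one
#' documented window semantics.
#'
#' @param n Window size in samples (>= 1).
#' @return Numeric kernel of odd length summing to 1.
#' @export
gaussian_kernel <- function(n) {
  if (n < 1) stop("window size must be >= 1")
  if (n == 1) return(1)
  h <- max(1L, floor(n / 2))
  k <- seq.int(-h, h)
  sigma <- n / 4
  w <- exp(-k^2 / (2 * sigma^2))
  w / sum(w)
}

#' Derivative-of-Gaussian kernel
#'
#' First-derivative kernel sharing sigma = n/4 with [gaussian_kernel()].
#' Normalized so that convolving a unit-slope-per-sample ramp returns
#' exactly 1; divide the response by the sampling interval to obtain a
#' per-second derivative.
#'
#' @param n Window size in samples (>= 2).
#' @return Numeric antisymmetric kernel.
#' @export
dog_kernel <- function(n) {
  if (n < 2) stop("derivative window must be >= 2")
  h <- max(1L, floor(n / 2))
  k <- seq.int(-h, h)
  sigma <- n / 4
  g <- exp(-k^2 / (2 * sigma^2))
  w <- k * g
  w / sum(k * w) # response to x_t = t is sum_k w_k * k = 1
}

#' Same-length convolution with edge reflection
#'
#' Computes `y_t = sum_k w_k x_(t+k)` for a centered odd-length kernel,
#' padding the series by reflection at both ends so the output has the
#' length of the input.
#'
#' @param x Numeric vector (or matrix; columns filtered independently).
#' @param w Odd-length kernel.
#' @return Filtered vector or matrix of the same shape.
#' @export
conv_same <- function(x, w) {
  if (is.matrix(x)) {
    return(apply(x, 2L, conv_same, w = w))
  }
  m <- length(w)
  if (m == 1L) return(x * w)
  if (m %% 2L == 0L) stop("kernel length must be odd")
  h <- (m - 1L) %/% 2L
  n <- length(x)
  if (n == 0L) return(x)
  # reflect (without repeating the edge sample)
  left <- x[pmin(n, pmax(1L, seq.int(h + 1L, 2L)))]
  right <- x[pmin(n, pmax(1L, seq.int(n - 1L, n - h)))]
  xp <- c(left, x, right)
  y <- stats::filter(xp, rev(w), method = "convolution", sides = 2L)
  as.numeric(y[(h + 1L):(h + n)])
}

gauss_smooth <- function(x, n) conv_same(x, gaussian_kernel(n))

#' @noRd
dog_deriv <- function(x, n, dt = 1) conv_same(x, dog_kernel(n)) / dt

running_window <- function(x, w, fun) {
  n <- length(x)
  h <- w %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    hi <- min(n, lo + w - 1L)
    lo <- max(1L, hi - w + 1L)
    out[i] <- fun(x[lo:hi])
  }
  out
}

running_min <- function(x, w) running_window(x, w, min)
running_max <- function(x, w) running_window(x, w, max)
running_sum <- function(x, w) running_window(x, w, sum)
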