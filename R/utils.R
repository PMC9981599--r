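`%||%` <- function(a, b) if (is.null(a)) b else a

#' Truncated-normal random deviates
#'
#' Inverse-CDF sampler for a normal distribution truncated below at `lower`.
#' Used for gaze dwell times, which must stay above a physiological floor.
#'
#' @param n number of draws
#' @param mean,sd mean and standard deviation of the parent normal
#' @param lower lower truncation bound
#' @return numeric vector of length `n`
#' @export
rtruncnorm <- function(n, mean, sd, lower = 0.2) {
  stopifnot(sd > 0)
  p0 <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p0, 1)
  stats::qnorm(u, mean, sd)
}

#' 1/f^alpha ("pink") noise
#'
#' Spectral-synthesis coloured noise: white Gaussian Fourier coefficients
#' scaled by `f^(-alpha/2)`, inverse transformed and standardised.
#'
#' @param n_samples samples per channel
#' @param n_channels number of independent channels
#' @param alpha spectral exponent (1 = pink)
#' @param sd target standard deviation per channel (uV)
#' @return matrix `n_channels x n_samples`
#' @export
pink_noise <- function(n_samples, n_channels = 1, alpha = 1, sd = 1) {
  out <- matrix(0, n_channels, n_samples)
  if (sd <= 0) return(out)
  nf <- floor(n_samples / 2)
  f <- seq_len(nf)
  scale <- f^(-alpha / 2)
  for (ch in seq_len(n_channels)) {
    amp <- stats::rnorm(nf) + 1i * stats::rnorm(nf)
    spec <- complex(real = rep(0, n_samples))
    spec[2:(nf + 1)] <- amp * scale
    # Hermitian symmetry for a real signal
    spec[n_samples:(n_samples - nf + 2)] <- Conj(spec[2:nf])
    x <- Re(stats::fft(spec, inverse = TRUE)) / n_samples
    out[ch, ] <- x / stats::sd(x) * sd
  }
  out
}

# centred ("same") complex convolution via FFT; x real/complex vector,
# kernel of odd length
conv_same <- function(x, kernel) {
  nx <- length(x)
  nk <- length(kernel)
  half <- (nk - 1L) %/% 2L
  n <- stats::nextn(nx + nk - 1L, 2L)
  X <- stats::fft(c(x, rep(0, n - nx)))
  K <- stats::fft(c(kernel, rep(0, n - nk)))
  full <- stats::fft(X * K, inverse = TRUE) / n
  full[(half + 1L):(half + nx)]
}

# random derangement (permutation with no fixed point) by rejection
derangement <- function(n) {
  stopifnot(n >= 2)
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

# wrap angles into (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# log-spaced sequence
logspace <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}

# derive a bounded child seed from a user seed (keeps below 2^31)
child_seed <- function(seed, i) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(i) %% 1000L
}
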