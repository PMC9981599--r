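#' Default wavelet frequency grid and cycle ramp
#'
#' 17 linearly spaced frequencies from 2 to 18 Hz; wavelet cycles increase
#' logarithmically from 3 to 10 across the grid, trading temporal precision
#' at low frequencies for spectral precision at high ones.
#'
#' @param n_freqs number of frequencies
#' @return numeric vector
#' @export
default_freqs <- function(n_freqs = 17) seq(2, 18, length.out = n_freqs)

#' @rdname default_freqs
#' @param freqs frequency grid the cycles are matched to
#' @export
default_cycles <- function(freqs = default_freqs()) {
  logspace(3, 10, length(freqs))
}

#' Complex Morlet wavelet decomposition
#'
#' Convolves the signal with Gaussian-windowed complex exponentials
#' (sigma_t = cycles / (2 pi f), support truncated at +/-4 sigma_t). Kernels
#' are amplitude-calibrated (scaled by 2 / sum of the Gaussian envelope) so
#' the coefficient magnitude at a matched frequency recovers the sinusoid's
#' amplitude; coefficient angles are the instantaneous phases consumed by
#' PLV, ITC and the event-locked maps. An `edge_valid` mask marks the samples
#' within half a wavelet length of either boundary, where estimates are
#' contaminated.
#'
#' @param x numeric vector (single channel) or channels-by-samples matrix
#' @param fs sampling rate (Hz); must exceed twice the highest frequency
#' @param freqs analysis frequencies (Hz)
#' @param cycles wavelet cycles per frequency (recycled if scalar)
#' @return a `tf_decomposition`: list with `coefficients` (complex,
#'   `freq x time` for a vector input, `channel x freq x time` for a matrix),
#'   `freqs`, `cycles`, `fs`, and `edge_valid` (`freq x time` logical)
#' @export
morlet_decompose <- function(x, fs, freqs = default_freqs(),
                             cycles = default_cycles(freqs)) {
  if (length(cycles) == 1) cycles <- rep(cycles, length(freqs))
  stopifnot(length(cycles) == length(freqs), all(freqs > 0))
  if (max(freqs) >= fs / 2) stop("frequencies must be below Nyquist")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  nf <- length(freqs)
  coef <- array(complex(real = 0), c(nrow(x), nf, n))
  edge_valid <- matrix(TRUE, nf, n)
  for (k in seq_len(nf)) {
    sigma <- cycles[k] / (2 * pi * freqs[k])
    half <- ceiling(4 * sigma * fs)
    tt <- (-half:half) / fs
    env <- exp(-tt^2 / (2 * sigma^2))
    kernel <- env * exp(1i * 2 * pi * freqs[k] * tt) * (2 / sum(env))
    for (ch in seq_len(nrow(x))) {
      coef[ch, k, ] <- conv_same(x[ch, ], kernel)
    }
    if (half >= 1) {
      bad <- unique(c(seq_len(min(half, n)), seq(max(1, n - half + 1), n)))
      edge_valid[k, bad] <- FALSE
    }
  }
  if (vec) coef <- array(coef[1, , ], c(nf, n))
  structure(list(coefficients = coef, freqs = freqs, cycles = cycles,
                 fs = fs, edge_valid = edge_valid),
            class = "tf_decomposition")
}

#' @export
print.tf_decomposition <- function(x, ...) {
  d <- dim(x$coefficients)
  cat("<tf_decomposition>",
      if (length(d) == 3) paste(d[1], "channels,"), length(x$freqs),
      "freqs (", min(x$freqs), "-", max(x$freqs), "Hz ),",
      d[length(d)], "samples @", x$fs, "Hz\n")
  invisible(x)
}

#' Phase and power of a decomposition
#'
#' @param tf a `tf_decomposition` (or a complex array)
#' @return array of phases in (-pi, pi] / of squared magnitudes
#' @export
tf_phase <- function(tf) {
  co <- if (inherits(tf, "tf_decomposition")) tf$coefficients else tf
  Arg(co)
}

#' @rdname tf_phase
#' @export
tf_power <- function(tf) {
  co <- if (inherits(tf, "tf_decomposition")) tf$coefficients else tf
  Mod(co)^2
}

#' Average values over a frequency band
#'
#' Unweighted mean over the grid frequencies inside `band` (both edges
#' inclusive, so 6 Hz belongs to both a 3-6 Hz theta and a 6-9 Hz alpha band,
#' mirroring the conventional overlapping infant band definitions).
#'
#' @param values vector (per frequency) or matrix (`freq x time`)
#' @param freqs frequency grid matching the first dimension
#' @param band c(lo, hi) in Hz
#' @return scalar (vector input) or time series (matrix input)
#' @export
band_average <- function(values, freqs, band) {
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stop("no grid frequencies inside band")
  if (is.null(dim(values))) return(mean(values[sel]))
  colMeans(values[sel, , drop = FALSE])
}
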