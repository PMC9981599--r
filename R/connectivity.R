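#' Windowed phase locking value
#'
#' PLV over non-overlapping temporal windows: within each window of T samples
#' the magnitude of the mean unit phasor of the phase differences,
#' `(1/T) |sum_n exp(i (phi_n - psi_n))|`. 1 = a perfectly constant phase
#' relation, 0 = uniformly scattered differences. Amplitude never enters.
#'
#' @param phase_x,phase_y phase series in radians: vectors, or matrices
#'   (`freq x time`) to evaluate several frequencies at once
#' @param fs sampling rate (Hz)
#' @param window window length in seconds (default 1 s, non-overlapping)
#' @return list with `per_window` (vector or `freq x window` matrix) and
#'   `mean` (scalar or per-frequency vector)
#' @export
plv_windowed <- function(phase_x, phase_y, fs, window = 1) {
  vec <- is.null(dim(phase_x))
  if (vec) {
    phase_x <- matrix(phase_x, nrow = 1)
    phase_y <- matrix(phase_y, nrow = 1)
  }
  stopifnot(all(dim(phase_x) == dim(phase_y)))
  wl <- round(window * fs)
  if (wl < 2) stop("window must contain at least 2 samples")
  n <- ncol(phase_x)
  nwin <- floor(n / wl)
  if (nwin < 1) stop("series shorter than one window")
  E <- exp(1i * (phase_x - phase_y))
  pw <- matrix(0, nrow(phase_x), nwin)
  for (w in seq_len(nwin)) {
    idx <- ((w - 1L) * wl + 1L):(w * wl)
    pw[, w] <- Mod(rowMeans(E[, idx, drop = FALSE]))
  }
  if (vec) list(per_window = pw[1, ], mean = mean(pw[1, ]))
  else list(per_window = pw, mean = rowMeans(pw))
}

#' Inter-trial coherence
#'
#' `ITC(t) = |(1/N) sum_k exp(i phi(t, k))|` over N trials: the consistency
#' of phase angles across trials at each time point, the signature of
#' event-locked phase resetting.
#'
#' @param phases `trials x time` matrix, or `trials x freq x time` array
#' @return time vector, or `freq x time` matrix
#' @export
itc <- function(phases) {
  d <- dim(phases)
  if (is.null(d) || d[1] < 2) stop("ITC needs at least 2 trials")
  E <- exp(1i * phases)
  if (length(d) == 2) return(Mod(colMeans(E)))
  apply(E, c(2, 3), function(z) Mod(mean(z)))
}

#' Fit a bivariate VAR model by least squares
#'
#' Stacks lagged regressors over one or more contiguous segments (lags never
#' cross segment boundaries); segments are demeaned first. No intercept.
#'
#' @param segments a `T x 2` matrix, or a list of such matrices
#' @param order model order p
#' @return a `var_model`: list with `A` (`2 x 2 x p` coefficient array),
#'   `sigma` (innovation covariance), `order`, `n_obs`, `logdet_ml`
#' @export
fit_var <- function(segments, order) {
  if (!is.list(segments)) segments <- list(segments)
  p <- as.integer(order)
  stopifnot(p >= 1)
  Xs <- list(); Ys <- list()
  for (seg in segments) {
    if (nrow(seg) <= p + 2L) next
    seg <- sweep(seg, 2, colMeans(seg))
    E <- stats::embed(seg, p + 1L)
    Ys[[length(Ys) + 1L]] <- E[, 1:2, drop = FALSE]
    Xs[[length(Xs) + 1L]] <- E[, -(1:2), drop = FALSE]
  }
  if (length(Ys) == 0) stop("segments too short for the requested order")
  X <- do.call(rbind, Xs)
  Y <- do.call(rbind, Ys)
  XtX <- crossprod(X)
  rc <- rcond(XtX)
  if (!is.finite(rc) || rc < 1e-12)
    stop("ill-conditioned VAR regression")
  B <- solve(XtX, crossprod(X, Y))
  resid <- Y - X %*% B
  n_obs <- nrow(Y)
  sig_ml <- crossprod(resid) / n_obs
  A <- array(0, c(2, 2, p))
  for (k in seq_len(p)) A[, , k] <- t(B[(2L * k - 1L):(2L * k), ])
  structure(list(A = A, sigma = sig_ml * n_obs / max(1, n_obs - 2 * p),
                 sigma_ml = sig_ml, order = p, n_obs = n_obs,
                 logdet_ml = determinant(sig_ml)$modulus[1]),
            class = "var_model")
}

#' Is a VAR model stable?
#'
#' Spectral radius of the companion matrix below 1.
#'
#' @param model a `var_model` (or a `2 x 2 x p` coefficient array)
#' @return logical
#' @export
var_is_stable <- function(model) {
  A <- if (inherits(model, "var_model")) model$A else model
  p <- dim(A)[3]
  d <- dim(A)[1]
  comp <- matrix(0, d * p, d * p)
  for (k in seq_len(p)) comp[1:d, (d * (k - 1) + 1):(d * k)] <- A[, , k]
  if (p > 1) comp[(d + 1):(d * p), 1:(d * (p - 1))] <- diag(d * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values)) < 1
}

#' Simulate from a bivariate VAR
#'
#' @param A `2 x 2 x p` coefficient array (target <- row, source <- column)
#' @param n samples to return (after a burn-in)
#' @param innov_sd innovation standard deviation(s)
#' @param burn burn-in samples
#' @return `n x 2` matrix
#' @export
simulate_var <- function(A, n, innov_sd = 1, burn = 200) {
  p <- dim(A)[3]
  total <- n + burn
  x <- matrix(stats::rnorm(total * 2, 0, innov_sd), total, 2)
  for (t in (p + 1):total) {
    for (k in seq_len(p)) x[t, ] <- x[t, ] + A[, , k] %*% x[t - k, ]
  }
  x[(burn + 1):total, , drop = FALSE]
}

#' BIC model-order selection for a bivariate VAR
#'
#' Fits orders 1..`max_order` by least squares and returns the argmin of
#' `BIC(p) = log det(Sigma_ML) + p d^2 log(T) / T` (d = 2, T = effective
#' sample size). When given a list of segment collections, one order is
#' selected per collection and the average (rounded) is returned, mirroring
#' the practice of averaging per-segment orders before fixing one value.
#'
#' @param x,y the two series (vectors), or `x` may be a list of `T x 2`
#'   segment matrices with `y` missing
#' @param max_order largest order tried
#' @return selected order (integer); attribute `"bic"` holds the criterion
#'   values for a single series pair
#' @export
select_var_order_bic <- function(x, y = NULL, max_order = 10) {
  if (is.list(x) && is.null(y) && is.matrix(x[[1]])) {
    orders <- vapply(x, function(seg)
      as.numeric(select_var_order_bic(seg[, 1], seg[, 2], max_order)),
      numeric(1))
    return(as.integer(round(mean(orders))))
  }
  seg <- cbind(x, y)
  stopifnot(nrow(seg) > 5 * max_order)
  bic <- numeric(max_order)
  for (p in seq_len(max_order)) {
    fit <- fit_var(seg, p)
    Teff <- fit$n_obs
    bic[p] <- fit$logdet_ml + p * 4 * log(Teff) / Teff
  }
  structure(which.min(bic), bic = bic)
}

#' Partial directed coherence of a VAR model
#'
#' Column-normalised PDC (Baccala-Sameshima): with
#' `Abar(f) = I - sum_k A_k exp(-i 2 pi f k / fs)`, the influence of source
#' j on target i is `|Abar_ij(f)| / sqrt(sum_m |Abar_mj(f)|^2)`, bounded in
#' `[0, 1]` with unit column sums of squares.
#'
#' @param model a `var_model` or `2 x 2 x p` coefficient array
#' @param freqs evaluation frequencies (Hz)
#' @param fs sampling rate (Hz)
#' @return `2 x 2 x n_freq` array; `[i, j, f]` is source j -> target i
#' @export
pdc_from_var <- function(model, freqs, fs) {
  A <- if (inherits(model, "var_model")) model$A else model
  p <- dim(A)[3]
  # exponential basis: p x n_freq
  E <- exp(-1i * 2 * pi * outer(seq_len(p), freqs) / fs)
  a11 <- Mod(1 - drop(A[1, 1, ] %*% E))
  a12 <- Mod(0 - drop(A[1, 2, ] %*% E))
  a21 <- Mod(0 - drop(A[2, 1, ] %*% E))
  a22 <- Mod(1 - drop(A[2, 2, ] %*% E))
  d1 <- sqrt(a11^2 + a21^2)
  d2 <- sqrt(a12^2 + a22^2)
  out <- array(0, c(2, 2, length(freqs)))
  out[1, 1, ] <- a11 / d1
  out[2, 1, ] <- a21 / d1
  out[1, 2, ] <- a12 / d2
  out[2, 2, ] <- a22 / d2
  out
}

#' Windowed PDC between two channels
#'
#' Fits a bivariate VAR in non-overlapping windows (default 1 s) and averages
#' the PDC spectra over windows; unstable or ill-conditioned windows are
#' skipped and counted.
#'
#' @param x,y the two series (e.g. one channel per partner)
#' @param fs sampling rate (Hz)
#' @param order VAR model order
#' @param freqs evaluation frequencies (Hz)
#' @param window window length in seconds
#' @return list with `x_to_y`, `y_to_x` (per-frequency means), `per_window`
#'   (`2 x 2 x freq x window` array), `n_skipped`
#' @export
pdc_windowed <- function(x, y, fs, order = 5, freqs = default_freqs(),
                         window = 1) {
  wl <- round(window * fs)
  nwin <- floor(length(x) / wl)
  if (nwin < 1) stop("series shorter than one window")
  per <- array(NA_real_, c(2, 2, length(freqs), nwin))
  skipped <- 0L
  for (w in seq_len(nwin)) {
    idx <- ((w - 1L) * wl + 1L):(w * wl)
    fit <- tryCatch(fit_var(cbind(x[idx], y[idx]), order),
                    error = function(e) NULL)
    if (is.null(fit) || !var_is_stable(fit)) { skipped <- skipped + 1L; next }
    per[, , , w] <- pdc_from_var(fit, freqs, fs)
  }
  if (skipped == nwin) stop("no stable VAR fit in any window")
  mean_map <- apply(per, c(1, 2, 3), mean, na.rm = TRUE)
  list(x_to_y = mean_map[2, 1, ], y_to_x = mean_map[1, 2, ],
       per_window = per, n_skipped = skipped, freqs = freqs)
}

#' Event-locked across-trial PLV map
#'
#' At each (frequency, time) point of the peri-event axis, the consistency of
#' the phase *difference* between the two partners across trials:
#' `|(1/K) sum_k exp(i (phi_x - phi_y))|`.
#'
#' @param phase_x,phase_y `trials x freq x time` phase arrays with identical
#'   time locking
#' @return `freq x time` matrix in `[0, 1]`
#' @export
event_locked_plv <- function(phase_x, phase_y) {
  stopifnot(all(dim(phase_x) == dim(phase_y)))
  if (dim(phase_x)[1] < 2) stop("need at least 2 trials")
  E <- exp(1i * (phase_x - phase_y))
  apply(E, c(2, 3), function(z) Mod(mean(z)))
}

#' Event-locked PDC map
#'
#' Slides a window across the peri-event axis; within each window position a
#' single VAR is fitted pooling all trials (each trial contributes one
#' segment, lags never cross trials) and the PDC spectrum is assigned to the
#' window centre.
#'
#' @param x_epochs,y_epochs `trials x samples` matrices (one channel each)
#' @param times peri-event time axis (s) matching the sample dimension
#' @param fs sampling rate (Hz)
#' @param order VAR order
#' @param freqs evaluation frequencies (Hz)
#' @param window window length (s)
#' @param step window step (s)
#' @return list with `x_to_y`, `y_to_x` (`freq x position` matrices) and
#'   `times` (window centres, s)
#' @export
event_locked_pdc <- function(x_epochs, y_epochs, times, fs, order = 5,
                             freqs = default_freqs(), window = 1,
                             step = 0.1) {
  stopifnot(all(dim(x_epochs) == dim(y_epochs)))
  wl <- round(window * fs)
  stp <- max(1L, round(step * fs))
  L <- ncol(x_epochs)
  starts <- seq(1L, L - wl + 1L, by = stp)
  nf <- length(freqs)
  m_xy <- matrix(NA_real_, nf, length(starts))
  m_yx <- matrix(NA_real_, nf, length(starts))
  for (s in seq_along(starts)) {
    idx <- starts[s]:(starts[s] + wl - 1L)
    segs <- lapply(seq_len(nrow(x_epochs)), function(k)
      cbind(x_epochs[k, idx], y_epochs[k, idx]))
    fit <- tryCatch(fit_var(segs, order), error = function(e) NULL)
    if (is.null(fit)) next
    pd <- pdc_from_var(fit, freqs, fs)
    m_xy[, s] <- pd[2, 1, ]
    m_yx[, s] <- pd[1, 2, ]
  }
  list(x_to_y = m_xy, y_to_x = m_yx,
       times = times[starts] + window / 2, freqs = freqs)
}
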