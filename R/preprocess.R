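#' Zero-phase band-pass filter
#'
#' Frequency-domain filter with raised-cosine transition bands: unity gain in
#' `[low, high]`, cosine roll-off to zero over `[low/2, low]` and
#' `[high, 1.5*high]`. Zero-phase by construction and at least 20 dB down one
#' octave outside the band. Signals are reflection-padded before the FFT to
#' suppress wrap-around edge effects.
#'
#' @param x numeric vector or channels-by-samples matrix
#' @param fs sampling rate (Hz)
#' @param low,high passband edges (Hz); `high` must be below Nyquist
#' @return filtered data, same shape as `x`
#' @export
bandpass_filter <- function(x, fs, low = 1, high = 20) {
  stopifnot(low > 0, high > low)
  if (high >= fs / 2) stop("high edge must be below the Nyquist frequency")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n0 <- ncol(x)
  pad <- min(n0 - 1L, 2L * round(fs))
  n <- n0 + 2L * pad
  fr <- (seq_len(n) - 1) / n * fs
  fr <- pmin(fr, fs - fr)
  hi2 <- min(1.5 * high, (high + fs / 2) / 2)
  H <- numeric(n)
  H[fr >= low & fr <= high] <- 1
  lo_t <- fr > low / 2 & fr < low
  H[lo_t] <- 0.5 * (1 - cos(pi * (fr[lo_t] - low / 2) / (low - low / 2)))
  hi_t <- fr > high & fr < hi2
  H[hi_t] <- 0.5 * (1 + cos(pi * (fr[hi_t] - high) / (hi2 - high)))
  out <- x
  for (ch in seq_len(nrow(x))) {
    padded <- c(rev(x[ch, seq_len(pad) + 1L]), x[ch, ],
                rev(x[ch, (n0 - pad):(n0 - 1L)]))
    y <- Re(stats::fft(stats::fft(padded) * H, inverse = TRUE)) / n
    out[ch, ] <- y[(pad + 1L):(pad + n0)]
  }
  if (vec) out[1, ] else out
}

#' Robust average reference
#'
#' Re-references each sample by subtracting the cross-channel median, which a
#' single extreme channel perturbs far less than the plain mean would.
#'
#' @param x channels-by-samples matrix (>= 2 channels)
#' @return re-referenced matrix
#' @export
robust_average_reference <- function(x) {
  if (is.null(dim(x)) || nrow(x) < 2)
    stop("robust average reference needs at least 2 channels")
  ref <- apply(x, 2, stats::median)
  sweep(x, 2, ref, "-")
}

# leave-one-out median across channels, vectorised via a per-sample sort
loo_median <- function(x) {
  nc <- nrow(x)
  S <- apply(x, 2, sort)
  m <- nc - 1L
  out <- matrix(0, nc, ncol(x))
  if (m %% 2L == 1L) {
    k <- (m + 1L) %/% 2L
    lo <- S[k, ]; hi <- S[k + 1L, ]
    for (i in seq_len(nc)) out[i, ] <- ifelse(x[i, ] <= lo, hi, lo)
  } else {
    k <- m %/% 2L
    a <- S[k, ]; b <- S[k + 1L, ]; cc <- S[k + 2L, ]
    for (i in seq_len(nc)) {
      below <- x[i, ] <= a
      above <- x[i, ] >= cc
      out[i, ] <- ifelse(below, (b + cc) / 2,
                  ifelse(above, (a + b) / 2, (a + cc) / 2))
    }
  }
  dimnames(out) <- dimnames(x)
  out
}

#' Interpolate channels poorly correlated with their robust estimate
#'
#' A channel whose Pearson correlation with the leave-one-out median of the
#' other channels falls below `corr_threshold` is replaced by the mean of its
#' `k` nearest good channels on the scalp (montage distance).
#'
#' @param x channels-by-samples matrix with channel labels as rownames
#' @param corr_threshold flagging threshold (default 0.7)
#' @param k number of neighbouring channels used for interpolation
#' @return list with `data` (matrix) and `interpolated` (labels replaced)
#' @export
interpolate_bad_channels <- function(x, corr_threshold = 0.7, k = 4) {
  stopifnot(!is.null(rownames(x)), nrow(x) >= 3)
  est <- loo_median(x)
  r <- vapply(seq_len(nrow(x)),
              function(i) suppressWarnings(stats::cor(x[i, ], est[i, ])),
              numeric(1))
  r[is.na(r)] <- 0
  bad <- which(r < corr_threshold)
  if (length(bad) > nrow(x) / 2)
    stop("more than half the channels flagged bad; data unusable")
  good <- setdiff(rownames(x), rownames(x)[bad])
  for (i in bad) {
    nb <- nearest_channels(rownames(x)[i], good, k)
    x[i, ] <- colMeans(x[nb, , drop = FALSE])
  }
  list(data = x, interpolated = rownames(x)[bad])
}

#' Reject high-power segments
#'
#' Sliding non-overlapping windows of `win` seconds are marked for rejection
#' when more than `channel_frac` of channels exceed their own mean epoch
#' power plus `sd_mult` standard deviations (statistics taken over all epochs
#' of the recording). Returns a sample mask consumed by the epoching and
#' segmentation functions so rejected data never reach an analysis.
#'
#' @param x channels-by-samples matrix
#' @param fs sampling rate (Hz)
#' @param win window length in seconds
#' @param channel_frac fraction of channels that must exceed threshold
#' @param sd_mult threshold in standard deviations above the mean power
#' @return list with `mask` (logical per sample, TRUE = rejected),
#'   `fraction_removed`, and `rejected_epochs` (indices)
#' @export
reject_highpower_segments <- function(x, fs, win = 1, channel_frac = 0.70,
                                      sd_mult = 5) {
  n <- ncol(x)
  wl <- round(win * fs)
  if (n < wl) stop("recording shorter than one window")
  n_ep <- floor(n / wl)
  pw <- matrix(0, nrow(x), n_ep)
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1L) * wl + 1L):(e * wl)
    seg <- x[, idx, drop = FALSE]
    seg <- seg - rowMeans(seg)
    pw[, e] <- rowMeans(seg^2)
  }
  mu <- rowMeans(pw)
  sdv <- apply(pw, 1, stats::sd)
  exceeds <- pw > (mu + sd_mult * sdv)
  rejected <- which(colMeans(exceeds) > channel_frac)
  mask <- rep(FALSE, n)
  for (e in rejected) mask[((e - 1L) * wl + 1L):(e * wl)] <- TRUE
  list(mask = mask, fraction_removed = mean(mask), rejected_epochs = rejected)
}

new_epoch_set <- function(data, times, fs, events, condition = NA_character_) {
  structure(list(data = data, times = times, fs = fs, events = events,
                 condition = condition),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set>", dim(x$data)[1], "trials x", dim(x$data)[2],
      "channels x", dim(x$data)[3], "samples;",
      sprintf("window [%g, %g] s", x$times[1], x$times[length(x$times)]), "\n")
  invisible(x)
}

#' Extract event-locked epochs from both partners
#'
#' Slices both partners' EEG around each event on the shared dyad clock
#' (t = 0 at the gaze onset; no lag between the partners' time locking).
#' Trials that would extend past the recording edges or overlap masked
#' samples are dropped and reported.
#'
#' @param dyad a `dyad_recording`
#' @param events data.frame of events (default `dyad$events`)
#' @param window c(start, end) seconds relative to onset
#' @param mask optional logical sample mask (TRUE = rejected)
#' @return list with `infant` and `adult` `epoch_set`s (identical trials and
#'   time axes) and `dropped` (data.frame of discarded events with reasons)
#' @export
extract_event_epochs <- function(dyad, events = dyad$events,
                                 window = c(-2.5, 2.5), mask = NULL) {
  fs <- dyad$fs
  n <- ncol(dyad$infant)
  L <- round((window[2] - window[1]) * fs)
  times <- window[1] + (seq_len(L) - 1) / fs
  starts <- round(events$onset_s * fs) + round(window[1] * fs)  # 0-based
  ok_edge <- starts >= 0 & (starts + L) <= n
  ok_mask <- rep(TRUE, length(starts))
  if (!is.null(mask)) {
    for (i in which(ok_edge)) {
      ok_mask[i] <- !any(mask[(starts[i] + 1L):(starts[i] + L)])
    }
  }
  keep <- ok_edge & ok_mask
  dropped <- events[!keep, , drop = FALSE]
  if (nrow(dropped) > 0) {
    dropped$reason <- ifelse(!ok_edge[!keep], "edge", "masked")
  } else dropped$reason <- character(0)
  kept <- events[keep, , drop = FALSE]
  one <- function(eeg) {
    dat <- array(0, c(nrow(kept), nrow(eeg), L),
                 dimnames = list(NULL, rownames(eeg), NULL))
    for (i in seq_len(nrow(kept))) {
      dat[i, , ] <- eeg[, (starts[keep][i] + 1L):(starts[keep][i] + L)]
    }
    new_epoch_set(dat, times, fs, kept)
  }
  list(infant = one(dyad$infant), adult = one(dyad$adult), dropped = dropped)
}

#' Segment paired EEG by joint gaze state
#'
#' Mutual looks are maximal frame runs where both partners are on `partner`;
#' non-mutual looks are runs where exactly one partner is. Each look
#' contributes one segment of both partners' EEG, extracted from the look
#' onset for the look's duration. Looks overlapping masked samples are
#' dropped.
#'
#' @param dyad a `dyad_recording`
#' @param timelines gaze timelines (default `dyad$timelines`)
#' @param mask optional logical sample mask (TRUE = rejected)
#' @return list with `mutual` and `nonmutual` `state_segment_set`s
#' @export
segment_by_gaze_state <- function(dyad, timelines = dyad$timelines,
                                  mask = NULL) {
  fr <- timelines$infant$frame_rate
  fs <- dyad$fs
  n <- ncol(dyad$infant)
  ip <- timelines$infant$states == "partner"
  ap <- timelines$adult$states == "partner"
  joint <- ifelse(ip & ap, "mutual", ifelse(xor(ip, ap), "nonmutual", "none"))
  runs <- rle(joint)
  ends <- cumsum(runs$lengths)
  starts_f <- ends - runs$lengths + 1L
  one_state <- function(state) {
    idx <- which(runs$values == state)
    segs <- list(); lens <- numeric(0); ons <- numeric(0)
    for (r in idx) {
      t0 <- (starts_f[r] - 1L) / fr
      t1 <- ends[r] / fr
      i1 <- round(t0 * fs) + 1L
      i2 <- min(n, round(t1 * fs))
      if (i2 <= i1) next
      if (!is.null(mask) && any(mask[i1:i2])) next
      segs[[length(segs) + 1L]] <- list(
        infant = dyad$infant[, i1:i2, drop = FALSE],
        adult = dyad$adult[, i1:i2, drop = FALSE],
        samples = c(i1, i2)
      )
      lens <- c(lens, (i2 - i1 + 1L) / fs)
      ons <- c(ons, t0)
    }
    structure(list(segments = segs, lengths_s = lens, total_s = sum(lens),
                   onsets_s = ons, fs = fs, state = state),
              class = "state_segment_set")
  }
  list(mutual = one_state("mutual"), nonmutual = one_state("nonmutual"))
}

#' @export
print.state_segment_set <- function(x, ...) {
  cat("<state_segment_set>", x$state, ":", length(x$segments), "looks,",
      round(x$total_s, 2), "s total\n")
  invisible(x)
}

#' Equalise the amount of data between two conditions
#'
#' Phase-based estimators are sensitive to the amount of data, so the larger
#' condition is truncated to the size of the smaller: the first `n` trials
#' for epoch sets, the first `n` samples (trimming the final look) for
#' state-segment sets. Idempotent; order preserved.
#'
#' @param a,b two `epoch_set`s or two `state_segment_set`s
#' @return list with truncated `a` and `b`
#' @export
match_condition_counts <- function(a, b) {
  if (inherits(a, "epoch_set") && inherits(b, "epoch_set")) {
    n <- min(dim(a$data)[1], dim(b$data)[1])
    if (n == 0) warning("one condition has no trials; both emptied")
    trunc_ep <- function(e) {
      e$data <- e$data[seq_len(n), , , drop = FALSE]
      e$events <- e$events[seq_len(n), , drop = FALSE]
      e
    }
    return(list(a = trunc_ep(a), b = trunc_ep(b)))
  }
  if (inherits(a, "state_segment_set") && inherits(b, "state_segment_set")) {
    fs <- a$fs
    n <- min(round(a$total_s * fs), round(b$total_s * fs))
    if (n == 0) warning("one condition has no data; both emptied")
    trunc_ss <- function(s) {
      kept <- list(); lens <- numeric(0); ons <- numeric(0); acc <- 0L
      for (k in seq_along(s$segments)) {
        if (acc >= n) break
        seg <- s$segments[[k]]
        len <- ncol(seg$infant)
        take <- min(len, n - acc)
        if (take < len) {
          seg$infant <- seg$infant[, seq_len(take), drop = FALSE]
          seg$adult <- seg$adult[, seq_len(take), drop = FALSE]
          seg$samples <- c(seg$samples[1], seg$samples[1] + take - 1L)
        }
        kept[[length(kept) + 1L]] <- seg
        lens <- c(lens, take / fs)
        ons <- c(ons, s$onsets_s[k])
        acc <- acc + take
      }
      s$segments <- kept; s$lengths_s <- lens; s$total_s <- sum(lens)
      s$onsets_s <- ons
      s
    }
    return(list(a = trunc_ss(a), b = trunc_ss(b)))
  }
  stop("a and b must both be epoch_sets or both state_segment_sets")
}

#' Concatenate a state-segment set into continuous matrices
#'
#' @param sss a `state_segment_set`
#' @param channels optional channel labels to keep
#' @return list with `infant`, `adult` (channels x total samples) and
#'   `boundaries` (cumulative segment end samples)
#' @export
concat_state_segments <- function(sss, channels = NULL) {
  pick <- function(m) if (is.null(channels)) m else m[channels, , drop = FALSE]
  if (length(sss$segments) == 0) {
    return(list(infant = NULL, adult = NULL, boundaries = integer(0)))
  }
  inf <- do.call(cbind, lapply(sss$segments, function(s) pick(s$infant)))
  ad <- do.call(cbind, lapply(sss$segments, function(s) pick(s$adult)))
  list(infant = inf, adult = ad,
       boundaries = cumsum(vapply(sss$segments, function(s) ncol(s$infant),
                                  integer(1))))
}
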