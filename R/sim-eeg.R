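#' ERP template used by the generator
#'
#' Sum of Gaussian-windowed components (P1/N290/P400 analogues for infants;
#' the same components shifted 100 ms earlier for adults) sampled at `fs`.
#'
#' @param config a [sim_config()]
#' @param population `"infant"` or `"adult"`
#' @param span template length in seconds after onset
#' @return numeric vector (uV), first sample at the onset
#' @export
erp_template <- function(config, population = c("infant", "adult"),
                         span = 0.8) {
  population <- match.arg(population)
  lat <- if (population == "infant") config$erp_latencies_infant
         else config$erp_latencies_adult
  t_ms <- (seq_len(round(span * config$fs)) - 1) / config$fs * 1000
  out <- numeric(length(t_ms))
  for (j in seq_along(config$erp_amplitudes)) {
    out <- out + config$erp_amplitudes[[j]] *
      exp(-(t_ms - lat[[j]])^2 / (2 * config$erp_widths[[j]]^2))
  }
  out
}

# add `template * scale` into `eeg[channels, ]` at each onset sample
add_template <- function(eeg, channels, onsets_s, fs, template, scale) {
  if (scale == 0 || length(onsets_s) == 0) return(eeg)
  n <- ncol(eeg)
  for (on in onsets_s) {
    i1 <- round(on * fs) + 1L
    len <- min(length(template), n - i1 + 1L)
    if (len < 1) next
    idx <- i1:(i1 + len - 1L)
    eeg[channels, idx] <- eeg[channels, idx] +
      rep(template[seq_len(len)] * scale, each = length(channels))
  }
  eeg
}

# phase offset implementing resets: circular pull toward `target` with the
# given per-event strengths, ramped over `ramp_n` samples
reset_offset <- function(base_phase, onset_samples, strengths, target, ramp_n) {
  n <- length(base_phase)
  offset <- numeric(n)
  ord <- order(onset_samples)
  for (k in ord) {
    s0 <- onset_samples[k]
    if (s0 < 1 || s0 > n) next
    delta <- wrap_angle(target - (base_phase[s0] + offset[s0])) * strengths[k]
    ramp_end <- min(n, s0 + ramp_n - 1L)
    m <- ramp_end - s0 + 1L
    offset[s0:ramp_end] <- offset[s0:ramp_end] + delta * (seq_len(m) / ramp_n)
    if (ramp_end < n) offset[(ramp_end + 1L):n] <- offset[(ramp_end + 1L):n] + delta
  }
  offset
}

#' Synthesize dual EEG for one dyad
#'
#' Builds a two-person EEG recording on a shared clock. Each channel is
#' 1/f^alpha noise plus ongoing oscillators with slowly drifting phase
#' (random-walk phase noise, shared within a partner, with channel-specific
#' phase offsets). At each sender gaze onset the sender's occipital channels
#' optionally receive (a) an additive ERP template and/or (b) a phase reset
#' (circular interpolation of oscillator phase toward a target angle over a
#' short ramp, which avoids the amplitude discontinuities that would
#' masquerade as phase synchrony). Mutual-gaze onsets can additionally reset
#' both partners (`mutual_reset_strength`), inter-brain coupling can be
#' injected over the central channels, and biphasic frontal saccade
#' transients can be added near sender onsets.
#'
#' @param timelines list with `infant`/`adult` gaze timelines
#' @param events data.frame from [derive_gaze_events()]
#' @param config a [sim_config()]
#' @return a `dyad_recording`: list with `infant` and `adult` channel-by-sample
#'   matrices (uV, rownames = channel labels), `channels`, `fs`, `duration`,
#'   `events` and `timelines`
#' @export
synthesize_dyad_eeg <- function(timelines, events, config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs
  n <- round(config$duration * fs)
  if (nrow(events) > 0 && (any(events$onset_s < 0) ||
                           any(events$onset_s >= config$duration)))
    stop("events outside recording duration")
  if (config$n_channels < 7)
    stop("need at least 7 channels to retain the analysis electrodes")
  labels <- unique(c(central_channels(), occipital_cluster(),
                     frontal_channels(), .biosemi32$label))
  labels <- labels[seq_len(config$n_channels)]
  occ <- match(intersect(occipital_cluster(), labels), labels)
  frontal <- match(intersect(frontal_channels(), labels), labels)
  ramp_n <- max(1L, round(config$reset_ramp * fs))
  set.seed(child_seed(config$seed, 501L))

  # per-partner reset events: own sender onsets plus mutual onsets (either
  # sender) under the dual-reset mechanism; combined multiplicatively
  reset_events <- function(role) {
    if (nrow(events) == 0) return(NULL)
    s_own <- ifelse(events$sender == role, config$reset_strength, 0)
    s_mut <- ifelse(events$gaze_type == "mutual",
                    config$mutual_reset_strength, 0)
    strength <- 1 - (1 - s_own) * (1 - s_mut)
    keep <- strength > 0
    if (!any(keep)) return(NULL)
    list(samples = round(events$onset_s[keep] * fs) + 1L,
         strengths = strength[keep])
  }

  make_partner <- function(role) {
    eeg <- pink_noise(n, length(labels), config$noise_alpha, config$noise_sd)
    rownames(eeg) <- labels
    rs <- reset_events(role)
    tvec <- (seq_len(n) - 1) / fs
    for (j in seq_along(config$osc_freqs)) {
      f <- config$osc_freqs[j]
      amp <- config$osc_amps[j]
      if (amp <= 0) next
      drift <- cumsum(stats::rnorm(n, 0, config$osc_drift_sd / sqrt(fs)))
      base <- 2 * pi * f * tvec + drift
      phi0 <- stats::runif(length(labels), -pi, pi)
      for (ch in seq_along(labels)) {
        ph <- base + phi0[ch]
        if (!is.null(rs) && ch %in% occ) {
          ph <- ph + reset_offset(ph, rs$samples, rs$strengths,
                                  config$reset_phase, ramp_n)
        }
        eeg[ch, ] <- eeg[ch, ] + amp * cos(ph)
      }
    }
    # sender-locked ERP template on the sender's own occipital channels
    if (config$erp_scale != 0 && nrow(events) > 0) {
      tmpl <- erp_template(config, role)
      eeg <- add_template(eeg, occ, events$onset_s[events$sender == role],
                          fs, tmpl, config$erp_scale)
    }
    # optional receiver response (partner is the sender)
    if (config$receiver_erp_scale != 0 && nrow(events) > 0) {
      tmpl <- erp_template(config, role)
      eeg <- add_template(eeg, occ, events$onset_s[events$sender != role],
                          fs, tmpl, config$receiver_erp_scale)
    }
    if (isTRUE(config$saccade_artifact) && nrow(events) > 0) {
      ons <- events$onset_s[events$sender == role]
      if (length(ons) > 0) {
        jit <- stats::runif(length(ons), -0.1, 0.1)
        sig <- 0.02
        tt <- seq(-0.08, 0.08, by = 1 / fs)
        shape <- -(tt / sig) * exp(-tt^2 / (2 * sig^2))
        shape <- 25 * shape / max(abs(shape))
        for (k in seq_along(ons)) {
          c0 <- round((ons[k] + jit[k]) * fs) + 1L - (length(tt) - 1L) %/% 2L
          idx <- c0:(c0 + length(tt) - 1L)
          ok <- idx >= 1 & idx <= n
          eeg[frontal, idx[ok]] <- eeg[frontal, idx[ok]] +
            rep(shape[ok], each = length(frontal))
        }
      }
    }
    eeg
  }

  infant <- make_partner("infant")
  adult <- make_partner("adult")

  cp <- config$coupling
  if (cp$type == "directed") {
    from <- cp$from %||% "infant"
    lag <- as.integer(cp$lag %||% 1L)
    gain <- cp$gain %||% 0.4
    src <- if (from == "infant") infant else adult
    cen <- match(intersect(central_channels(), labels), labels)
    shifted <- cbind(matrix(0, length(cen), lag),
                     src[cen, seq_len(n - lag), drop = FALSE])
    if (from == "infant") adult[cen, ] <- adult[cen, ] + gain * shifted
    else infant[cen, ] <- infant[cen, ] + gain * shifted
  } else if (cp$type == "common_driver") {
    f <- cp$freq %||% 4
    gain <- cp$gain %||% 3
    during <- cp$during %||% "all"
    tvec <- (seq_len(n) - 1) / fs
    drift <- cumsum(stats::rnorm(n, 0, config$osc_drift_sd / sqrt(fs)))
    driver <- gain * cos(2 * pi * f * tvec + drift)
    if (during == "mutual") {
      fr_idx <- pmin(floor(tvec * config$frame_rate) + 1L,
                     length(timelines$infant$states))
      ind <- (timelines$infant$states == "partner" &
              timelines$adult$states == "partner")[fr_idx]
      driver <- driver * as.numeric(ind)
    }
    cen <- match(intersect(central_channels(), labels), labels)
    infant[cen, ] <- infant[cen, ] + rep(driver, each = length(cen))
    adult[cen, ] <- adult[cen, ] + rep(driver, each = length(cen))
  }

  structure(list(infant = infant, adult = adult, channels = labels,
                 fs = fs, duration = config$duration,
                 events = events, timelines = timelines),
            class = "dyad_recording")
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat("<dyad_recording>", length(x$channels), "channels,", x$duration,
      "s @", x$fs, "Hz,", nrow(x$events), "gaze events\n")
  invisible(x)
}

#' Simulate a complete dyad
#'
#' Convenience wrapper: gaze timelines, derived events, and synthetic dual
#' EEG, all reproducible from `config$seed`.
#'
#' @param config a [sim_config()]
#' @return a `dyad_recording`
#' @export
simulate_dyad <- function(config) {
  tl <- generate_gaze_timelines(config)
  ev <- derive_gaze_events(tl$infant, tl$adult)
  synthesize_dyad_eeg(tl, ev, config)
}
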