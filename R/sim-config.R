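#' Simulation configuration for a synthetic dyad
#'
#' Bundles every tunable of the synthetic dyadic-EEG generator. Defaults
#' emulate the behavioural and neural structure of a naturalistic
#' infant-caregiver play session: ~386 s recordings, 50 Hz frame-coded gaze
#' with infant occupancy ~34/31/35% and adult ~62/31/7% over
#' partner/puppet/inattentive, 32-channel 512 Hz EEG made of 1/f noise plus
#' band-limited oscillators with slowly drifting phase, and optional
#' sender-locked ERP templates, phase resets, inter-brain coupling and
#' saccade-like frontal transients.
#'
#' Dwell-time means are chosen so that (a) state occupancy converges to the
#' targets (occupancy is proportional to mean dwell under uniform switching)
#' and (b) partner-look onset rates match observed event counts (~31 infant
#' and ~44 adult partner-look onsets per 386 s session). Dwells are truncated
#' normal with a 0.2 s floor.
#'
#' @param seed integer RNG seed; the whole dyad is reproducible from it
#' @param duration recording length in seconds
#' @param fs EEG sampling rate (Hz)
#' @param frame_rate gaze coding rate (Hz)
#' @param n_channels number of EEG channels (<= 32, taken from the montage;
#'   must retain the occipital and central analysis channels)
#' @param dwell_mean,dwell_sd named lists (`infant`, `adult`) of length-3
#'   vectors (partner, puppet, inattentive) of dwell means/SDs in seconds
#' @param dwell_floor lower truncation bound for dwell times (s)
#' @param occupancy named list of length-3 target occupancy proportions;
#'   states with target 0 are never entered
#' @param noise_sd 1/f noise standard deviation (uV); 0 disables noise
#' @param noise_alpha spectral exponent of the background noise
#' @param osc_freqs,osc_amps ongoing oscillator frequencies (Hz) and
#'   amplitudes (uV)
#' @param osc_drift_sd phase-drift standard deviation (rad per sqrt(s))
#' @param erp_scale multiplier on the ERP template added to the sender's
#'   occipital channels at each of their gaze onsets (0 disables)
#' @param erp_amplitudes,erp_widths component amplitudes (uV) and Gaussian
#'   widths (ms); latencies are population specific (`erp_latencies_infant`,
#'   `erp_latencies_adult`, ms)
#' @param reset_strength in `[0, 1]`: how strongly the sender's occipital
#'   oscillator phase is pulled to `reset_phase` at their own gaze onsets
#' @param mutual_reset_strength in `[0, 1]`: phase reset applied to *both*
#'   partners at mutual gaze onsets (the dual phase-resetting mechanism)
#' @param reset_phase target phase angle (rad)
#' @param reset_ramp reset ramp duration (s); circular interpolation over
#'   this window avoids amplitude discontinuities
#' @param coupling list describing inter-brain coupling:
#'   `list(type = "none")`, `list(type = "common_driver", freq, gain,
#'   during = c("all", "mutual"))`, or `list(type = "directed", from =
#'   "infant", lag, gain)` with `lag` in samples
#' @param receiver_erp_scale ERP template multiplier for the receiver (0 =
#'   the sender-only world)
#' @param saccade_artifact logical; add a biphasic frontal transient within
#'   +/-150 ms of each sender gaze onset
#' @return an object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       duration = 386,
                       fs = 512,
                       frame_rate = 50,
                       n_channels = 32,
                       dwell_mean = list(infant = c(partner = 4.23, puppet = 3.86, inattentive = 4.36),
                                         adult  = c(partner = 5.49, puppet = 2.74, inattentive = 0.62)),
                       dwell_sd = NULL,
                       dwell_floor = 0.2,
                       occupancy = list(infant = c(partner = 0.34, puppet = 0.31, inattentive = 0.35),
                                        adult  = c(partner = 0.62, puppet = 0.31, inattentive = 0.07)),
                       noise_sd = 10,
                       noise_alpha = 1,
                       osc_freqs = c(4, 8),
                       osc_amps = c(4, 3),
                       osc_drift_sd = 1.5,
                       erp_scale = 0,
                       erp_amplitudes = c(P1 = 5, N290 = -6, P400 = 4),
                       erp_latencies_infant = c(P1 = 120, N290 = 290, P400 = 450),
                       erp_latencies_adult = c(P1 = 20, N290 = 190, P400 = 350),
                       erp_widths = c(P1 = 30, N290 = 40, P400 = 60),
                       reset_strength = 0,
                       mutual_reset_strength = 0,
                       reset_phase = 0,
                       reset_ramp = 0.05,
                       coupling = list(type = "none"),
                       receiver_erp_scale = 0,
                       saccade_artifact = FALSE) {
  if (is.null(dwell_sd)) {
    dwell_sd <- lapply(dwell_mean, function(m) m / 3)
  }
  stopifnot(
    duration > 0, fs > 0, frame_rate > 0,
    n_channels >= 2, n_channels <= nrow(.biosemi32),
    reset_strength >= 0, reset_strength <= 1,
    mutual_reset_strength >= 0, mutual_reset_strength <= 1,
    all(unlist(dwell_mean) > 0), all(unlist(dwell_sd) > 0),
    length(osc_freqs) == length(osc_amps),
    coupling$type %in% c("none", "common_driver", "directed")
  )
  cfg <- list(
    seed = as.integer(seed), duration = duration, fs = fs,
    frame_rate = frame_rate, n_channels = n_channels,
    dwell_mean = dwell_mean, dwell_sd = dwell_sd, dwell_floor = dwell_floor,
    occupancy = occupancy,
    noise_sd = noise_sd, noise_alpha = noise_alpha,
    osc_freqs = osc_freqs, osc_amps = osc_amps, osc_drift_sd = osc_drift_sd,
    erp_scale = erp_scale, erp_amplitudes = erp_amplitudes,
    erp_latencies_infant = erp_latencies_infant,
    erp_latencies_adult = erp_latencies_adult,
    erp_widths = erp_widths,
    reset_strength = reset_strength,
    mutual_reset_strength = mutual_reset_strength,
    reset_phase = reset_phase, reset_ramp = reset_ramp,
    coupling = coupling, receiver_erp_scale = receiver_erp_scale,
    saccade_artifact = saccade_artifact
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$duration, "s @", x$fs, "Hz,", x$n_channels,
      "channels, seed", x$seed, "\n")
  invisible(x)
}

#' Read/write a simulation configuration as JSON
#'
#' @param cfg a [sim_config()] object
#' @param path file path
#' @return `read_sim_config` returns a `sim_config`
#' @export
write_sim_config <- function(cfg, path) {
  out <- unclass(cfg)
  # jsonlite drops names of atomic vectors; keep the state names as keys
  for (f in c("dwell_mean", "dwell_sd", "occupancy")) {
    out[[f]] <- lapply(out[[f]], as.list)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$dwell_mean <- lapply(raw$dwell_mean, unlist)
  raw$dwell_sd <- lapply(raw$dwell_sd, unlist)
  raw$occupancy <- lapply(raw$occupancy, unlist)
  do.call(sim_config, raw)
}
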