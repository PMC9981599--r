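GAZE_STATES <- c("partner", "puppet", "inattentive")

new_gaze_timeline <- function(role, states, frame_rate, duration) {
  structure(list(role = role, states = states, frame_rate = frame_rate,
                 duration = duration),
            class = "gaze_timeline")
}

#' @export
print.gaze_timeline <- function(x, ...) {
  occ <- round(100 * prop.table(table(factor(x$states, GAZE_STATES))))
  cat("<gaze_timeline>", x$role, ":", length(x$states), "frames @",
      x$frame_rate, "Hz; occupancy", paste0(occ, "%", collapse = "/"), "\n")
  invisible(x)
}

# one semi-Markov state sequence; dwell times are truncated normal, the
# embedded chain switches uniformly among the *other* states with a positive
# occupancy target (a zero target removes the state entirely)
simulate_gaze_sequence <- function(n_frames, frame_rate, dwell_mean, dwell_sd,
                                   dwell_floor, occupancy) {
  active <- GAZE_STATES[occupancy[GAZE_STATES] > 0]
  if (length(active) == 0) stop("all occupancy targets are zero")
  states <- character(n_frames)
  pos <- 1L
  cur <- sample(active, 1, prob = occupancy[active])
  while (pos <= n_frames) {
    d <- rtruncnorm(1, dwell_mean[[cur]], dwell_sd[[cur]], dwell_floor)
    len <- max(1L, round(d * frame_rate))
    end <- min(n_frames, pos + len - 1L)
    states[pos:end] <- cur
    pos <- end + 1L
    nxt <- setdiff(active, cur)
    cur <- if (length(nxt) == 1) nxt else sample(nxt, 1)
  }
  states
}

#' Generate a dyad's gaze timelines
#'
#' Simulates two independent semi-Markov gaze sequences (infant and adult)
#' over the states partner/puppet/inattentive, at the configured coding frame
#' rate. Dwell times are truncated-normal draws; empirical state occupancy
#' converges to the configured targets as duration grows.
#'
#' @param config a [sim_config()]
#' @return list with elements `infant` and `adult`, each a `gaze_timeline`
#' @examples
#' tl <- generate_gaze_timelines(sim_config(seed = 1, duration = 120))
#' table(tl$infant$states)
#' @export
generate_gaze_timelines <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$duration <= 0) stop("duration must be positive")
  set.seed(config$seed)
  n_frames <- round(config$duration * config$frame_rate)
  out <- lapply(c(infant = "infant", adult = "adult"), function(role) {
    states <- simulate_gaze_sequence(
      n_frames, config$frame_rate,
      config$dwell_mean[[role]], config$dwell_sd[[role]],
      config$dwell_floor, config$occupancy[[role]]
    )
    new_gaze_timeline(role, states, config$frame_rate, config$duration)
  })
  out
}

#' Derive sender gaze-onset events from two timelines
#'
#' A gaze event is a frame at which one partner's state transitions *into*
#' `partner` (a saccade towards the other person). That partner is the
#' event's sender; the event is `mutual` when the other partner is already
#' looking at them at that frame, `nonmutual` otherwise. Both partners
#' shifting in the same frame produce two events, each with its own sender.
#'
#' @param infant,adult `gaze_timeline` objects with equal frame rate/length
#' @return data.frame with columns `onset_s`, `frame` (0-based), `sender`,
#'   `gaze_type`, `receiver_state`
#' @export
derive_gaze_events <- function(infant, adult) {
  stopifnot(inherits(infant, "gaze_timeline"), inherits(adult, "gaze_timeline"))
  if (infant$frame_rate != adult$frame_rate)
    stop("timelines have different frame rates")
  if (length(infant$states) != length(adult$states))
    stop("timelines have different lengths")
  fr <- infant$frame_rate
  one_side <- function(sender_tl, receiver_tl, sender) {
    s <- sender_tl$states
    idx <- which(s == "partner" & c(FALSE, s[-length(s)] != "partner"))
    if (length(idx) == 0) return(NULL)
    rs <- receiver_tl$states[idx]
    data.frame(
      onset_s = (idx - 1) / fr,
      frame = idx - 1L,
      sender = sender,
      gaze_type = ifelse(rs == "partner", "mutual", "nonmutual"),
      receiver_state = rs,
      stringsAsFactors = FALSE
    )
  }
  ev <- rbind(one_side(infant, adult, "infant"),
              one_side(adult, infant, "adult"))
  if (is.null(ev)) {
    ev <- data.frame(onset_s = numeric(0), frame = integer(0),
                     sender = character(0), gaze_type = character(0),
                     receiver_state = character(0), stringsAsFactors = FALSE)
  }
  ev <- ev[order(ev$onset_s, ev$sender), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
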