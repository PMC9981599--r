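#' Write and read a dyad recording as plain text
#'
#' EEG goes to one tab-separated file per partner (one column per channel,
#' header row of labels, values in uV), events to a TSV with columns
#' `onset_s`, `sender`, `gaze_type`, `receiver_state`, gaze timelines to a
#' TSV frame table, and the scalar metadata to JSON.
#'
#' @param dyad a `dyad_recording`
#' @param dir output directory (created if needed)
#' @param name file stem
#' @return invisibly, the files written
#' @export
write_dyad_recording <- function(dyad, dir, name = "dyad") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (role in c("infant", "adult")) {
    f <- file.path(dir, sprintf("%s_%s_eeg.tsv", name, role))
    utils::write.table(t(dyad[[role]]), f, sep = "\t", row.names = FALSE,
                       col.names = dyad$channels, quote = FALSE)
    files <- c(files, f)
  }
  fe <- file.path(dir, sprintf("%s_events.tsv", name))
  utils::write.table(
    dyad$events[, c("onset_s", "sender", "gaze_type", "receiver_state")],
    fe, sep = "\t", row.names = FALSE, quote = FALSE)
  ft <- file.path(dir, sprintf("%s_gaze.tsv", name))
  utils::write.table(
    data.frame(frame = seq_along(dyad$timelines$infant$states) - 1L,
               infant = dyad$timelines$infant$states,
               adult = dyad$timelines$adult$states),
    ft, sep = "\t", row.names = FALSE, quote = FALSE)
  fm <- file.path(dir, sprintf("%s_meta.json", name))
  jsonlite::write_json(list(fs = dyad$fs, duration = dyad$duration,
                            frame_rate = dyad$timelines$infant$frame_rate,
                            channels = dyad$channels),
                       fm, auto_unbox = TRUE, digits = NA)
  invisible(c(files, fe, ft, fm))
}

#' @rdname write_dyad_recording
#' @export
read_dyad_recording <- function(dir, name = "dyad") {
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_meta.json", name)),
                              simplifyVector = TRUE)
  read_eeg <- function(role) {
    m <- t(as.matrix(utils::read.table(
      file.path(dir, sprintf("%s_%s_eeg.tsv", name, role)),
      header = TRUE, sep = "\t", check.names = FALSE)))
    rownames(m) <- meta$channels
    m
  }
  ev <- utils::read.table(file.path(dir, sprintf("%s_events.tsv", name)),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("numeric", "character", "character",
                                         "character"))
  ev$frame <- as.integer(round(ev$onset_s * meta$frame_rate))
  gz <- utils::read.table(file.path(dir, sprintf("%s_gaze.tsv", name)),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  tl <- list(
    infant = new_gaze_timeline("infant", gz$infant, meta$frame_rate,
                               meta$duration),
    adult = new_gaze_timeline("adult", gz$adult, meta$frame_rate,
                              meta$duration)
  )
  structure(list(infant = read_eeg("infant"), adult = read_eeg("adult"),
                 channels = meta$channels, fs = meta$fs,
                 duration = meta$duration, events = ev, timelines = tl),
            class = "dyad_recording")
}
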