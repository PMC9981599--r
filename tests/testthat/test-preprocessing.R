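test_that("band-pass filter meets its frequency-response contract", {
  fs <- 256
  t <- seq(1 / fs, 20, by = 1 / fs)
  mid <- 1000:4000
  gain <- function(f) {
    x <- sin(2 * pi * f * t)
    sd(bandpass_filter(x, fs)[mid]) / sd(x[mid])
  }
  expect_lt(abs(gain(10) - 1), 0.05)            # passband preserved
  expect_lt(20 * log10(gain(0.2)), -20)          # drift strongly attenuated
  expect_lt(20 * log10(gain(40)), -20)           # one octave above band
  # idempotence on in-band content
  x <- sin(2 * pi * 5 * t) + 0.5 * sin(2 * pi * 12 * t)
  once <- bandpass_filter(x, fs)
  expect_equal(bandpass_filter(once, fs)[mid], once[mid], tolerance = 1e-3)
  expect_error(bandpass_filter(x, fs, high = 130), "Nyquist")
})

test_that("robust average reference removes common mode and resists outliers", {
  set.seed(1)
  m <- matrix(rnorm(16 * 500), 16)
  expect_equal(robust_average_reference(m + 100), robust_average_reference(m))
  expect_equal(max(abs(apply(robust_average_reference(m), 2, median))), 0,
               tolerance = 1e-12)
  ident <- matrix(rep(rnorm(500), each = 8), 8, byrow = FALSE)
  expect_equal(max(abs(robust_average_reference(ident))), 0)
  # an extreme channel perturbs the median reference less than a mean one
  m2 <- m
  m2[1, ] <- m2[1, ] * 100
  med_resid <- robust_average_reference(m2)[2, ] - m[2, ]
  mean_resid <- sweep(m2, 2, colMeans(m2))[2, ] - m[2, ]
  expect_lt(sd(med_resid), sd(mean_resid))
  expect_error(robust_average_reference(m[1, , drop = FALSE]))
})

test_that("channel interpolation flags exactly the decorrelated channels", {
  set.seed(2)
  fs <- 128
  base <- sin(2 * pi * 5 * seq(1 / fs, 4, by = 1 / fs))
  eeg <- t(sapply(1:32, function(i) base + rnorm(length(base), 0, 0.1)))
  rownames(eeg) <- biosemi_montage()$label
  expect_equal(interpolate_bad_channels(eeg)$interpolated, character(0))
  bad <- eeg
  bad["Pz", ] <- rnorm(ncol(bad))
  r <- interpolate_bad_channels(bad)
  expect_identical(r$interpolated, "Pz")
  # replacement is an average of neighbours, so it re-correlates with the rest
  expect_gt(cor(r$data["Pz", ], base), 0.9)
  # three constructed bad channels -> exactly three flagged
  bad3 <- eeg
  for (ch in c("F3", "Oz", "T8")) bad3[ch, ] <- rnorm(ncol(bad3))
  expect_setequal(interpolate_bad_channels(bad3)$interpolated,
                  c("F3", "Oz", "T8"))
  # unusable data aborts
  worst <- eeg
  worst[1:20, ] <- matrix(rnorm(20 * ncol(eeg)), 20)
  expect_error(interpolate_bad_channels(worst), "unusable")
})

test_that("high-power rejection applies the 1 s / 70% / 5 SD rule", {
  set.seed(3)
  fs <- 128
  clean <- matrix(rnorm(32 * 60 * fs), 32)
  expect_equal(reject_highpower_segments(clean, fs)$fraction_removed, 0)
  idx <- (10 * fs + 1):(11 * fs)
  hot <- clean
  hot[1:26, idx] <- hot[1:26, idx] * 10   # 81% of channels
  r <- reject_highpower_segments(hot, fs)
  expect_equal(r$rejected_epochs, 11L)
  expect_equal(which(r$mask), idx)
  half <- clean
  half[1:16, idx] <- half[1:16, idx] * 10  # 50% of channels: below the vote
  expect_equal(length(reject_highpower_segments(half, fs)$rejected_epochs), 0)
})

test_that("event epochs use exact index arithmetic on the shared clock", {
  cfg <- sim_config(seed = 1, duration = 20, fs = 512, noise_sd = 1,
                    osc_amps = c(0, 0))
  tl <- generate_gaze_timelines(cfg)
  ev <- data.frame(onset_s = 10, frame = 500L, sender = "infant",
                   gaze_type = "mutual", receiver_state = "partner")
  dy <- synthesize_dyad_eeg(tl, ev, cfg)
  ep <- extract_event_epochs(dy, ev)
  expect_equal(dim(ep$infant$data)[3], 2560L)
  expect_equal(which(abs(ep$infant$times) < 1e-9), 1281L)
  expect_equal(ep$infant$data[1, , ], dy$infant[, 3841:6400],
               ignore_attr = TRUE)
  # sender and receiver epoch sets share trials and time axes
  expect_equal(ep$adult$times, ep$infant$times)
  expect_equal(dim(ep$adult$data), dim(ep$infant$data))
  # zero events is a valid empty object
  ep0 <- extract_event_epochs(dy, ev[0, ])
  expect_equal(dim(ep0$infant$data)[1], 0L)
  # event too close to the edge is dropped and reported
  ev2 <- rbind(ev, data.frame(onset_s = 19, frame = 950L, sender = "adult",
                              gaze_type = "mutual", receiver_state = "partner"))
  ep2 <- extract_event_epochs(dy, ev2)
  expect_equal(nrow(ep2$dropped), 1L)
  expect_equal(ep2$dropped$reason, "edge")
})

test_that("masked samples never reach epochs or segments", {
  cfg <- quick_sim_config(seed = 8, duration = 30)
  dy <- simulate_dyad(cfg)
  fs <- dy$fs
  mask <- rep(FALSE, ncol(dy$infant))
  mask[(10 * fs + 1):(12 * fs)] <- TRUE
  ev <- valid <- dy$events
  ep <- extract_event_epochs(dy, ev, window = c(-1, 1), mask = mask)
  kept <- ep$infant$events$onset_s
  expect_true(all(kept + 1 <= 10 | kept - 1 >= 12))
  segs <- segment_by_gaze_state(dy, mask = mask)
  for (sss in segs) {
    for (seg in sss$segments) {
      expect_false(any(mask[seg$samples[1]:seg$samples[2]]))
    }
  }
})

test_that("gaze-state segmentation recovers hand-built episode structure", {
  fr <- 50
  inf <- make_timeline("infant", list(list("puppet", 4), list("partner", 2),
                                      list("inattentive", 4)))
  ad <- make_timeline("adult", list(list("partner", 6), list("puppet", 4)))
  cfg <- sim_config(seed = 2, duration = 10, fs = 128, noise_sd = 1,
                    osc_amps = c(0, 0))
  ev <- derive_gaze_events(inf, ad)
  dy <- synthesize_dyad_eeg(list(infant = inf, adult = ad), ev, cfg)
  dy$timelines <- list(infant = inf, adult = ad)
  segs <- segment_by_gaze_state(dy)
  expect_equal(segs$mutual$total_s, 2, tolerance = 1 / fr + 1e-9)
  expect_equal(length(segs$mutual$segments), 1L)
  # nonmutual: adult-on-partner alone (0-4 s) = 4 s
  expect_equal(segs$nonmutual$total_s, 4, tolerance = 1 / fr + 1e-9)
  # no partner overlap at all -> empty mutual set
  ad2 <- make_timeline("adult", list(list("puppet", 10)))
  dy$timelines$adult <- ad2
  expect_equal(segment_by_gaze_state(dy)$mutual$total_s, 0)
})

test_that("condition count matching truncates to the smaller set and is idempotent", {
  cfg <- quick_sim_config(seed = 6, duration = 120)
  dy <- simulate_dyad(cfg)
  ep <- extract_event_epochs(dy, window = c(-1, 1))
  inf <- ep$infant
  a <- inf; a$data <- a$data[1:12, , , drop = FALSE]
  a$events <- a$events[1:12, ]
  b <- inf; b$data <- b$data[1:7, , , drop = FALSE]
  b$events <- b$events[1:7, ]
  m <- match_condition_counts(a, b)
  expect_equal(dim(m$a$data)[1], 7L)
  expect_equal(m$a$data[1:7, , ], a$data[1:7, , ])  # first n, original order
  m2 <- match_condition_counts(m$a, m$b)
  expect_equal(m2$a$data, m$a$data)
  # segment sets: sample-count matching within one sample of equality
  segs <- segment_by_gaze_state(dy)
  ms <- match_condition_counts(segs$mutual, segs$nonmutual)
  expect_equal(round(ms$a$total_s * dy$fs), round(ms$b$total_s * dy$fs))
  eq <- match_condition_counts(ms$a, ms$b)
  expect_equal(eq$a$total_s, ms$a$total_s)
})
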