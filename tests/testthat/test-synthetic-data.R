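test_that("gaze timelines match configured dwell and occupancy structure", {
  # 30-minute simulation with the mutual-look dwell statistics
  cfg <- sim_config(seed = 4, duration = 1800, fs = 128,
                    dwell_mean = list(
                      infant = c(partner = 2.7, puppet = 3.9, inattentive = 4.4),
                      adult = c(partner = 5.5, puppet = 2.7, inattentive = 0.62)),
                    dwell_sd = list(
                      infant = c(partner = 0.9, puppet = 1.3, inattentive = 1.5),
                      adult = c(partner = 1.8, puppet = 0.9, inattentive = 0.3)))
  tl <- generate_gaze_timelines(cfg)
  runs <- rle(tl$infant$states)
  partner_dwells <- runs$lengths[runs$values == "partner"] / 50
  # interior looks only (first/last may be truncated by the recording edge)
  expect_lt(abs(mean(partner_dwells) - 2.7) / 2.7, 0.10)

  # occupancy converges towards the default targets (+/- 5 percentage points)
  cfg2 <- sim_config(seed = 11, duration = 1800)
  tl2 <- generate_gaze_timelines(cfg2)
  for (role in c("infant", "adult")) {
    occ <- prop.table(table(factor(tl2[[role]]$states,
                                   c("partner", "puppet", "inattentive"))))
    expect_true(all(abs(occ - cfg2$occupancy[[role]]) < 0.05),
                label = paste(role, "occupancy within 5 points"))
  }
})

test_that("impossible states are never entered and seeds reproduce exactly", {
  cfg <- sim_config(seed = 2, duration = 120,
                    occupancy = list(
                      infant = c(partner = 0, puppet = 0.5, inattentive = 0.5),
                      adult = c(partner = 0.62, puppet = 0.31, inattentive = 0.07)))
  tl <- generate_gaze_timelines(cfg)
  expect_false(any(tl$infant$states == "partner"))
  ev <- derive_gaze_events(tl$infant, tl$adult)
  # the infant never looks at the adult, so no frame has both on partner
  expect_false(any(ev$gaze_type == "mutual" & ev$sender == "adult"))
  expect_equal(sum(ev$sender == "infant"), 0)

  cfg3 <- quick_sim_config(seed = 9)
  expect_identical(generate_gaze_timelines(cfg3),
                   generate_gaze_timelines(cfg3))
  expect_error(generate_gaze_timelines(sim_config(duration = -1)))
})

test_that("gaze events implement the sender/receiver transition rule", {
  # adult on partner from t = 2.0 s; infant shifts puppet -> partner at 3.0 s
  inf <- make_timeline("infant", list(list("puppet", 3), list("partner", 2)))
  ad <- make_timeline("adult", list(list("puppet", 2), list("partner", 3)))
  ev <- derive_gaze_events(inf, ad)
  expect_equal(nrow(ev), 2)  # adult's own shift at 2.0 s is also an event
  infant_ev <- ev[ev$sender == "infant", ]
  expect_equal(infant_ev$onset_s, 3.0)
  expect_equal(infant_ev$gaze_type, "mutual")
  adult_ev <- ev[ev$sender == "adult", ]
  expect_equal(adult_ev$onset_s, 2.0)
  expect_equal(adult_ev$gaze_type, "nonmutual")  # infant still on puppet

  # inattentive -> partner while the other is on puppet: non-mutual
  inf2 <- make_timeline("infant", list(list("inattentive", 2), list("partner", 2)))
  ad2 <- make_timeline("adult", list(list("puppet", 4)))
  ev2 <- derive_gaze_events(inf2, ad2)
  expect_equal(ev2$sender, "infant")
  expect_equal(ev2$gaze_type, "nonmutual")
  expect_equal(ev2$receiver_state, "puppet")

  # no transitions at all -> zero events
  inf3 <- make_timeline("infant", list(list("partner", 3)))
  ad3 <- make_timeline("adult", list(list("partner", 3)))
  expect_equal(nrow(derive_gaze_events(inf3, ad3)), 0)

  expect_error(derive_gaze_events(inf3, make_timeline("adult",
                                                      list(list("partner", 4)))))
})

test_that("gaze events satisfy their invariants on generated timelines", {
  for (seed in 1:5) {
    tl <- generate_gaze_timelines(quick_sim_config(seed))
    ev <- derive_gaze_events(tl$infant, tl$adult)
    expect_true(all(ev$gaze_type == ifelse(ev$receiver_state == "partner",
                                           "mutual", "nonmutual")))
    expect_true(all(ev$onset_s >= 0 & ev$onset_s < tl$infant$duration))
    for (i in seq_len(nrow(ev))) {
      s <- tl[[ev$sender[i]]]$states
      f <- ev$frame[i] + 1L
      expect_identical(s[f], "partner")
      expect_false(s[f - 1L] == "partner")
    }
  }
})

test_that("noise-free synthesis reproduces the ERP template exactly", {
  cfg <- quick_sim_config(seed = 5, noise_sd = 0, osc_amps = c(0, 0),
                          erp_scale = 1)
  dy <- simulate_dyad(cfg)
  ev <- dy$events[dy$events$sender == "infant" &
                    dy$events$onset_s > 1 & dy$events$onset_s < 58, ]
  ep <- extract_event_epochs(dy, ev, window = c(-0.5, 0.8))
  tmpl <- erp_template(cfg, "infant")
  for (ch in occipital_cluster()) {
    avg <- apply(ep$infant$data[, ch, , drop = FALSE], 3, mean)
    post <- which(ep$infant$times >= 0)[seq_len(80)]
    expect_equal(avg[post], tmpl[seq_len(80)], tolerance = 1e-12)
  }
  # receiver's occipital channels carry no response in the sender-only world
  expect_equal(max(abs(ep$adult$data)), 0)
})

test_that("full phase reset yields near-perfect post-onset ITC at 4 Hz", {
  cfg <- quick_sim_config(seed = 7, duration = 120, noise_sd = 0,
                          osc_freqs = 4, osc_amps = 4, osc_drift_sd = 0.8,
                          reset_strength = 1)
  dy <- simulate_dyad(cfg)
  ons <- dy$events$onset_s[dy$events$sender == "infant"]
  ons <- ons[ons > 3 & ons < 117]
  occ <- colMeans(dy$infant[occipital_cluster(), ])
  tf <- morlet_decompose(occ, dy$fs)
  ph <- tf_phase(tf)
  L <- round(5 * dy$fs)
  starts <- round(ons * dy$fs) - round(2.5 * dy$fs)
  phs <- array(0, c(length(ons), length(tf$freqs), L))
  for (k in seq_along(ons)) phs[k, , ] <- ph[, (starts[k] + 1):(starts[k] + L)]
  it <- itc(phs)
  tt <- -2.5 + (seq_len(L) - 1) / dy$fs
  f4 <- which(tf$freqs == 4)
  expect_gt(mean(it[f4, tt > 0.1 & tt < 0.3]), 0.9)
  expect_lt(mean(it[f4, tt > -1.5 & tt < -0.5]), 0.55)
})

test_that("synthesis is seed-deterministic and validates events", {
  cfg <- quick_sim_config(seed = 3, duration = 20)
  expect_identical(simulate_dyad(cfg), simulate_dyad(cfg))
  tl <- generate_gaze_timelines(cfg)
  bad <- data.frame(onset_s = 25, frame = 1250L, sender = "infant",
                    gaze_type = "mutual", receiver_state = "partner")
  expect_error(synthesize_dyad_eeg(tl, bad, cfg), "outside")
})

test_that("recordings round-trip through the plain-text interchange format", {
  cfg <- quick_sim_config(seed = 13, duration = 20)
  dy <- simulate_dyad(cfg)
  dir <- withr::local_tempdir()
  write_dyad_recording(dy, dir, "t")
  dy2 <- read_dyad_recording(dir, "t")
  expect_equal(dy2$infant, dy$infant, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(dy2$events$onset_s, dy$events$onset_s)
  expect_identical(dy2$timelines$adult$states, dy$timelines$adult$states)
  cf <- file.path(dir, "cfg.json")
  write_sim_config(cfg, cf)
  cfg2 <- read_sim_config(cf)
  expect_equal(cfg2$dwell_mean, cfg$dwell_mean)
  expect_equal(cfg2$osc_freqs, cfg$osc_freqs)
})
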