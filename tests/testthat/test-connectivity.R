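test_that("PLV matches direct evaluation of its defining formula", {
  # frozen hand computation: |2 + 2i| / 4
  expect_equal(plv_windowed(c(0, pi / 2, 0, pi / 2), rep(0, 4),
                            fs = 4, window = 1)$mean,
               sqrt(2) / 2, tolerance = 1e-12)
  # brute-force oracle agreement on tiny random inputs
  set.seed(10)
  for (r in 1:20) {
    n <- sample(4:10, 1)
    phi <- runif(n, -pi, pi)
    psi <- runif(n, -pi, pi)
    expect_equal(plv_windowed(phi, psi, fs = n, window = 1)$mean,
                 plv_brute(phi, psi), tolerance = 1e-12)
  }
  # constant lag -> perfect locking in every window
  fs <- 128
  ph <- 2 * pi * 5 * seq_len(512) / fs
  out <- plv_windowed(ph, ph - 1.1, fs)
  expect_equal(out$per_window, rep(1, 4), tolerance = 1e-12)
  # independent uniform phases, T = 512: near zero
  set.seed(11)
  null_plv <- replicate(100, plv_windowed(runif(512, -pi, pi),
                                          runif(512, -pi, pi),
                                          fs = 512, window = 1)$mean)
  expect_lt(mean(null_plv), 0.1)
  expect_error(plv_windowed(1:3, 1:3, fs = 128, window = 1), "window")
})

test_that("ITC matches its defining formula and detects cancellation", {
  expect_equal(itc(matrix(c(0, pi / 2, pi), 3, 1))[1], 1 / 3,
               tolerance = 1e-12)
  set.seed(12)
  for (r in 1:20) {
    n <- sample(2:10, 1)
    ph <- runif(n, -pi, pi)
    expect_equal(itc(matrix(ph, n, 1))[1], itc_brute(ph), tolerance = 1e-12)
  }
  expect_equal(itc(matrix(0.7, 5, 8)), rep(1, 8))
  expect_equal(itc(matrix(c(0.3, 0.3 + pi), 2, 4)), rep(0, 4),
               tolerance = 1e-12)
  expect_error(itc(matrix(0, 1, 4)), "trials")
  # array form: trials x freq x time
  arr <- array(runif(3 * 2 * 5, -pi, pi), c(3, 2, 5))
  direct <- itc(arr)
  expect_equal(direct[2, 4], itc_brute(arr[, 2, 4]), tolerance = 1e-12)
})

test_that("PLV and ITC depend on phase only (amplitude invariance)", {
  fs <- 128
  set.seed(13)
  x <- rnorm(512); y <- rnorm(512)
  px <- tf_phase(morlet_decompose(x, fs))
  px_scaled <- tf_phase(morlet_decompose(20 * x, fs))
  expect_equal(px, px_scaled, tolerance = 1e-9)
  py <- tf_phase(morlet_decompose(y, fs))
  expect_equal(plv_windowed(px, py, fs)$mean,
               plv_windowed(px_scaled, py, fs)$mean, tolerance = 1e-9)
})

test_that("PDC reproduces the closed form and is column normalised", {
  A <- array(c(0.5, 0.4, 0, 0.5), c(2, 2, 1))  # x drives y, gain 0.4
  pd0 <- pdc_from_var(A, 0, 512)
  expect_equal(pd0[2, 1, 1], 0.4 / sqrt(0.41), tolerance = 1e-12)
  expect_equal(pd0[1, 2, 1], 0)
  # agreement with an independently coded evaluation across frequencies
  A2 <- var5_truth()
  for (f in c(0, 3, 7.5, 18)) {
    expect_equal(pdc_from_var(A2, f, 128)[, , 1], pdc_brute(A2, f, 128),
                 tolerance = 1e-12)
  }
  # sum of squared PDC over targets = 1 for every source and frequency
  pd <- pdc_from_var(A2, 2:18, 128)
  for (j in 1:2) {
    expect_equal(colSums(pd[, j, ]^2), rep(1, 17), tolerance = 1e-12)
  }
})

test_that("estimated PDC converges to the generating model's PDC", {
  A <- array(c(0.5, 0.4, 0, 0.5), c(2, 2, 1))
  set.seed(14)
  xy <- simulate_var(A, 1e4)
  fit <- fit_var(xy, 1)
  expect_lt(abs(pdc_from_var(fit, 0, 512)[2, 1, 1] - 0.4 / sqrt(0.41)), 0.05)
  expect_lt(pdc_from_var(fit, 0, 512)[1, 2, 1], 0.1)
  # estimation error shrinks with sample size (consistency)
  err_at <- function(T, reps = 20) {
    mean(replicate(reps, {
      fit <- fit_var(simulate_var(A, T), 1)
      abs(pdc_from_var(fit, 0, 512)[2, 1, 1] - 0.4 / sqrt(0.41))
    }))
  }
  set.seed(15)
  expect_lt(err_at(4000), err_at(1000))
})

test_that("windowed and event-locked estimators have the contracted shapes", {
  set.seed(16)
  A <- var5_truth()
  xy <- simulate_var(A, 2560)
  pw <- pdc_windowed(xy[, 1], xy[, 2], fs = 256, order = 5, freqs = 2:18)
  expect_length(pw$x_to_y, 17)
  expect_true(all(pw$x_to_y >= 0 & pw$x_to_y <= 1))
  expect_true(all(pw$y_to_x >= 0 & pw$y_to_x <= 1))

  ph_x <- array(runif(8 * 3 * 40, -pi, pi), c(8, 3, 40))
  ph_y <- array(runif(8 * 3 * 40, -pi, pi), c(8, 3, 40))
  m <- event_locked_plv(ph_x, ph_y)
  expect_equal(dim(m), c(3, 40))
  expect_true(all(m >= 0 & m <= 1))
  # identical phase difference across trials -> map of ones
  ph_y2 <- ph_x - 0.4
  expect_equal(event_locked_plv(ph_x, ph_y2), matrix(1, 3, 40),
               tolerance = 1e-12)

  fs <- 128
  tr <- lapply(1:6, function(k) simulate_var(A, 5 * fs))
  xe <- t(sapply(tr, function(m) m[, 1]))
  ye <- t(sapply(tr, function(m) m[, 2]))
  times <- -2.5 + (seq_len(5 * fs) - 1) / fs
  em <- event_locked_pdc(xe, ye, times, fs, order = 5, freqs = 2:18,
                         window = 1, step = 0.25)
  expect_equal(dim(em$x_to_y), c(17, length(em$times)))
  expect_true(all(em$x_to_y >= 0 & em$x_to_y <= 1, na.rm = TRUE))
  # the driven direction dominates in the pooled event-locked fit too
  expect_gt(mean(em$x_to_y, na.rm = TRUE), mean(em$y_to_x, na.rm = TRUE))
})

test_that("BIC order selection recovers the truth and penalises white noise", {
  A <- var5_truth()
  set.seed(17)
  sel <- replicate(10, {
    xy <- simulate_var(A, 5000)
    as.integer(select_var_order_bic(xy[, 1], xy[, 2], 10))
  })
  expect_gte(sum(sel == 5), 9)
  seln <- replicate(10, {
    as.integer(select_var_order_bic(rnorm(2000), rnorm(2000), 6))
  })
  expect_gt(mean(seln == 1), 0.5)
  # per-segment orders are averaged then rounded
  set.seed(18)
  segs <- lapply(1:4, function(k) simulate_var(A, 3000))
  expect_equal(as.integer(select_var_order_bic(segs, max_order = 8)), 5L)
})

test_that("VAR fitting is stable-aware and rejects degenerate input", {
  A <- var5_truth()
  expect_true(var_is_stable(A))
  unstable <- array(c(1.2, 0, 0, 1.2), c(2, 2, 1))
  expect_false(var_is_stable(unstable))
  const <- cbind(rep(1, 100), rep(1, 100))
  expect_error(fit_var(const, 2), "ill-conditioned|short")
})
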