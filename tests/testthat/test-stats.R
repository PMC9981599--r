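test_that("z-score p-values match the Gaussian tail", {
  null <- rnorm(1000)
  null <- (null - mean(null)) / sd(null)  # exactly standardised
  expect_equal(zscore_pvalue(0, null)$p, 0.5, tolerance = 1e-12)
  expect_equal(zscore_pvalue(1.6449, null)$p, 0.05, tolerance = 1e-4)
  expect_equal(zscore_pvalue(-1, null)$p, 0.8413447, tolerance = 1e-6)
  expect_equal(zscore_pvalue(1.6449, null, n_comparisons = 12)$p_adjusted,
               0.6, tolerance = 1e-3)
  # monotone decreasing in the observed value
  ps <- vapply(seq(-2, 2, by = 0.5), function(o) zscore_pvalue(o, null)$p,
               numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(zscore_pvalue(1, rep(3, 100)), "degenerate")
})

test_that("dyad-pairing surrogates are derangements and exchangeable", {
  set.seed(20)
  mm <- matrix(rnorm(400, 5), 20, 20)
  sn <- surrogate_dyad_null(mm, n_perm = 500, seed = 1)
  expect_equal(sn$observed, mean(diag(mm)))
  # exchangeable entries: null centres near the observed's expectation
  expect_lt(abs(sn$null_mean - mean(mm[row(mm) != col(mm)])), 0.05)
  expect_identical(surrogate_dyad_null(mm, n_perm = 200, seed = 7)$null,
                   surrogate_dyad_null(mm, n_perm = 200, seed = 7)$null)
  expect_error(surrogate_dyad_null(matrix(1, 1, 1)), "2 dyads")
  # derangement helper never returns a fixed point
  for (r in 1:50) expect_false(any(gazesync:::derangement(6) == 1:6))
})

test_that("surrogate event onsets respect edges and masks", {
  fs <- 128
  ons <- surrogate_event_onsets(10, duration = 60, fs = fs,
                                window = c(-2.5, 2.5), n_perm = 50)
  expect_equal(dim(ons), c(50, 10))
  expect_true(all(ons >= 2.5 & ons <= 57.5))
  mask <- rep(FALSE, 60 * fs)
  mask[(20 * fs):(30 * fs)] <- TRUE
  ons2 <- surrogate_event_onsets(5, 60, fs, c(-1, 1), mask, n_perm = 20)
  for (o in as.vector(ons2)) {
    expect_false(any(mask[(round(o * fs) - fs + 1):(round(o * fs) + fs)]))
  }
  expect_error(surrogate_event_onsets(3, 4, fs, c(-2.5, 2.5), n_perm = 5),
               "short")
})

test_that("random-event nulls flag event-locked structure only when present", {
  set.seed(21)
  fs <- 128
  dur <- 120
  # signal with deterministic bumps at known events
  events <- seq(10, 110, by = 5)
  sig <- rnorm(dur * fs)
  for (e in events) {
    idx <- round(e * fs) + seq_len(round(0.3 * fs))
    sig[idx] <- sig[idx] + 3
  }
  stat_fn <- function(onsets) {
    mean(vapply(onsets, function(o)
      mean(sig[round(o * fs) + seq_len(round(0.3 * fs))]), numeric(1)))
  }
  sn <- surrogate_event_null(stat_fn, length(events), dur, fs,
                             window = c(-1, 1), n_perm = 300,
                             observed = stat_fn(events), seed = 2)
  expect_gt(zscore_pvalue(sn$observed, sn)$z, 3)
  # the same machinery on structure-free data sits inside its null
  sig <- rnorm(dur * fs)
  sn0 <- surrogate_event_null(stat_fn, length(events), dur, fs,
                              window = c(-1, 1), n_perm = 300,
                              observed = stat_fn(events), seed = 3)
  expect_lt(abs(zscore_pvalue(sn0$observed, sn0)$z), 3)
})

test_that("cluster permutation finds injected effects and respects exchangeability", {
  set.seed(22)
  # paired mode: strong contiguous effect in a 17 x 20 grid
  n <- 12
  a <- array(rnorm(n * 17 * 20), c(n, 17, 20))
  b <- array(rnorm(n * 17 * 20), c(n, 17, 20))
  a[, 5:7, 8:11] <- a[, 5:7, 8:11] + 2.5
  cr <- cluster_permutation_test(cond_a = a, cond_b = b, n_perm = 500,
                                 seed = 5)
  expect_true(has_significant_cluster(cr, 0.05))
  top <- cr$clusters[[1]]
  expect_lt(top$p, 0.01)
  expect_true(all(top$members[, 1] %in% 3:9))  # found near the injection
  expect_gt(top$mass, 0)
  # clusters are 4-connected components of the thresholded map
  lab <- gazesync:::cluster_label_cpp(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  expect_equal(attr(lab, "n_clusters"), 2L)  # diagonal cells do not connect
  lab2 <- gazesync:::cluster_label_cpp(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  expect_equal(attr(lab2, "n_clusters"), 1L)  # joined through the shared edge

  # baseline mode: observed identical to every permutation map -> nothing
  om <- matrix(1, 10, 10)
  nm <- array(1, c(10, 10, 250))
  cr0 <- cluster_permutation_test(observed = om, null_maps = nm)
  expect_length(cr0$clusters, 0)

  # baseline mode detects an elevated patch
  nm2 <- array(rnorm(10 * 10 * 250, 0.5, 0.1), c(10, 10, 250))
  om2 <- matrix(0.5, 10, 10)
  om2[3:5, 3:6] <- 0.9
  cr1 <- cluster_permutation_test(observed = om2, null_maps = nm2,
                                  alpha = 0.025)
  expect_true(has_significant_cluster(cr1))
  expect_error(cluster_permutation_test(observed = om2,
                                        null_maps = nm2[, , 1:100]),
               "200")
})

test_that("cluster permutation controls the family-wise error rate", {
  set.seed(23)
  nsim <- 150
  rej <- logical(nsim)
  for (s in seq_len(nsim)) {
    D <- array(rnorm(10 * 17 * 20), c(10, 17, 20))
    rej[s] <- has_significant_cluster(
      cluster_permutation_test(cond_a = D, n_perm = 250), 0.05)
  }
  expect_lte(mean(rej), 0.10)  # liberal bound for the quick in-suite check
})

test_that("2x2 repeated-measures ANOVA matches the paired-t identity", {
  set.seed(24)
  n <- 16
  d <- expand.grid(subject = 1:n, f1 = c("a1", "a2"), f2 = c("b1", "b2"))
  d$value <- rnorm(nrow(d)) + ifelse(d$f2 == "b1", 1, 0)  # band effect only
  res <- rm_anova_2x2(d, factor_names = c("gaze", "band"))
  # F for each 1-df effect equals the squared paired t of its contrast
  cells <- with(d, tapply(value, list(subject, f1, f2), mean))
  gz <- (cells[, 1, 1] + cells[, 1, 2] - cells[, 2, 1] - cells[, 2, 2]) / 2
  tt <- mean(gz) / (sd(gz) / sqrt(n))
  expect_equal(res$effects$F[res$effects$effect == "gaze"], tt^2,
               tolerance = 1e-10)
  expect_equal(res$effects$df1, rep(1, 3))
  expect_equal(res$effects$df2, rep(n - 1, 3))
  expect_lt(res$effects$p[res$effects$effect == "band"], 0.01)
  expect_gt(res$effects$p[res$effects$effect == "gaze"], 0.05)
  # identical conditions -> F = 0, p = 1 for every effect
  d2 <- d
  d2$value <- rep(rnorm(n), 4)
  res2 <- rm_anova_2x2(d2)
  expect_equal(res2$effects$F, rep(0, 3))
  expect_equal(res2$effects$p, rep(1, 3))
  # Tukey-Kramer: 6 pairwise comparisons, adjusted p in [0, 1]
  expect_equal(nrow(res$tukey), 6)
  expect_true(all(res$tukey$p_adj >= 0 & res$tukey$p_adj <= 1))
  expect_gt(min(res$tukey$p_adj), min(2 * pnorm(-abs(res$tukey$t))) - 1e-9)
  expect_error(rm_anova_2x2(d[d$subject > 2 | d$f1 == "a1", ]), "missing|cells")
})

test_that("JZS Bayes factors behave like a default Bayesian t test", {
  set.seed(25)
  x <- rnorm(30)
  bf0 <- jzs_bayes_factor_paired(x - mean(x))  # t exactly 0
  expect_lt(bf0$BF10, 1)
  expect_equal(bf0$BF01, 1 / bf0$BF10)
  # strictly increasing in |t| at fixed n
  bfs <- vapply(c(0, 0.5, 1, 2, 3, 5), function(tv) {
    d <- rnorm(20)
    d <- d - mean(d) + tv * sd(d) / sqrt(20)  # forces t = tv
    jzs_bayes_factor_paired(d)$BF10
  }, numeric(1))
  expect_true(all(diff(bfs) > 0))
  # large effect -> strong evidence
  expect_gt(jzs_bayes_factor_paired(rnorm(30, 1.5, 1))$BF10, 100)
  expect_error(jzs_bayes_factor_paired(rep(1, 10), rep(0, 10)), "variance")
})

test_that("power calculation reproduces the noncentral-t behaviour", {
  expect_gt(power_from_r2(0.332, 55, 0.05), 0.99)
  # r^2 -> 0 approaches the significance level
  expect_equal(power_from_r2(1e-8, 55, 0.05), 0.05, tolerance = 1e-3)
  # strictly increasing in n
  pw <- vapply(c(5, 10, 20, 40, 80), function(n)
    power_from_r2(0.1, n, 0.05), numeric(1))
  expect_true(all(diff(pw) > 0))
  expect_error(power_from_r2(1.2, 10), "r_squared")
})
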