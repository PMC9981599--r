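#' One-sided p-value from a z-scored position on a Gaussian
#'
#' `z = (observed - mean(null)) / sd(null)`; upper-tail
#' `p = 1 - Phi(z)`. A Bonferroni helper multiplies by the number of planned
#' comparisons.
#'
#' @param observed observed statistic
#' @param null numeric vector of null samples (or a `surrogate_null`)
#' @param n_comparisons Bonferroni comparison count
#' @return list with `z`, `p`, `p_adjusted`
#' @export
zscore_pvalue <- function(observed, null, n_comparisons = 1) {
  if (inherits(null, "surrogate_null")) null <- null$null
  mu <- mean(null)
  sdv <- stats::sd(null)
  if (!is.finite(sdv) || sdv <= 0) stop("degenerate null distribution")
  z <- (observed - mu) / sdv
  p <- stats::pnorm(z, lower.tail = FALSE)
  list(z = z, p = p, p_adjusted = min(1, p * n_comparisons))
}

new_surrogate_null <- function(observed, null, statistic, n_perm) {
  structure(list(observed = observed, null = null, statistic = statistic,
                 n_perm = n_perm, null_mean = mean(null),
                 null_sd = stats::sd(null)),
            class = "surrogate_null")
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat("<surrogate_null>", x$statistic, ": observed",
      signif(x$observed, 4), "vs null", signif(x$null_mean, 4), "+/-",
      signif(x$null_sd, 4), sprintf("(%d permutations)\n", x$n_perm))
  invisible(x)
}

#' Surrogate null from random infant-adult re-pairings
#'
#' Under the null hypothesis that inter-brain synchrony arises from the
#' real-time interaction, randomly re-paired (non-partner) infants and adults
#' should show the same group-mean synchrony. Each permutation samples a
#' derangement (no infant keeps its own partner) and averages the metric over
#' the surrogate pairs.
#'
#' @param metric_matrix `n x n` matrix: entry (i, j) is the metric for infant
#'   i paired with adult j; the diagonal holds the real pairs
#' @param n_perm number of random pairings (default 1000)
#' @param seed optional RNG seed
#' @return a `surrogate_null` with `observed = mean(diag)`
#' @export
surrogate_dyad_null <- function(metric_matrix, n_perm = 1000, seed = NULL) {
  n <- nrow(metric_matrix)
  if (is.null(n) || n < 2 || n != ncol(metric_matrix))
    stop("need a square metric matrix for at least 2 dyads")
  if (!is.null(seed)) set.seed(seed)
  observed <- mean(diag(metric_matrix))
  null <- vapply(seq_len(n_perm), function(b) {
    p <- derangement(n)
    mean(metric_matrix[cbind(seq_len(n), p)])
  }, numeric(1))
  new_surrogate_null(observed, null, "dyad-pairing", n_perm)
}

#' Random surrogate event onsets
#'
#' Draws pseudo-event onset times uniformly over the part of the recording
#' where a full peri-event epoch fits (edge-safe) and, if a rejection mask is
#' supplied, where the epoch overlaps no masked sample. One row per
#' permutation; the event count is matched to the real events.
#'
#' @param n_events events per permutation
#' @param duration recording length (s)
#' @param fs sampling rate (Hz)
#' @param window peri-event window c(start, end) (s)
#' @param mask optional logical sample mask (TRUE = rejected)
#' @param n_perm number of permutations
#' @return `n_perm x n_events` matrix of onset times (s)
#' @export
surrogate_event_onsets <- function(n_events, duration, fs,
                                   window = c(-2.5, 2.5), mask = NULL,
                                   n_perm = 1000) {
  lo <- -window[1]
  hi <- duration - window[2]
  if (hi <= lo) stop("recording too short to place surrogate events")
  ok <- function(on) {
    if (is.null(mask)) return(rep(TRUE, length(on)))
    L <- round((window[2] - window[1]) * fs)
    starts <- round(on * fs) + round(window[1] * fs)
    vapply(starts, function(s) !any(mask[(s + 1L):(s + L)]), logical(1))
  }
  out <- matrix(0, n_perm, n_events)
  for (b in seq_len(n_perm)) {
    got <- numeric(0)
    tries <- 0L
    while (length(got) < n_events) {
      cand <- stats::runif(n_events, lo, hi)
      cand <- cand[ok(cand)]
      got <- c(got, cand)
      tries <- tries + 1L
      if (tries > 100L) stop("insufficient valid span for surrogate events")
    }
    out[b, ] <- got[seq_len(n_events)]
  }
  out
}

#' Surrogate null from randomly inserted events
#'
#' Evaluates `analysis_fn` on epochs time-locked to random onsets, matched in
#' number to the real events.
#'
#' @param analysis_fn function(onsets) -> scalar statistic
#' @param n_events real event count to match
#' @param duration,fs,window,mask see [surrogate_event_onsets()]
#' @param n_perm permutations
#' @param observed optional observed statistic to store
#' @param seed optional RNG seed
#' @return a `surrogate_null`
#' @export
surrogate_event_null <- function(analysis_fn, n_events, duration, fs,
                                 window = c(-2.5, 2.5), mask = NULL,
                                 n_perm = 1000, observed = NA_real_,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ons <- surrogate_event_onsets(n_events, duration, fs, window, mask, n_perm)
  null <- vapply(seq_len(n_perm), function(b) analysis_fn(ons[b, ]),
                 numeric(1))
  new_surrogate_null(observed, null, "random-events", n_perm)
}

# observed cluster extraction on a stat map given a mask
extract_clusters <- function(stat, mask) {
  nf <- nrow(stat); nt <- ncol(stat)
  labels <- cluster_label_cpp(as.logical(mask), nf, nt)
  nclust <- attr(labels, "n_clusters")
  labels <- matrix(labels, nf, nt)
  out <- list()
  for (k in seq_len(nclust)) {
    members <- which(labels == k, arr.ind = TRUE)
    out[[k]] <- list(members = members, mass = sum(stat[labels == k]))
  }
  out
}

#' Cluster-based permutation test on (frequency, time) maps
#'
#' Two modes share the cluster machinery (4-connected components scored by
#' mass, family-wise correction via the permutation distribution of the
#' maximum cluster mass):
#'
#' * **baseline mode** (`observed` + `null_maps`): the observed group map is
#'   z-scored pointwise against the permutation maps, thresholded one-sided
#'   at `forming_alpha`, and observed cluster masses are compared with the
#'   maximum cluster mass of each z-scored permutation map. Used for
#'   synchrony-above-surrogate tests, which have a directional alternative.
#' * **paired mode** (`cond_a` + `cond_b`, `subject x freq x time`): a paired
#'   t map is thresholded two-sided at `forming_alpha` and sign-flip
#'   permutations of the subject difference maps build the max-mass null.
#'   `cond_b = 0` gives a one-sample test against zero.
#'
#' @param observed `freq x time` matrix (baseline mode)
#' @param null_maps `freq x time x n_perm` array (baseline mode)
#' @param cond_a,cond_b `subject x freq x time` arrays (paired mode);
#'   `cond_b` may be the scalar 0
#' @param forming_alpha cluster-forming threshold (pointwise alpha)
#' @param alpha family-wise significance level for the corrected cluster p
#' @param n_perm sign-flip permutations (paired mode)
#' @param seed optional RNG seed (paired mode)
#' @return a `cluster_result`: list of clusters (members, mass, corrected p),
#'   the pointwise statistic map, threshold, and `max_null` distribution
#' @export
cluster_permutation_test <- function(observed = NULL, null_maps = NULL,
                                     cond_a = NULL, cond_b = NULL,
                                     forming_alpha = 0.05, alpha = 0.05,
                                     n_perm = 1000, seed = NULL) {
  if (!is.null(observed) && !is.null(null_maps)) {
    B <- dim(null_maps)[3]
    if (B < 200) stop("need at least 200 permutation maps")
    mu <- rowMeans(null_maps, dims = 2)
    sdv <- sqrt(pmax(0, (rowSums(null_maps^2, dims = 2) - B * mu^2) /
                         (B - 1)))
    sdv[sdv <= 0 | !is.finite(sdv)] <- Inf
    z <- (observed - mu) / sdv
    thr <- stats::qnorm(1 - forming_alpha)
    clusters <- extract_clusters(z, z > thr)
    nf <- nrow(z); nt <- ncol(z)
    Zperm <- t((matrix(null_maps, nf * nt, B) - as.vector(mu)) /
                 as.vector(sdv))
    max_null <- max_cluster_masses_cpp(Zperm, nf, nt, thr, FALSE)
    stat_map <- z
    two_sided <- FALSE
  } else if (!is.null(cond_a)) {
    if (is.null(cond_b) || identical(cond_b, 0)) {
      D <- cond_a
    } else {
      stopifnot(all(dim(cond_a) == dim(cond_b)))
      D <- cond_a - cond_b
    }
    n <- dim(D)[1]
    if (n < 3) stop("paired cluster test needs at least 3 subjects")
    if (n_perm < 200) stop("need at least 200 permutations")
    nf <- dim(D)[2]; nt <- dim(D)[3]
    Dm <- matrix(D, n, nf * nt)
    ssq <- colSums(Dm^2)
    m <- colMeans(Dm)
    vr <- pmax(0, (ssq - n * m^2) / (n - 1))
    se <- sqrt(vr / n)
    se[se == 0] <- Inf
    tmap <- matrix(m / se, nf, nt)
    thr <- stats::qt(1 - forming_alpha / 2, n - 1)
    clusters <- c(extract_clusters(tmap, tmap > thr),
                  lapply(extract_clusters(-tmap, -tmap > thr), function(cl) {
                    cl$mass <- -cl$mass
                    cl
                  }))
    if (!is.null(seed)) set.seed(seed)
    S <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    Mp <- crossprod(S, Dm) / n
    VRp <- sweep(-n * Mp^2, 2, ssq, "+") / (n - 1)
    SEp <- sqrt(pmax(VRp, 0) / n)
    SEp[SEp == 0] <- Inf
    Tp <- Mp / SEp
    max_null <- max_cluster_masses_cpp(Tp, nf, nt, thr, TRUE)
    stat_map <- tmap
    two_sided <- TRUE
  } else {
    stop("supply observed+null_maps or cond_a (+cond_b)")
  }
  B <- length(max_null)
  for (k in seq_along(clusters)) {
    clusters[[k]]$p <- (1 + sum(max_null >= abs(clusters[[k]]$mass))) / (B + 1)
  }
  if (length(clusters) > 0) {
    clusters <- clusters[order(vapply(clusters, function(cl) cl$p, 1))]
  }
  structure(list(clusters = clusters, stat_map = stat_map,
                 forming_threshold = thr, alpha = alpha,
                 max_null = max_null, two_sided = two_sided),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  sig <- sum(vapply(x$clusters, function(cl) cl$p <= x$alpha, logical(1)))
  cat("<cluster_result>", length(x$clusters), "clusters,", sig,
      "significant at alpha", x$alpha, "\n")
  invisible(x)
}

#' Any significant cluster?
#'
#' @param x a `cluster_result`
#' @param alpha significance level (default: the one stored)
#' @return logical
#' @export
has_significant_cluster <- function(x, alpha = x$alpha) {
  any(vapply(x$clusters, function(cl) cl$p <= alpha, logical(1)))
}

#' Two-way repeated-measures ANOVA (2 x 2) with Tukey-Kramer pairwise tests
#'
#' Within-subject decomposition for two two-level factors: each 1-df effect's
#' F(1, n-1) equals the squared paired t of its difference contrast. Pairwise
#' cell comparisons are adjusted with the studentized-range (Tukey-Kramer)
#' correction over the four cells.
#'
#' @param data data.frame with columns `subject`, `f1`, `f2`, `value`; both
#'   factors must have exactly two levels and the table must be complete
#' @param factor_names optional names for the two factors in the output
#' @return list with `effects` (data.frame: effect, F, df1, df2, p),
#'   `tukey` (pairwise cell comparisons with adjusted p), `n`
#' @export
rm_anova_2x2 <- function(data, factor_names = c("f1", "f2")) {
  stopifnot(all(c("subject", "f1", "f2", "value") %in% names(data)))
  l1 <- sort(unique(data$f1)); l2 <- sort(unique(data$f2))
  if (length(l1) != 2 || length(l2) != 2)
    stop("both factors must have exactly 2 levels")
  cells <- with(data, tapply(value, list(subject, f1, f2), mean))
  if (anyNA(cells)) stop("missing cells in the within-subject table")
  n <- dim(cells)[1]
  if (n < 3) stop("need at least 3 subjects")
  contrast_f <- function(d) {
    if (stats::sd(d) == 0) {
      # degenerate contrast: identical conditions give a zero effect
      return(c(F = 0, p = 1))
    }
    tt <- mean(d) / (stats::sd(d) / sqrt(n))
    Fv <- tt^2
    c(F = Fv, p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE))
  }
  c_f1 <- (cells[, 1, 1] + cells[, 1, 2] - cells[, 2, 1] - cells[, 2, 2]) / 2
  c_f2 <- (cells[, 1, 1] + cells[, 2, 1] - cells[, 1, 2] - cells[, 2, 2]) / 2
  c_int <- (cells[, 1, 1] - cells[, 2, 1]) - (cells[, 1, 2] - cells[, 2, 2])
  eff <- rbind(contrast_f(c_f1), contrast_f(c_f2), contrast_f(c_int))
  effects <- data.frame(
    effect = c(factor_names[1], factor_names[2],
               paste(factor_names, collapse = ":")),
    F = eff[, "F"], df1 = 1, df2 = n - 1, p = eff[, "p"],
    row.names = NULL
  )
  cell_names <- c(paste(l1[1], l2[1], sep = "."), paste(l1[2], l2[1], sep = "."),
                  paste(l1[1], l2[2], sep = "."), paste(l1[2], l2[2], sep = "."))
  cmat <- cbind(cells[, 1, 1], cells[, 2, 1], cells[, 1, 2], cells[, 2, 2])
  pairs <- utils::combn(4, 2)
  tukey <- data.frame(pair = character(0), diff = numeric(0), t = numeric(0),
                      p_adj = numeric(0))
  for (j in seq_len(ncol(pairs))) {
    d <- cmat[, pairs[1, j]] - cmat[, pairs[2, j]]
    tt <- mean(d) / (stats::sd(d) / sqrt(n))
    p_adj <- stats::ptukey(abs(tt) * sqrt(2), 4, n - 1, lower.tail = FALSE)
    tukey <- rbind(tukey, data.frame(
      pair = paste(cell_names[pairs[1, j]], "-", cell_names[pairs[2, j]]),
      diff = mean(d), t = tt, p_adj = p_adj
    ))
  }
  list(effects = effects, tukey = tukey, n = n)
}

#' JZS Bayes factor for a paired (or one-sample) t contrast
#'
#' Default-prior Bayes factor: Cauchy(0, `rscale`) prior on the standardised
#' effect, integrated numerically against the noncentral-t likelihood of the
#' observed t statistic. `BF10` quantifies evidence for a nonzero effect,
#' `BF01 = 1/BF10` for its absence.
#'
#' @param x first sample (or difference scores if `y` is NULL)
#' @param y optional second (paired) sample
#' @param rscale Cauchy prior scale (default sqrt(2)/2)
#' @return list with `BF10`, `BF01`, `t`, `n`
#' @export
jzs_bayes_factor_paired <- function(x, y = NULL, rscale = sqrt(2) / 2) {
  d <- if (is.null(y)) x else x - y
  n <- length(d)
  stopifnot(n >= 2)
  sdd <- stats::sd(d)
  if (sdd == 0) stop("zero variance of differences")
  tval <- mean(d) / (sdd / sqrt(n))
  nu <- n - 1
  # dt(ncp=) emits spurious full-precision warnings far in the tails
  like_alt <- suppressWarnings(stats::integrate(function(delta) {
    stats::dt(tval, nu, ncp = delta * sqrt(n)) *
      stats::dcauchy(delta, 0, rscale)
  }, -Inf, Inf, rel.tol = 1e-8)$value)
  like_null <- stats::dt(tval, nu)
  bf10 <- like_alt / like_null
  list(BF10 = bf10, BF01 = 1 / bf10, t = tval, n = n)
}

#' Achieved power of a matched-pairs t test from an r-squared effect size
#'
#' Converts r^2 to `r`, then to Cohen's d = 2r / sqrt(1 - r^2), and evaluates
#' the power of a two-sided paired t test with `n` pairs at level `alpha`
#' via the noncentral t distribution (noncentrality d * sqrt(n)).
#'
#' @param r_squared squared correlation effect size, in (0, 1)
#' @param n number of pairs
#' @param alpha significance level
#' @return achieved power in (0, 1)
#' @export
power_from_r2 <- function(r_squared, n, alpha = 0.05) {
  if (!(r_squared > 0 && r_squared < 1)) stop("r_squared must be in (0, 1)")
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  r <- sqrt(r_squared)
  d <- 2 * r / sqrt(1 - r^2)
  ncp <- d * sqrt(n)
  tc <- stats::qt(1 - alpha / 2, n - 1)
  stats::pt(tc, n - 1, ncp, lower.tail = FALSE) + stats::pt(-tc, n - 1, ncp)
}
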