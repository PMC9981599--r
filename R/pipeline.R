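#' Analysis configuration for a cohort run
#'
#' Bundles every analysis parameter of the three families. Defaults follow
#' the study design: 2-18 Hz wavelets, theta 3-6 / alpha 6-9 Hz bands,
#' C3/C4 for the non-event-locked inter-brain measures, the five-channel
#' occipital cluster for event-locked analyses, -2.5..2.5 s epochs with a
#' -1000..-700 ms ERP baseline, VAR order 5, 1000 surrogate pairings, a
#' minimum of 5 gaze onsets per condition, and cluster correction at 0.025
#' (inter-brain, ERP) and 0.05 (ITC).
#'
#' @param freqs,cycles wavelet grid
#' @param bands named list of frequency bands (Hz)
#' @param central,occipital electrode sets
#' @param epoch_window peri-event window (s)
#' @param baseline_window ERP baseline (s)
#' @param min_onsets minimum gaze onsets per condition for inclusion
#' @param var_order fixed VAR order used for PDC (the BIC-selected study
#'   value); set `estimate_order = TRUE` to re-estimate per cohort
#' @param estimate_order,max_order BIC order re-estimation controls
#' @param n_perm_pairing random infant-adult pairings for the non-event null
#' @param n_perm_event random-event surrogate maps per dyad (PLV / ITC)
#' @param n_perm_pdc random-event surrogate maps per dyad for event PDC
#' @param n_perm_cluster sign-flip permutations for paired cluster tests
#' @param n_perm_erp permutations for the ERP time-shuffling test
#' @param erp_perm_method ERP permutation scheme; `"circular"` (default)
#'   preserves the ERP's autocorrelation and is calibrated for band-limited
#'   EEG, `"shuffle"` permutes time points literally (see
#'   [erp_onset_permutation_test()])
#' @param forming_alpha pointwise cluster-forming alpha
#' @param alpha_interbrain,alpha_itc,alpha_erp family-wise alphas
#' @param bonferroni_n comparison count for the non-event-locked z tests
#' @param decim decimation factor for the peri-event time axis of PLV/ITC
#'   maps
#' @param pdc_window,pdc_step event-locked PDC sliding window and step (s)
#' @param max_cond_seconds cap on per-condition data entering the
#'   non-event-locked analysis (after count matching); `Inf` uses all
#' @param preprocess apply robust average reference + band-pass first
#' @param filter_band band-pass edges (Hz)
#' @param artifact_rejection run high-power segment rejection on the infant
#'   data and mask rejected samples
#' @param seed seed for every stochastic step of a run
#' @return an object of class `cohort_config`
#' @export
cohort_config <- function(freqs = default_freqs(),
                          cycles = default_cycles(freqs),
                          bands = list(theta = c(3, 6), alpha = c(6, 9)),
                          central = central_channels(),
                          occipital = occipital_cluster(),
                          epoch_window = c(-2.5, 2.5),
                          baseline_window = c(-1, -0.7),
                          min_onsets = 5,
                          var_order = 5,
                          estimate_order = FALSE,
                          max_order = 10,
                          n_perm_pairing = 1000,
                          n_perm_event = 200,
                          n_perm_pdc = 200,
                          n_perm_cluster = 500,
                          n_perm_erp = 1000,
                          erp_perm_method = "circular",
                          forming_alpha = 0.05,
                          alpha_interbrain = 0.025,
                          alpha_itc = 0.05,
                          alpha_erp = 0.025,
                          bonferroni_n = 12,
                          decim = 5,
                          pdc_window = 1,
                          pdc_step = 0.25,
                          max_cond_seconds = Inf,
                          preprocess = TRUE,
                          filter_band = c(1, 20),
                          artifact_rejection = FALSE,
                          seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

#' Simulate a cohort of dyads
#'
#' @param n_dyads number of dyads
#' @param sim a [sim_config()] template; each dyad gets a seed derived from
#'   `seed` and its index
#' @param seed cohort seed
#' @return list of `dyad_recording`s
#' @export
simulate_cohort <- function(n_dyads, sim = sim_config(), seed = 1L) {
  lapply(seq_len(n_dyads), function(i) {
    cfg <- sim
    cfg$seed <- child_seed(seed, i)
    simulate_dyad(cfg)
  })
}

# ---- internal helpers -----------------------------------------------------

preprocess_dyad <- function(dyad, cfg) {
  mask <- NULL
  if (isTRUE(cfg$preprocess)) {
    for (role in c("infant", "adult")) {
      x <- robust_average_reference(dyad[[role]])
      dyad[[role]] <- bandpass_filter(x, dyad$fs, cfg$filter_band[1],
                                      cfg$filter_band[2])
    }
  }
  if (isTRUE(cfg$artifact_rejection)) {
    mask <- reject_highpower_segments(dyad$infant, dyad$fs)$mask
  }
  list(dyad = dyad, mask = mask)
}

occ_average <- function(eeg, occipital) {
  colMeans(eeg[occipital, , drop = FALSE])
}

# events with a full epoch inside the recording and off the mask
valid_events <- function(events, duration, window, fs, mask = NULL) {
  keep <- events$onset_s >= -window[1] &
    events$onset_s <= duration - window[2]
  if (!is.null(mask)) {
    L <- round((window[2] - window[1]) * fs)
    starts0 <- round(events$onset_s * fs) + round(window[1] * fs)
    mok <- rep(TRUE, nrow(events))
    for (i in which(keep)) {
      mok[i] <- !any(mask[(starts0[i] + 1L):(starts0[i] + L)])
    }
    keep <- keep & mok
  }
  events[keep, , drop = FALSE]
}

# per sender role: edge-safe mutual/nonmutual onsets, count matched (first n)
matched_onsets <- function(events, duration, window, fs, mask = NULL) {
  ev <- valid_events(events, duration, window, fs, mask)
  out <- list()
  for (snd in c("infant", "adult")) {
    m <- ev$onset_s[ev$sender == snd & ev$gaze_type == "mutual"]
    nm <- ev$onset_s[ev$sender == snd & ev$gaze_type == "nonmutual"]
    k <- min(length(m), length(nm))
    out[[snd]] <- list(mutual = m[seq_len(k)], nonmutual = nm[seq_len(k)],
                       n = k, n_raw_mutual = length(m),
                       n_raw_nonmutual = length(nm))
  }
  out
}

# event-locked magnitude-of-mean map from a complex (freq x time) series
map_from_complex <- function(E, onsets, fs, window, sel_rel) {
  starts0 <- round(onsets * fs) + round(window[1] * fs)
  acc <- matrix(0 + 0i, nrow(E), length(sel_rel))
  for (s0 in starts0) acc <- acc + E[, s0 + sel_rel, drop = FALSE]
  Mod(acc) / length(onsets)
}

# epochs of a single-channel signal as a trials x samples matrix
gather_epochs_vec <- function(sig, onsets, fs, window) {
  L <- round((window[2] - window[1]) * fs)
  starts0 <- round(onsets * fs) + round(window[1] * fs)
  t(vapply(starts0, function(s0) sig[(s0 + 1L):(s0 + L)], numeric(L)))
}

# band-averaged cross-pair PLV from complex unit-phasor matrices
plv_band_pair <- function(Ei, Ej, wl, freqs, bands) {
  T0 <- min(ncol(Ei), ncol(Ej))
  nwin <- floor(T0 / wl)
  if (nwin < 1) return(rep(NA_real_, length(bands)))
  nf <- nrow(Ei)
  P <- Ei[, seq_len(nwin * wl), drop = FALSE] *
    Conj(Ej[, seq_len(nwin * wl), drop = FALSE])
  dim(P) <- c(nf, wl, nwin)
  cm <- colMeans(aperm(P, c(2, 1, 3)))
  per_freq <- rowMeans(matrix(Mod(cm), nf))
  vapply(bands, function(b) band_average(per_freq, freqs, b), numeric(1))
}

# symmetric 12x12 (for order p: 2(p+1) square) matrix from packed upper tri
unpack_sym <- function(g, d) {
  G <- matrix(0, d, d)
  G[upper.tri(G, diag = TRUE)] <- g
  G <- G + t(G)
  diag(G) <- diag(G) / 2
  G
}

# VAR coefficients from a pooled crossproduct matrix; NULL if singular
var_from_crossprod <- function(G, p) {
  d <- 2L * (p + 1L)
  XtX <- G[3:d, 3:d]
  if (!is.finite(rcond(XtX)) || rcond(XtX) < 1e-10) return(NULL)
  B <- solve(XtX, G[3:d, 1:2])
  A <- array(0, c(2, 2, p))
  for (k in seq_len(p)) A[, , k] <- t(B[(2L * k - 1L):(2L * k), ])
  A
}

# windowed PDC between two window-blocked series (each consecutive block of
# `wl` samples is contiguous in its own recording; blocks are paired by
# index, so real and surrogate pairs are treated identically)
pdc_pair_windows <- function(x, y, fs, order, freqs, wl) {
  p <- order
  nwin <- floor(min(length(x), length(y)) / wl)
  nf <- length(freqs)
  acc <- matrix(0, 2, nf)
  cnt <- 0L
  for (w in seq_len(nwin)) {
    idx <- ((w - 1L) * wl + 1L):(w * wl)
    Z <- stats::embed(cbind(x[idx], y[idx]), p + 1L)
    A <- var_from_crossprod(crossprod(Z), p)
    if (is.null(A)) next
    pd <- pdc_from_var(A, freqs, fs)
    acc[1, ] <- acc[1, ] + pd[2, 1, ]  # x -> y
    acc[2, ] <- acc[2, ] + pd[1, 2, ]  # y -> x
    cnt <- cnt + 1L
  }
  if (cnt == 0L) return(matrix(NA_real_, 2, nf))
  acc / cnt
}

# cumulative lagged-crossproduct machinery for event-locked PDC
pdc_epoch_prep <- function(x, y, order) {
  Z <- stats::embed(cbind(x, y), order + 1L)
  d <- ncol(Z)
  ut <- which(upper.tri(matrix(0, d, d), diag = TRUE), arr.ind = TRUE)
  P <- Z[, ut[, 1]] * Z[, ut[, 2]]
  S <- rbind(0, apply(P, 2, cumsum))
  list(S = S, p = order, d = d, n = nrow(Z))
}

pdc_event_maps <- function(prep, onsets, fs, window, wl, step_n, freqs) {
  p <- prep$p
  L <- round((window[2] - window[1]) * fs)
  starts_rel <- seq(1L, L - wl + 1L, by = step_n)
  e0 <- round(onsets * fs) + round(window[1] * fs) + 1L
  nf <- length(freqs)
  m_xy <- matrix(NA_real_, nf, length(starts_rel))
  m_yx <- matrix(NA_real_, nf, length(starts_rel))
  for (s in seq_along(starts_rel)) {
    a <- e0 + starts_rel[s] - 1L
    b <- a + wl - 1L - p
    ok <- a >= 1L & b <= prep$n
    if (!any(ok)) next
    g <- colSums(prep$S[b[ok] + 1L, , drop = FALSE] -
                 prep$S[a[ok], , drop = FALSE])
    A <- var_from_crossprod(unpack_sym(g, prep$d), p)
    if (is.null(A)) next
    pd <- pdc_from_var(A, freqs, fs)
    m_xy[, s] <- pd[2, 1, ]
    m_yx[, s] <- pd[1, 2, ]
  }
  list(x_to_y = m_xy, y_to_x = m_yx,
       times = window[1] + (starts_rel - 1L) / fs + wl / (2 * fs))
}

category_names <- function() {
  c("infant_sender_mutual", "infant_sender_nonmutual",
    "adult_sender_mutual", "adult_sender_nonmutual")
}

cat_parts <- function(cat) {
  parts <- strsplit(cat, "_")[[1]]
  list(sender = parts[1], gaze = parts[3])
}

# ---- non-event-locked analysis -------------------------------------------

#' Non-event-locked inter-brain analysis over a cohort
#'
#' Per dyad: the paired EEG is segmented into mutual and non-mutual gaze
#' looks, the amount of data is matched between conditions, and PLV plus
#' bidirectional PDC are computed over the central electrodes (C3, C4, each
#' electrode paired with its homologue, values averaged over the pair) in
#' the theta and alpha bands. Group level: every metric is tested against a
#' null of random (non-partner) infant-adult pairings with the
#' z-score-to-Gaussian procedure (Bonferroni corrected), gaze type and band
#' enter a 2x2 repeated-measures ANOVA with Tukey-Kramer pairwise tests, and
#' JZS Bayes factors quantify the gaze-type evidence per band.
#'
#' @param cohort list of `dyad_recording`s
#' @param cfg a [cohort_config()]
#' @return a report list: `dyad_values`, `surrogate_tests`, `anova`,
#'   `bayes_factors`, `inclusion`, `order_used`, `cfg`
#' @export
run_nonevent_analysis <- function(cohort, cfg = cohort_config()) {
  stopifnot(length(cohort) >= 2)
  set.seed(child_seed(cfg$seed, 101L))
  fs <- cohort[[1]]$fs
  wl <- round(fs)
  band_freqs <- sort(unique(unlist(lapply(cfg$bands, function(b)
    cfg$freqs[cfg$freqs >= b[1] & cfg$freqs <= b[2]]))))
  bcycles <- cfg$cycles[match(band_freqs, cfg$freqs)]
  conds <- c("mutual", "nonmutual")
  n <- length(cohort)

  E <- list()    # E[[cond]][[dyad]][[partner]][[electrode]] unit phasors
  raw <- list()  # matched central-channel samples for the PDC fits
  seconds <- matrix(0, n, 2, dimnames = list(NULL, conds))
  for (d in seq_len(n)) {
    pp <- preprocess_dyad(cohort[[d]], cfg)
    dyad <- pp$dyad
    segs <- segment_by_gaze_state(dyad, mask = pp$mask)
    mt <- match_condition_counts(segs$mutual, segs$nonmutual)
    matched <- list(mutual = mt$a, nonmutual = mt$b)
    ph <- list()
    for (role in c("infant", "adult")) {
      tf <- morlet_decompose(dyad[[role]][cfg$central, , drop = FALSE],
                             fs, band_freqs, bcycles)
      ph[[role]] <- tf
    }
    for (cond in conds) {
      # 1-s analysis windows are taken *within* looks (never across the
      # concatenation boundaries) so that every window is contiguous data;
      # surrogate pairs then see exactly the window structure real pairs do
      starts <- unlist(lapply(matched[[cond]]$segments, function(s) {
        k <- (s$samples[2] - s$samples[1] + 1L) %/% wl
        if (k < 1L) return(integer(0))
        s$samples[1] + (seq_len(k) - 1L) * wl
      }))
      if (length(starts) == 0) next
      nwin <- min(length(starts), floor(cfg$max_cond_seconds))
      starts <- starts[seq_len(nwin)]
      idx <- as.vector(vapply(starts, function(s) s:(s + wl - 1L),
                              integer(wl)))
      seconds[d, cond] <- nwin * wl / fs
      for (role in c("infant", "adult")) {
        co <- ph[[role]]$coefficients
        E[[cond]][[role]][[d]] <- lapply(seq_along(cfg$central), function(el)
          exp(1i * Arg(co[el, , idx])))
      }
      raw[[cond]][[d]] <- list(
        infant = dyad$infant[cfg$central, idx, drop = FALSE],
        adult = dyad$adult[cfg$central, idx, drop = FALSE])
    }
  }
  included <- which(seconds[, 1] >= 1 & seconds[, 2] >= 1)
  if (length(included) < 2) stop("fewer than 2 dyads with usable data")
  inclusion <- data.frame(dyad = seq_len(n),
                          mutual_s = seconds[, 1],
                          nonmutual_s = seconds[, 2],
                          included = seq_len(n) %in% included)

  order_used <- cfg$var_order
  if (isTRUE(cfg$estimate_order)) {
    segs1 <- lapply(included, function(d)
      cbind(raw$mutual[[d]]$infant[1, ], raw$mutual[[d]]$adult[1, ]))
    order_used <- select_var_order_bic(segs1, max_order = cfg$max_order)
  }

  nb <- length(cfg$bands)
  ni <- length(included)
  M_plv <- array(NA_real_, c(ni, ni, nb, 2),
                 dimnames = list(NULL, NULL, names(cfg$bands), conds))
  M_i2a <- M_plv
  M_a2i <- M_plv
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    for (ii in seq_len(ni)) {
      di <- included[ii]
      for (jj in seq_len(ni)) {
        dj <- included[jj]
        acc_plv <- rep(0, nb)
        acc_dir <- matrix(0, 2, nb)
        for (el in seq_along(cfg$central)) {
          acc_plv <- acc_plv + plv_band_pair(
            E[[cond]]$infant[[di]][[el]], E[[cond]]$adult[[dj]][[el]],
            wl, band_freqs, cfg$bands)
          pw <- pdc_pair_windows(raw[[cond]][[di]]$infant[el, ],
                                 raw[[cond]][[dj]]$adult[el, ],
                                 fs, order_used, band_freqs, wl)
          for (bi in seq_len(nb)) {
            sel <- band_freqs >= cfg$bands[[bi]][1] &
              band_freqs <= cfg$bands[[bi]][2]
            acc_dir[, bi] <- acc_dir[, bi] + rowMeans(pw[, sel, drop = FALSE])
          }
        }
        M_plv[ii, jj, , ci] <- acc_plv / length(cfg$central)
        M_i2a[ii, jj, , ci] <- acc_dir[1, ] / length(cfg$central)
        M_a2i[ii, jj, , ci] <- acc_dir[2, ] / length(cfg$central)
      }
    }
  }

  metrics <- list(plv = M_plv, pdc_i2a = M_i2a, pdc_a2i = M_a2i)
  surrogate_tests <- data.frame()
  dyad_values <- data.frame()
  for (mn in names(metrics)) {
    for (bi in seq_len(nb)) {
      for (ci in seq_along(conds)) {
        mm <- metrics[[mn]][, , bi, ci]
        sn <- surrogate_dyad_null(mm, n_perm = cfg$n_perm_pairing)
        zp <- zscore_pvalue(sn$observed, sn, cfg$bonferroni_n)
        surrogate_tests <- rbind(surrogate_tests, data.frame(
          metric = mn, band = names(cfg$bands)[bi], gaze = conds[ci],
          observed = sn$observed, null_mean = sn$null_mean,
          null_sd = sn$null_sd, z = zp$z, p = zp$p,
          p_bonferroni = zp$p_adjusted))
        dyad_values <- rbind(dyad_values, data.frame(
          dyad = included, metric = mn, band = names(cfg$bands)[bi],
          gaze = conds[ci], value = diag(mm)))
      }
    }
  }

  anova <- list()
  bayes <- data.frame()
  for (mn in names(metrics)) {
    dv <- dyad_values[dyad_values$metric == mn, ]
    tab <- data.frame(subject = dv$dyad, f1 = dv$gaze, f2 = dv$band,
                      value = dv$value)
    anova[[mn]] <- rm_anova_2x2(tab, factor_names = c("gaze", "band"))
    for (bi in seq_len(nb)) {
      bn <- names(cfg$bands)[bi]
      xm <- dv$value[dv$band == bn & dv$gaze == "mutual"]
      xn <- dv$value[dv$band == bn & dv$gaze == "nonmutual"]
      bf <- jzs_bayes_factor_paired(xm, xn)
      bayes <- rbind(bayes, data.frame(metric = mn, band = bn,
                                       BF10 = bf$BF10, BF01 = bf$BF01,
                                       t = bf$t, n = bf$n))
    }
  }

  structure(list(dyad_values = dyad_values, surrogate_tests = surrogate_tests,
                 anova = anova, bayes_factors = bayes, inclusion = inclusion,
                 order_used = order_used, cfg = cfg),
            class = "nonevent_report")
}

# ---- event-locked inter-brain analysis -----------------------------------

#' Event-locked inter-brain analysis over a cohort
#'
#' Time-frequency PLV and bidirectional PDC maps are computed over the
#' occipital cluster average around the four onset categories
#' (infant/adult sender x mutual/non-mutual; sender and receiver onsets are
#' the same clock events viewed from either brain). Each dyad also
#' contributes surrogate maps time-locked to randomly inserted events
#' (count-matched). Group level: cluster-based permutation tests compare the
#' observed group maps against the surrogate distribution (baseline tests)
#' and mutual against non-mutual maps (paired tests), both corrected at
#' `alpha_interbrain`.
#'
#' @inheritParams run_nonevent_analysis
#' @param metrics which maps to compute (subset of `"plv"`, `"pdc"`)
#' @return a report list: `maps`, `baseline_tests`, `contrast_tests`,
#'   `inclusion`, `times`, `cfg`
#' @export
run_event_locked_analysis <- function(cohort, cfg = cohort_config(),
                                      metrics = c("plv", "pdc")) {
  stopifnot(length(cohort) >= 3)
  set.seed(child_seed(cfg$seed, 202L))
  fs <- cohort[[1]]$fs
  window <- cfg$epoch_window
  L <- round((window[2] - window[1]) * fs)
  sel_rel <- seq(1L, L, by = cfg$decim)
  times_plv <- window[1] + (sel_rel - 1L) / fs
  wl <- round(cfg$pdc_window * fs)
  step_n <- max(1L, round(cfg$pdc_step * fs))
  nf <- length(cfg$freqs)
  n <- length(cohort)
  cats <- category_names()

  obs <- list(); surr_sum <- list(); incl <- list()
  times_pdc <- NULL
  for (cat in cats) {
    for (mn in metrics) {
      for (dir in if (mn == "plv") "plv" else c("pdc_i2a", "pdc_a2i")) {
        obs[[cat]][[dir]] <- list()
        surr_sum[[cat]][[dir]] <- NULL
      }
    }
    incl[[cat]] <- logical(n)
  }
  counts <- matrix(0L, n, length(cats), dimnames = list(NULL, cats))

  for (d in seq_len(n)) {
    pp <- preprocess_dyad(cohort[[d]], cfg)
    dyad <- pp$dyad
    occ_i <- occ_average(dyad$infant, cfg$occipital)
    occ_a <- occ_average(dyad$adult, cfg$occipital)
    mo <- matched_onsets(dyad$events, dyad$duration, window, fs, pp$mask)
    Ediff <- NULL
    prep <- NULL
    if ("plv" %in% metrics) {
      tf_i <- morlet_decompose(occ_i, fs, cfg$freqs, cfg$cycles)
      tf_a <- morlet_decompose(occ_a, fs, cfg$freqs, cfg$cycles)
      Ediff <- exp(1i * (Arg(tf_i$coefficients) - Arg(tf_a$coefficients)))
    }
    if ("pdc" %in% metrics) prep <- pdc_epoch_prep(occ_i, occ_a, cfg$var_order)
    for (cat in cats) {
      p <- cat_parts(cat)
      onsets <- mo[[p$sender]][[p$gaze]]
      K <- length(onsets)
      counts[d, cat] <- K
      if (K < cfg$min_onsets) next
      incl[[cat]][d] <- TRUE
      surr <- surrogate_event_onsets(K, dyad$duration, fs, window, pp$mask,
                                     n_perm = max(cfg$n_perm_event,
                                                  cfg$n_perm_pdc))
      if ("plv" %in% metrics) {
        obs[[cat]]$plv[[d]] <- map_from_complex(Ediff, onsets, fs, window,
                                                sel_rel)
        ss <- surr_sum[[cat]]$plv
        if (is.null(ss)) ss <- array(0, c(nf, length(sel_rel),
                                          cfg$n_perm_event))
        for (b in seq_len(cfg$n_perm_event)) {
          ss[, , b] <- ss[, , b] + map_from_complex(Ediff, surr[b, ], fs,
                                                    window, sel_rel)
        }
        surr_sum[[cat]]$plv <- ss
      }
      if ("pdc" %in% metrics) {
        om <- pdc_event_maps(prep, onsets, fs, window, wl, step_n, cfg$freqs)
        times_pdc <- om$times
        obs[[cat]]$pdc_i2a[[d]] <- om$x_to_y
        obs[[cat]]$pdc_a2i[[d]] <- om$y_to_x
        for (dir in c("pdc_i2a", "pdc_a2i")) {
          if (is.null(surr_sum[[cat]][[dir]]))
            surr_sum[[cat]][[dir]] <- array(0, c(nf, length(om$times),
                                                 cfg$n_perm_pdc))
        }
        for (b in seq_len(cfg$n_perm_pdc)) {
          sm <- pdc_event_maps(prep, surr[b, ], fs, window, wl, step_n,
                               cfg$freqs)
          surr_sum[[cat]]$pdc_i2a[, , b] <- surr_sum[[cat]]$pdc_i2a[, , b] +
            sm$x_to_y
          surr_sum[[cat]]$pdc_a2i[, , b] <- surr_sum[[cat]]$pdc_a2i[, , b] +
            sm$y_to_x
        }
      }
    }
  }

  dirs <- unlist(lapply(metrics, function(mn)
    if (mn == "plv") "plv" else c("pdc_i2a", "pdc_a2i")))
  baseline_tests <- list()
  group_maps <- list()
  for (cat in cats) {
    nd <- sum(incl[[cat]])
    for (dir in dirs) {
      if (nd < 3) next
      om <- Reduce(`+`, obs[[cat]][[dir]][incl[[cat]]]) / nd
      group_maps[[cat]][[dir]] <- om
      baseline_tests[[cat]][[dir]] <- cluster_permutation_test(
        observed = om, null_maps = surr_sum[[cat]][[dir]] / nd,
        forming_alpha = cfg$forming_alpha, alpha = cfg$alpha_interbrain)
    }
  }
  contrast_tests <- list()
  for (snd in c("infant", "adult")) {
    cm <- paste0(snd, "_sender_mutual")
    cn <- paste0(snd, "_sender_nonmutual")
    both <- which(incl[[cm]] & incl[[cn]])
    for (dir in dirs) {
      if (length(both) < 3) next
      dm <- dim(obs[[cm]][[dir]][[both[1]]])
      arr_m <- array(0, c(length(both), dm))
      arr_n <- array(0, c(length(both), dm))
      for (k in seq_along(both)) {
        arr_m[k, , ] <- obs[[cm]][[dir]][[both[k]]]
        arr_n[k, , ] <- obs[[cn]][[dir]][[both[k]]]
      }
      contrast_tests[[paste0(snd, "_sender")]][[dir]] <-
        cluster_permutation_test(cond_a = arr_m, cond_b = arr_n,
                                 forming_alpha = cfg$forming_alpha,
                                 alpha = cfg$alpha_interbrain,
                                 n_perm = cfg$n_perm_cluster)
    }
  }

  inclusion <- data.frame(dyad = seq_len(n), counts,
                          check.names = FALSE)
  structure(list(maps = group_maps, dyad_maps = obs,
                 baseline_tests = baseline_tests,
                 contrast_tests = contrast_tests,
                 inclusion = inclusion, included = incl,
                 times = list(plv = times_plv, pdc = times_pdc),
                 freqs = cfg$freqs, cfg = cfg),
            class = "event_interbrain_report")
}

# ---- intra-brain event-locked analysis -----------------------------------

#' Intra-brain event-locked analysis over a cohort
#'
#' Occipital-cluster ERPs and ITC maps around the four onset categories,
#' analysed separately for each partner's brain and each role (the sender of
#' a gaze shift, and the receiver whose partner shifted). ERPs are
#' baseline-corrected and tested with the time-shuffling permutation test;
#' component amplitudes (P1, N170/N290, P300/P400) are measured per subject
#' and compared between gaze types for senders. ITC is tested against
#' random-event surrogate maps with cluster permutation at `alpha_itc`, and
#' mutual vs non-mutual contrasts use paired cluster tests.
#'
#' @inheritParams run_nonevent_analysis
#' @return a report list: `erp` (per combo: subject ERP matrix, onset test,
#'   components, contrast t tests), `itc` (per combo: group map, baseline
#'   test, contrasts), `inclusion`, `times`, `cfg`
#' @export
run_intrabrain_analysis <- function(cohort, cfg = cohort_config()) {
  stopifnot(length(cohort) >= 3)
  set.seed(child_seed(cfg$seed, 303L))
  fs <- cohort[[1]]$fs
  window <- cfg$epoch_window
  L <- round((window[2] - window[1]) * fs)
  erp_times <- window[1] + (seq_len(L) - 1L) / fs
  sel_rel <- seq(1L, L, by = cfg$decim)
  itc_times <- window[1] + (sel_rel - 1L) / fs
  nf <- length(cfg$freqs)
  n <- length(cohort)
  cats <- category_names()

  combos <- list()
  for (subj in c("infant", "adult")) {
    for (role in c("sender", "receiver")) {
      for (gz in c("mutual", "nonmutual")) {
        combos[[paste(subj, role, gz, sep = "_")]] <-
          list(subject = subj, role = role, gaze = gz)
      }
    }
  }

  erps <- lapply(combos, function(cb) matrix(NA_real_, n, L))
  itc_obs <- lapply(combos, function(cb) vector("list", n))
  itc_surr <- lapply(combos, function(cb) NULL)
  incl <- lapply(combos, function(cb) logical(n))
  counts <- matrix(0L, n, length(cats), dimnames = list(NULL, cats))

  for (d in seq_len(n)) {
    pp <- preprocess_dyad(cohort[[d]], cfg)
    dyad <- pp$dyad
    occ <- list(infant = occ_average(dyad$infant, cfg$occipital),
                adult = occ_average(dyad$adult, cfg$occipital))
    Eph <- lapply(occ, function(sig)
      exp(1i * Arg(morlet_decompose(sig, fs, cfg$freqs,
                                    cfg$cycles)$coefficients)))
    mo <- matched_onsets(dyad$events, dyad$duration, window, fs, pp$mask)
    for (cat in cats) counts[d, cat] <-
      mo[[cat_parts(cat)$sender]]$n
    for (nm in names(combos)) {
      cb <- combos[[nm]]
      snd <- if (cb$role == "sender") cb$subject
             else setdiff(c("infant", "adult"), cb$subject)
      onsets <- mo[[snd]][[cb$gaze]]
      K <- length(onsets)
      if (K < cfg$min_onsets) next
      incl[[nm]][d] <- TRUE
      ep <- gather_epochs_vec(occ[[cb$subject]], onsets, fs, window)
      ep <- baseline_correct(ep, cfg$baseline_window, times = erp_times)
      erps[[nm]][d, ] <- colMeans(ep)
      itc_obs[[nm]][[d]] <- map_from_complex(Eph[[cb$subject]], onsets, fs,
                                             window, sel_rel)
      surr <- surrogate_event_onsets(K, dyad$duration, fs, window, pp$mask,
                                     n_perm = cfg$n_perm_event)
      ss <- itc_surr[[nm]]
      if (is.null(ss)) ss <- array(0, c(nf, length(sel_rel),
                                        cfg$n_perm_event))
      for (b in seq_len(cfg$n_perm_event)) {
        ss[, , b] <- ss[, , b] + map_from_complex(Eph[[cb$subject]],
                                                  surr[b, ], fs, window,
                                                  sel_rel)
      }
      itc_surr[[nm]] <- ss
    }
  }

  erp_out <- list()
  itc_out <- list()
  for (nm in names(combos)) {
    cb <- combos[[nm]]
    idx <- which(incl[[nm]])
    if (length(idx) < 3) next
    em <- erps[[nm]][idx, , drop = FALSE]
    onset_test <- erp_onset_permutation_test(em, erp_times,
                                             n_perm = cfg$n_perm_erp,
                                             alpha = cfg$alpha_erp,
                                             method = cfg$erp_perm_method)
    comp <- lapply(idx, function(k)
      component_amplitudes(erps[[nm]][k, ], erp_times, cb$subject))
    erp_out[[nm]] <- list(subject_erps = em, dyads = idx,
                          grand = colMeans(em), onset_test = onset_test,
                          components = comp)
    om <- Reduce(`+`, itc_obs[[nm]][idx]) / length(idx)
    itc_out[[nm]] <- list(
      group_map = om, dyads = idx,
      baseline_test = cluster_permutation_test(
        observed = om, null_maps = itc_surr[[nm]] / length(idx),
        forming_alpha = cfg$forming_alpha, alpha = cfg$alpha_itc))
  }

  # mutual vs non-mutual contrasts (ITC cluster tests, ERP component t tests)
  itc_contrasts <- list()
  erp_component_tests <- data.frame()
  for (subj in c("infant", "adult")) {
    for (role in c("sender", "receiver")) {
      nm_m <- paste(subj, role, "mutual", sep = "_")
      nm_n <- paste(subj, role, "nonmutual", sep = "_")
      both <- which(incl[[nm_m]] & incl[[nm_n]])
      if (length(both) < 3) next
      dm <- c(nf, length(sel_rel))
      arr_m <- array(0, c(length(both), dm))
      arr_n <- array(0, c(length(both), dm))
      for (k in seq_along(both)) {
        arr_m[k, , ] <- itc_obs[[nm_m]][[both[k]]]
        arr_n[k, , ] <- itc_obs[[nm_n]][[both[k]]]
      }
      itc_contrasts[[paste(subj, role, sep = "_")]] <-
        cluster_permutation_test(cond_a = arr_m, cond_b = arr_n,
                                 forming_alpha = cfg$forming_alpha,
                                 alpha = cfg$alpha_itc,
                                 n_perm = cfg$n_perm_cluster)
      if (role == "sender") {
        for (comp_i in seq_len(3)) {
          p2p <- function(nm) vapply(both, function(k)
            component_amplitudes(erps[[nm]][k, ], erp_times,
                                 subj)$peak_to_peak[comp_i], numeric(1))
          a <- p2p(nm_m); b <- p2p(nm_n)
          tt <- stats::t.test(a, b, paired = TRUE)
          comp_name <- component_amplitudes(erps[[nm_m]][both[1], ],
                                            erp_times, subj)$component[comp_i]
          erp_component_tests <- rbind(erp_component_tests, data.frame(
            subject = subj, component = comp_name,
            mean_mutual = mean(a), mean_nonmutual = mean(b),
            t = unname(tt$statistic), p = tt$p.value, n = length(both)))
        }
      }
    }
  }

  inclusion <- data.frame(dyad = seq_len(n), counts, check.names = FALSE)
  structure(list(erp = erp_out, itc = itc_out,
                 itc_contrasts = itc_contrasts,
                 erp_component_tests = erp_component_tests,
                 inclusion = inclusion, included = incl,
                 times = list(erp = erp_times, itc = itc_times),
                 freqs = cfg$freqs, cfg = cfg),
            class = "intrabrain_report")
}

# ---- report output --------------------------------------------------------

#' Write a report's tables to disk
#'
#' Data frames become CSV files; a JSON manifest records the configuration,
#' seed and significance summaries.
#'
#' @param report a report from one of the `run_*_analysis` functions
#' @param dir output directory
#' @return invisibly, the files written
#' @export
save_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(report)) {
    if (is.data.frame(report[[nm]])) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(report[[nm]], f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  summarise_tests <- function(x) {
    if (inherits(x, "cluster_result")) {
      return(list(n_clusters = length(x$clusters),
                  significant = has_significant_cluster(x),
                  min_p = if (length(x$clusters)) x$clusters[[1]]$p else NA))
    }
    if (is.list(x)) return(lapply(x, summarise_tests))
    NULL
  }
  manifest <- list(class = class(report)[1],
                   seed = report$cfg$seed,
                   tests = summarise_tests(
                     report[intersect(names(report),
                                      c("baseline_tests", "contrast_tests",
                                        "itc", "itc_contrasts"))]))
  fm <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, fm, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(c(files, fm))
}
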