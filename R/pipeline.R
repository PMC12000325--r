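#' End-to-end phase opposition workflow
#'
#' Runs the full phase-opposition chain on one dataset: analytic extraction
#' (Morlet, plus an optional causal-filter control), POP map, label
#' permutation, cluster-based correction in the pre-movement window,
#' optimal-angle estimation at the most significant (frequency, time) point,
#' optimal/non-optimal trial partition, and the phase-binned outcome
#' probability. When `labels` carries a `rating` column, ratings are first
#' detrended against movement delay (when a `delay` column is present) and
#' split into extreme thirds.
#'
#' @param trials a [trial_set()].
#' @param labels a [label_set()]; either high/low labels or ratings.
#' @param freqs Morlet frequency grid.
#' @param n_cycles Morlet width in cycles.
#' @param causal_band optional `c(f_lo, f_hi)` for the causal-filter control
#'   (NULL skips it).
#' @param n_perm permutations.
#' @param seed integer seed (all stochastic steps derive from it).
#' @param window cluster-correction time window, seconds.
#' @param threshold_T cluster-forming threshold.
#' @param n_bins bins for the phase-binned outcome probability.
#' @param channel channel index to analyse.
#' @param time_decim keep every k-th sample for the permutation stage
#'   (statistical maps only; phases for partitioning use the full map).
#' @return list of class `pop_report`; see elements `permutation`,
#'   `clusters`, `peak` (frequency/time of minimal p), `optimal_angle`,
#'   `partition`, `phase_binned`, `causal` and `config`.
#' @export
run_pop_workflow <- function(trials, labels,
                             freqs = seq(4, 13, length.out = 10),
                             n_cycles = 2 * pi, causal_band = NULL,
                             n_perm = 1000L, seed = 1L, window = c(-0.5, 0),
                             threshold_T = 2, n_bins = 6L, channel = 1L,
                             time_decim = 1L) {
  stopifnot(inherits(trials, "trial_set"))
  config <- list(
    freqs = freqs, n_cycles = n_cycles, causal_band = causal_band,
    n_perm = n_perm, seed = seed, window = window, threshold_T = threshold_T,
    n_bins = n_bins, channel = channel, time_decim = time_decim
  )
  if (!is.null(labels$rating) && any(!is.na(labels$rating))) {
    ratings <- labels$rating
    if (!is.null(labels$delay) && sd(labels$delay) > 0) {
      ratings <- detrend_ratings_by_delay(ratings, labels$delay)
    }
    labels <- split_rating_extremes(as.numeric(ratings))
  }
  lab <- as_label_vector(labels, dim(trials)[1])
  if (sum(lab == "high") < 2L || sum(lab == "low") < 2L) {
    stop_cfg("insufficient trials per condition after labelling")
  }
  analytic <- morlet_analytic(trials, freqs, n_cycles)
  an_perm <- subset_analytic(analytic, time_decim = time_decim)
  perm <- permutation_pvalues(an_perm, lab, n_perm = n_perm, seed = seed,
                              channel = channel)
  clus <- cluster_correct(perm, threshold_T = threshold_T, window = window)
  # peak = minimal-p cell inside the window; under permutation-count
  # saturation ties resolve to the largest observed POP
  tmask <- an_perm$times >= window[1] & an_perm$times < window[2]
  pwin <- perm$p[, tmask, drop = FALSE]
  owin <- perm$observed[, tmask, drop = FALSE]
  cand <- which(pwin == min(pwin), arr.ind = TRUE)
  ij <- cand[which.max(owin[cand]), ]
  peak_freq <- an_perm$freqs[ij[1]]
  peak_time <- an_perm$times[tmask][ij[2]]
  # phases at the peak cell from the full-resolution map
  fi <- match_freqs(peak_freq, analytic$freqs)
  ti <- which.min(abs(analytic$times - peak_time))
  ph <- Arg(analytic$values[, channel, fi, ti])
  opt <- optimal_phase_angle(ph[lab == "high"], ph[lab == "low"])
  part <- select_phase_trials(ph, opt)
  binned <- phase_binned_outcome_probability(
    ph[lab != "excluded"], as.integer(lab[lab != "excluded"] == "high"),
    n_bins = n_bins, reference_angle = opt
  )
  causal <- NULL
  if (!is.null(causal_band)) {
    can <- causal_analytic(trials, causal_band)
    cperm <- permutation_pvalues(
      subset_analytic(can, time_decim = time_decim), lab,
      n_perm = n_perm, seed = seed + 1L, channel = channel
    )
    cwin <- cperm$times >= window[1] & cperm$times < window[2]
    causal <- list(
      permutation = cperm,
      min_p_pre_movement = min(cperm$p[, cwin, drop = FALSE]),
      group_delay_s = can$params$group_delay_s
    )
  }
  structure(
    list(
      labels = lab, permutation = perm, clusters = clus,
      peak = list(freq = peak_freq, time = peak_time, p = min(pwin)),
      optimal_angle = opt, partition = part, phase_binned = binned,
      causal = causal, config = config
    ),
    class = "pop_report"
  )
}

#' @export
print.pop_report <- function(x, ...) {
  cat("<pop_report>\n")
  cat(sprintf("  peak: %.3g Hz at %.3f s (uncorrected p = %.4g)\n",
              x$peak$freq, x$peak$time, x$peak$p))
  if (nrow(x$clusters$clusters)) {
    cat(sprintf("  best cluster: score %.2f, corrected p = %.4g\n",
                x$clusters$clusters$score[1], x$clusters$clusters$p_corrected[1]))
  } else {
    cat("  no supra-threshold cluster\n")
  }
  cat(sprintf("  optimal angle: %.3f rad; %d optimal / %d non-optimal trials\n",
              x$optimal_angle, length(x$partition$optimal),
              length(x$partition$non_optimal)))
  invisible(x)
}

#' End-to-end phase-gated connectivity workflow
#'
#' For each subject: tests pre-movement phase opposition (subjects without
#' any cell at uncorrected p < 0.05 in the declared band/window are excluded
#' and listed in the report); estimates the per-subject optimal angle at the
#' frequency of strongest opposition from the time-averaged pre-movement
#' phase; partitions trials; then contrasts seed-to-target debiased WPLI
#' between optimal and non-optimal trials across subjects (frequency cluster
#' test, optional macro-group Bonferroni) and runs the lag-coherence
#' directionality analysis.
#'
#' @param subjects list; each element needs `trials` (a [trial_set()]) and
#'   `labels` (a [label_set()]).
#' @param seed_channel,target_channels channel indices.
#' @param pop_freqs frequency grid for the phase-opposition step.
#' @param conn_freqs frequency grid for the WPLI contrast (default 42
#'   linearly spaced points over 4-45 Hz).
#' @param dir_freqs frequencies for the directionality analysis.
#' @param pre_window pre-movement window, seconds.
#' @param window post-movement connectivity window, seconds.
#' @param n_perm permutations for the POP step and cluster tests.
#' @param lags lag grid for the directionality analysis, seconds.
#' @param groups optional macro-group map (name -> target channels).
#' @param threshold_T cluster-forming threshold.
#' @param seed integer seed.
#' @param time_decim decimation for the POP permutation stage.
#' @return list of class `connectivity_report`.
#' @export
run_connectivity_workflow <- function(subjects, seed_channel = 1L,
                                      target_channels = NULL,
                                      pop_freqs = seq(8, 13, by = 0.5),
                                      conn_freqs = seq(4, 45, length.out = 42),
                                      dir_freqs = 9:12,
                                      pre_window = c(-0.5, 0),
                                      window = c(0.2, 1.2),
                                      n_perm = 500L,
                                      lags = seq(-0.1, 0.1, by = 0.005),
                                      groups = NULL, threshold_T = 2,
                                      seed = 1L, time_decim = 2L) {
  config <- list(
    seed_channel = seed_channel, pop_freqs = pop_freqs,
    conn_freqs = conn_freqs, dir_freqs = dir_freqs,
    pre_window = pre_window, window = window, n_perm = n_perm,
    lags = lags, threshold_T = threshold_T, seed = seed
  )
  seeds <- derive_seeds(seed, length(subjects) + 1L)
  kept <- list()
  excluded <- integer(0)
  subject_info <- vector("list", length(subjects))
  for (s in seq_along(subjects)) {
    tr <- subjects[[s]]$trials
    lab <- as_label_vector(subjects[[s]]$labels, dim(tr)[1])
    an_pop <- morlet_analytic(tr, pop_freqs)
    perm <- permutation_pvalues(
      subset_analytic(an_pop, time_decim = time_decim), lab,
      n_perm = n_perm, seed = seeds[s], channel = seed_channel
    )
    tmask <- perm$times >= pre_window[1] & perm$times < pre_window[2]
    significant <- any(perm$p[, tmask] < 0.05)
    f_star <- peak_pop_frequency(perm, pre_window)
    subject_info[[s]] <- list(significant = significant,
                              pop_peak_freq = as.numeric(f_star))
    if (!significant) {
      excluded <- c(excluded, s)
      next
    }
    # time-averaged pre-movement phase at the per-subject peak frequency:
    # phases are extrapolated (de-rotated at f*) to the window midpoint
    # before circular averaging, otherwise the oscillation's own advance
    # would cancel the average
    fi <- match_freqs(as.numeric(f_star), an_pop$freqs)
    tsel <- which(an_pop$times >= pre_window[1] & an_pop$times < pre_window[2] &
                    an_pop$valid[fi, ])
    u <- an_pop$values[, seed_channel, fi, tsel, drop = TRUE]
    if (is.null(dim(u))) u <- matrix(u, nrow = 1L)
    u <- u / Mod(u)
    t_mid <- mean(an_pop$times[tsel])
    rot <- exp(-1i * 2 * pi * as.numeric(f_star) * (an_pop$times[tsel] - t_mid))
    ph <- Arg(as.vector(u %*% rot))
    opt <- optimal_phase_angle(ph[lab == "high"], ph[lab == "low"])
    part <- select_phase_trials(ph, opt)
    an_conn <- morlet_analytic(tr, conn_freqs)
    kept[[length(kept) + 1L]] <- list(
      index = s, analytic = an_conn, partition = part,
      optimal_angle = opt, pop_peak_freq = as.numeric(f_star)
    )
  }
  if (!length(kept)) stop_cfg("all subjects excluded: no significant phase opposition")
  contrast <- phase_split_connectivity_contrast(
    kept, seed_channel = seed_channel, target_channels = target_channels,
    freqs = conn_freqs, window = window, groups = groups,
    group_freqs = range(dir_freqs), n_perm = n_perm,
    threshold_T = threshold_T, seed = seeds[length(seeds)]
  )
  target1 <- (target_channels %||% setdiff(
    seq_len(dim(kept[[1]]$analytic$values)[2]), seed_channel
  ))[1]
  curves_opt <- lapply(kept, function(k) {
    lag_phase_coherence(k$analytic, seed_channel, target1, lags,
                        freqs = dir_freqs, window = window,
                        trials = k$partition$optimal)
  })
  curves_non <- lapply(kept, function(k) {
    lag_phase_coherence(k$analytic, seed_channel, target1, lags,
                        freqs = dir_freqs, window = window,
                        trials = k$partition$non_optimal)
  })
  direction <- directionality_shift_test(curves_opt, curves_non)
  structure(
    list(
      subject_info = subject_info, excluded = excluded,
      n_kept = length(kept),
      optimal_angles = vapply(kept, `[[`, numeric(1), "optimal_angle"),
      contrast = contrast,
      curves_optimal = curves_opt, curves_non_optimal = curves_non,
      directionality = direction, config = config
    ),
    class = "connectivity_report"
  )
}
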