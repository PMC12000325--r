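#' Oscillation phases at spike times
#'
#' Looks up the analytic phase at the requested frequency at the sample
#' nearest to each spike (ties broken toward the earlier sample). Spikes
#' falling outside the epoch or on edge-invalid samples are dropped; the
#' count of dropped spikes is reported in the `n_dropped` attribute.
#'
#' @param analytic an `analytic_map`.
#' @param spikes a `spike_train_set` (columns `unit`, `trial`, `time_s`).
#' @param freq frequency, Hz; must be on the analytic grid.
#' @param channel channel index.
#' @return data.frame of class `phase_sample`: `unit`, `trial`, `phase`.
#' @export
phases_at_spikes <- function(analytic, spikes, freq, channel = 1L) {
  stopifnot(inherits(analytic, "analytic_map"))
  fi <- match_freqs(freq, analytic$freqs)
  times <- analytic$times
  fs <- analytic$fs
  ns <- length(times)
  # nearest sample, ties toward the earlier sample
  pos <- (spikes$time_s - times[1]) * fs
  idx <- as.integer(ceiling(pos - 0.5)) + 1L
  ok <- idx >= 1L & idx <= ns
  ok[ok] <- analytic$valid[fi, idx[ok]]
  n_drop <- sum(!ok)
  if (!any(ok)) stop_cfg("no spikes fall on valid samples")
  tr <- spikes$trial[ok]
  w <- analytic$values[cbind(tr, channel, fi, idx[ok])]
  out <- data.frame(unit = spikes$unit[ok], trial = tr, phase = Arg(w))
  attr(out, "n_dropped") <- n_drop
  attr(out, "freq") <- analytic$freqs[fi]
  class(out) <- c("phase_sample", "data.frame")
  out
}

#' Spike-field phase-locking value
#'
#' PLV = modulus of the mean unit phasor over all pooled spikes — the ITC of
#' oscillation phases sampled at spike times.
#'
#' @param phases a `phase_sample`, or numeric angles in radians.
#' @return scalar PLV in `[0, 1]`.
#' @export
spike_field_plv <- function(phases) {
  ph <- if (is.data.frame(phases)) phases$phase else phases
  if (!length(ph)) stop_cfg("no spikes")
  if (length(ph) < 50L) warning("fewer than 50 spikes; PLV estimate is noisy")
  Mod(mean(exp(1i * ph)))
}

#' Spike-field PLV spectrum over the analytic frequency grid
#'
#' @param analytic an `analytic_map`.
#' @param spikes a `spike_train_set`.
#' @param channel channel index.
#' @return data.frame: `freq` (Hz), `plv`, `n_spikes`.
#' @export
spike_plv_spectrum <- function(analytic, spikes, channel = 1L) {
  res <- lapply(analytic$freqs, function(f) {
    ps <- phases_at_spikes(analytic, spikes, f, channel)
    data.frame(freq = f, plv = suppressWarnings(spike_field_plv(ps)),
               n_spikes = nrow(ps))
  })
  do.call(rbind, res)
}

#' Spike-phase histogram relative to a reference phase
#'
#' Equal-width phase bins with the first bin centred on `reference` (the
#' global preferred phase); probabilities sum to one. Uniform phases put
#' 1/n_bins in each bin. Clopper-Pearson binomial confidence intervals at
#' the requested level.
#'
#' @param phases a `phase_sample` or numeric angles.
#' @param n_bins number of bins (default 5, >= 2).
#' @param reference reference angle, radians.
#' @param conf binomial confidence level (default 0.66).
#' @return data.frame: bin centre (radians, relative to reference),
#'   count, probability, ci_lower, ci_upper.
#' @export
spike_phase_histogram <- function(phases, n_bins = 5L, reference = 0,
                                  conf = 0.66) {
  if (n_bins < 2L) stop_cfg("`n_bins` must be >= 2")
  ph <- if (is.data.frame(phases)) phases$phase else phases
  width <- 2 * pi / n_bins
  u <- (ph - reference + width / 2) %% (2 * pi)
  bin <- pmin(floor(u / width), n_bins - 1L) + 1L
  count <- tabulate(bin, n_bins)
  n <- sum(count)
  ci <- binom_ci(count, n, conf)
  data.frame(
    centre = wrap_angle((seq_len(n_bins) - 1L) * width),
    count = count,
    probability = count / n,
    ci_lower = ci[, 1], ci_upper = ci[, 2]
  )
}

#' Per-unit preferred phase angles
#'
#' Preferred angle = argument of the per-unit spike-phase resultant; the
#' resultant length (mean vector modulus) measures coupling strength. Units
#' with fewer than `min_spikes` spikes are flagged `low_count`.
#'
#' @param phases a `phase_sample`.
#' @param min_spikes flagging threshold (default 10).
#' @return data.frame: `unit`, `n_spikes`, `angle`, `resultant`,
#'   `low_count`.
#' @export
unit_preferred_angles <- function(phases, min_spikes = 10L) {
  stopifnot(is.data.frame(phases))
  units <- sort(unique(phases$unit))
  res <- lapply(units, function(u) {
    ph <- phases$phase[phases$unit == u]
    z <- mean(exp(1i * ph))
    data.frame(
      unit = u, n_spikes = length(ph), angle = Arg(z), resultant = Mod(z),
      low_count = length(ph) < min_spikes
    )
  })
  do.call(rbind, res)
}

#' Trial-averaged firing-rate contrast with cluster correction over time
#'
#' Pools spikes over units, bins them over the epoch, and compares
#' per-trial rates between high and low trials with a pointwise t statistic
#' and a label-permutation cluster test over time bins (|t| >= threshold, as
#' in the time-frequency case but with 1-D adjacency). Bins with no spikes
#' count as rate 0.
#'
#' @param spikes a `spike_train_set`.
#' @param labels a [label_set()] or label vector (per trial).
#' @param trials the `trial_set` the spikes are linked to (for the epoch).
#' @param bin_width bin width, seconds.
#' @param n_perm permutations for the cluster test.
#' @param seed integer seed.
#' @param threshold_T cluster-forming threshold on |t|.
#' @return list of class `rate_contrast`: bin centres, per-condition mean
#'   rates (Hz per unit) and standard errors, `t`, `clusters`.
#' @export
firing_rate_contrast <- function(spikes, labels, trials, bin_width = 0.05,
                                 n_perm = 500L, seed = 1L, threshold_T = 2) {
  tt <- trial_times(trials)
  n_tr <- dim(trials)[1]
  lab <- as_label_vector(labels, n_tr)
  ia <- which(lab == "high"); ib <- which(lab == "low")
  if (!length(ia) || !length(ib)) stop_cfg("both conditions must be non-empty")
  n_units <- length(unique(spikes$unit))
  breaks <- seq(tt[1], tt[length(tt)] + bin_width, by = bin_width)
  nb <- length(breaks) - 1L
  bin <- findInterval(spikes$time_s, breaks, rightmost.closed = TRUE)
  keep <- bin >= 1L & bin <= nb
  # trials x bins spike-count matrix -> rate per unit
  cnt <- matrix(0, n_tr, nb)
  if (any(keep)) {
    tb <- table(factor(spikes$trial[keep], levels = seq_len(n_tr)),
                factor(bin[keep], levels = seq_len(nb)))
    cnt <- matrix(as.numeric(tb), n_tr, nb)
  }
  rate <- cnt / (n_units * bin_width)
  tstat <- function(ia, ib) {
    xa <- rate[ia, , drop = FALSE]; xb <- rate[ib, , drop = FALSE]
    ma <- colMeans(xa); mb <- colMeans(xb)
    va <- colSums(sweep(xa, 2, ma)^2); vb <- colSums(sweep(xb, 2, mb)^2)
    sp2 <- (va + vb) / (length(ia) + length(ib) - 2)
    se <- sqrt(sp2 * (1 / length(ia) + 1 / length(ib)))
    t <- (ma - mb) / se
    t[se == 0] <- 0
    t
  }
  t_obs <- tstat(ia, ib)
  mask <- matrix(TRUE, 1L, nb)
  obs <- cluster_scores(matrix(abs(t_obs), 1L, nb), threshold_T, mask)
  used <- c(ia, ib)
  set.seed(seed)
  null_max <- numeric(n_perm)
  for (j in seq_len(n_perm)) {
    sh <- sample(used)
    tj <- abs(tstat(sh[seq_along(ia)], sh[-seq_along(ia)]))
    sc <- cluster_scores(matrix(tj, 1L, nb), threshold_T, mask)$scores
    null_max[j] <- if (length(sc)) max(sc) else 0
  }
  k <- length(obs$scores)
  clusters <- data.frame(
    cluster = seq_len(k), score = obs$scores,
    p_corrected = vapply(obs$scores, function(s) {
      (1 + sum(null_max >= s)) / (1 + n_perm)
    }, numeric(1))
  )
  se_of <- function(idx) apply(rate[idx, , drop = FALSE], 2, sd) / sqrt(length(idx))
  structure(
    list(
      time = (breaks[-1] + breaks[-(nb + 1L)]) / 2,
      rate_high = colMeans(rate[ia, , drop = FALSE]),
      rate_low = colMeans(rate[ib, , drop = FALSE]),
      se_high = se_of(ia), se_low = se_of(ib),
      t = t_obs, clusters = clusters[order(clusters$p_corrected), , drop = FALSE],
      bin_labels = obs$labels
    ),
    class = "rate_contrast"
  )
}

#' Spike-field PLV contrast between trial labels
#'
#' Difference of the pooled PLV between spikes from high vs low trials,
#' with a spike-level label-permutation two-sided p-value. Relabelling the
#' groups flips the sign of the difference exactly.
#'
#' @param phases a `phase_sample`.
#' @param labels per-trial labels (the spike's trial determines its group).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param min_spikes warn if either group has fewer spikes than this.
#' @return list: `delta_plv` (high - low), `plv_high`, `plv_low`, `p`.
#' @export
plv_contrast_by_label <- function(phases, labels, n_perm = 1000L, seed = 1L,
                                  min_spikes = 50L) {
  stopifnot(is.data.frame(phases))
  lab_tr <- as_label_vector(labels)
  g <- lab_tr[phases$trial]
  ph <- phases$phase[g %in% c("high", "low")]
  g <- g[g %in% c("high", "low")]
  if (!any(g == "high") || !any(g == "low")) stop_cfg("a label group has no spikes")
  if (min(sum(g == "high"), sum(g == "low")) < min_spikes) {
    warning("fewer than ", min_spikes, " spikes in a group; contrast is noisy")
  }
  z <- exp(1i * ph)
  dplv <- function(gg) {
    Mod(mean(z[gg == "high"])) - Mod(mean(z[gg == "low"]))
  }
  obs <- dplv(g)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(j) dplv(sample(g)), numeric(1))
  list(
    delta_plv = obs,
    plv_high = Mod(mean(z[g == "high"])),
    plv_low = Mod(mean(z[g == "low"])),
    p = (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm),
    n_high = sum(g == "high"), n_low = sum(g == "low")
  )
}
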