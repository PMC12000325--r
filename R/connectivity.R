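#' Debiased weighted phase-lag index
#'
#' Debiased WPLI (imaginary cross-spectrum based, insensitive to zero-lag
#' coupling, with small-sample bias correction) between two channels,
#' estimated from all (trial, window-sample) observations at each frequency:
#' \deqn{dWPLI = \frac{(\sum Im X)^2 - \sum (Im X)^2}
#'                    {(\sum |Im X|)^2 - \sum (Im X)^2}}
#' with \eqn{X = w_1 \bar w_2} the cross-spectrum. The degenerate 0/0 case
#' (all imaginary parts zero, e.g. an exact zero-lag copy) is reported as 0
#' with a flag — zero-lag mixing is precisely what WPLI discounts.
#'
#' @param analytic an `analytic_map` with at least two channels.
#' @param channels `c(seed, target)` channel indices.
#' @param trials trial indices (default all); fewer than 2 is an error,
#'   fewer than 20 a warning.
#' @param window `c(t_min, t_max)` seconds (default the post-movement
#'   0.2-1.2 s window).
#' @param freqs frequencies (default the full analytic grid).
#' @return list of class `connectivity_spectrum`: `freqs`, `wpli`,
#'   `degenerate` flags, `n_trials`, `window`.
#' @export
debiased_wpli <- function(analytic, channels = c(1L, 2L), trials = NULL,
                          window = c(0.2, 1.2), freqs = NULL) {
  stopifnot(inherits(analytic, "analytic_map"))
  d <- dim(analytic$values)
  trials <- trials %||% seq_len(d[1])
  if (length(trials) < 2L) stop_cfg("debiased WPLI undefined for fewer than 2 trials")
  if (length(trials) < 20L) warning("fewer than 20 trials; WPLI estimate is noisy")
  fi <- if (is.null(freqs)) seq_along(analytic$freqs) else {
    match_freqs(freqs, analytic$freqs)
  }
  times <- analytic$times
  wpli <- numeric(length(fi))
  degen <- logical(length(fi))
  for (k in seq_along(fi)) {
    f <- fi[k]
    sel <- which(times >= window[1] & times < window[2] & analytic$valid[f, ])
    if (!length(sel)) {
      wpli[k] <- NA_real_
      degen[k] <- TRUE
      next
    }
    X <- analytic$values[trials, channels[1], f, sel] *
      Conj(analytic$values[trials, channels[2], f, sel])
    im <- Im(X)
    s1 <- sum(im); s2 <- sum(im^2); sa <- sum(abs(im))
    den <- sa^2 - s2
    if (den <= .Machine$double.eps * sa^2 || sa == 0) {
      wpli[k] <- 0
      degen[k] <- TRUE
    } else {
      wpli[k] <- (s1^2 - s2) / den
    }
  }
  structure(
    list(
      freqs = analytic$freqs[fi], wpli = wpli, degenerate = degen,
      n_trials = length(trials), window = window, channels = channels
    ),
    class = "connectivity_spectrum"
  )
}

# Paired t statistic from its definition; two-sided p. Zero-variance
# differences give t = 0 (p = 1) when all differences are zero.
paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  t <- if (s == 0) {
    if (m == 0) 0 else sign(m) * Inf
  } else {
    m / (s / sqrt(n))
  }
  list(t = t, df = n - 1L, p = 2 * pt(-abs(t), n - 1L), mean_diff = m)
}

#' Phase-conditioned connectivity contrast across subjects
#'
#' For each subject, averages seed-to-target debiased WPLI over targets for
#' the optimal-phase and non-optimal-phase trial subsets and contrasts them
#' (optimal minus non-optimal) with a paired t per frequency across
#' subjects. Multiple comparisons across frequencies are handled by a
#' sign-flip cluster permutation (|t| >= `threshold_T`, 1-D adjacency over
#' the frequency grid). Optionally aggregates the contrast over declared
#' macro-groups of targets at `group_freqs` with Bonferroni correction
#' across groups.
#'
#' @param subjects list; each element needs `analytic` (an `analytic_map`)
#'   and `partition` (a [select_phase_trials()] result). At least 3.
#' @param seed_channel seed channel index.
#' @param target_channels target channel indices (default: all but the
#'   seed).
#' @param freqs frequency grid for the contrast (default the analytic
#'   grid of the first subject).
#' @param window WPLI window, seconds.
#' @param groups optional named list mapping group name -> target channel
#'   indices for the macro-group analysis.
#' @param group_freqs frequencies over which group contrasts are averaged
#'   (default 9-12 Hz).
#' @param n_perm sign-flip permutations.
#' @param threshold_T cluster-forming threshold.
#' @param seed integer seed.
#' @param min_trials minimum trials per partition cell per subject.
#' @return list of class `connectivity_contrast`: per-frequency `t`,
#'   per-subject `delta` matrix, `clusters` (corrected p), optional
#'   `group_table` with Bonferroni-corrected p-values.
#' @export
phase_split_connectivity_contrast <- function(subjects, seed_channel = 1L,
                                              target_channels = NULL,
                                              freqs = NULL,
                                              window = c(0.2, 1.2),
                                              groups = NULL,
                                              group_freqs = c(9, 12),
                                              n_perm = 1000L, threshold_T = 2,
                                              seed = 1L, min_trials = 10L) {
  if (length(subjects) < 3L) stop_cfg("paired contrast needs at least 3 subjects")
  a1 <- subjects[[1]]$analytic
  freqs <- freqs %||% a1$freqs
  n_sub <- length(subjects)
  n_f <- length(freqs)
  targ_default <- function(an) setdiff(seq_len(dim(an$values)[2]), seed_channel)
  # per-subject per-target per-frequency contrast
  delta_target <- vector("list", n_sub)
  delta <- matrix(0, n_sub, n_f) # mean over targets
  for (s in seq_len(n_sub)) {
    an <- subjects[[s]]$analytic
    pt_ <- subjects[[s]]$partition
    if (length(pt_$optimal) < min_trials || length(pt_$non_optimal) < min_trials) {
      stop_cfg("subject ", s, " has fewer than ", min_trials,
               " trials in a partition cell")
    }
    targets <- target_channels %||% targ_default(an)
    dt <- matrix(0, length(targets), n_f)
    for (j in seq_along(targets)) {
      w_opt <- suppressWarnings(debiased_wpli(
        an, c(seed_channel, targets[j]), pt_$optimal, window, freqs
      ))
      w_non <- suppressWarnings(debiased_wpli(
        an, c(seed_channel, targets[j]), pt_$non_optimal, window, freqs
      ))
      dt[j, ] <- w_opt$wpli - w_non$wpli
    }
    delta_target[[s]] <- dt
    delta[s, ] <- colMeans(dt)
  }
  tvec <- function(m) {
    mu <- colMeans(m)
    se <- apply(m, 2, sd) / sqrt(nrow(m))
    t <- mu / se
    t[se == 0] <- 0
    t
  }
  t_obs <- tvec(delta)
  mask <- matrix(TRUE, 1L, n_f)
  obs <- cluster_scores(matrix(abs(t_obs), 1L, n_f), threshold_T, mask)
  set.seed(seed)
  null_max <- numeric(n_perm)
  for (j in seq_len(n_perm)) {
    flip <- sample(c(-1, 1), n_sub, replace = TRUE)
    tj <- abs(tvec(delta * flip))
    sc <- cluster_scores(matrix(tj, 1L, n_f), threshold_T, mask)$scores
    null_max[j] <- if (length(sc)) max(sc) else 0
  }
  k <- length(obs$scores)
  clusters <- data.frame(
    cluster = seq_len(k), score = obs$scores,
    p_corrected = vapply(obs$scores, function(s) {
      (1 + sum(null_max >= s)) / (1 + n_perm)
    }, numeric(1)),
    f_min = vapply(seq_len(k), function(i) min(freqs[obs$labels == i]), numeric(1)),
    f_max = vapply(seq_len(k), function(i) max(freqs[obs$labels == i]), numeric(1))
  )
  group_table <- NULL
  if (!is.null(groups)) {
    fsel <- which(freqs >= group_freqs[1] & freqs <= group_freqs[2])
    targets1 <- target_channels %||% targ_default(a1)
    rows <- lapply(names(groups), function(gname) {
      members <- match(groups[[gname]], targets1)
      if (anyNA(members)) stop_cfg("group '", gname, "' references unknown targets")
      gd <- vapply(seq_len(n_sub), function(s) {
        mean(delta_target[[s]][members, fsel, drop = FALSE])
      }, numeric(1))
      tt <- paired_t(gd, rep(0, n_sub))
      data.frame(
        group = gname, mean_delta = mean(gd), t = tt$t, df = tt$df,
        p = tt$p, p_bonferroni = min(1, tt$p * length(groups))
      )
    })
    group_table <- do.call(rbind, rows)
  }
  structure(
    list(
      freqs = freqs, t = t_obs, delta = delta,
      clusters = clusters[order(clusters$p_corrected), , drop = FALSE],
      null_max = null_max, group_table = group_table,
      n_subjects = n_sub, window = window
    ),
    class = "connectivity_contrast"
  )
}

#' Lagged phase coherence between a seed and a target channel
#'
#' For every lag, computes the phase differences
#' `phi_seed(t) - phi_target(t + lag)` over window samples, takes their ITC
#' within each trial and frequency, then averages over trials and
#' frequencies to leave only the lag dependence. The lag of maximal
#' coherence indicates the leading signal: positive peak = seed leads. Peak
#' ties are broken toward lag 0 (and toward the positive lag when |lags|
#' tie).
#'
#' @param analytic an `analytic_map` with both channels.
#' @param seed_channel,target_channel channel indices.
#' @param lags lag grid in seconds (default +/-100 ms in 5 ms steps);
#'   snapped to whole samples.
#' @param freqs frequencies to average over (default 9-12 Hz integers
#'   intersected with the grid, else the full grid).
#' @param window `c(t_min, t_max)` seconds; the window shifted by every lag
#'   must stay inside the valid epoch.
#' @param trials trial indices (default all).
#' @return list of class `lag_coherence_curve`: `lags` (s), `coherence`,
#'   `peak_lag` (s), `freqs`, `window`.
#' @export
lag_phase_coherence <- function(analytic, seed_channel = 1L, target_channel = 2L,
                                lags = seq(-0.1, 0.1, by = 0.005),
                                freqs = NULL, window = c(0.2, 1.2),
                                trials = NULL) {
  stopifnot(inherits(analytic, "analytic_map"))
  fs <- analytic$fs
  d <- dim(analytic$values)
  trials <- trials %||% seq_len(d[1])
  fi <- if (is.null(freqs)) seq_along(analytic$freqs) else {
    match_freqs(freqs, analytic$freqs)
  }
  li <- unique(round(lags * fs))
  lags_s <- li / fs
  times <- analytic$times
  sel <- which(times >= window[1] & times < window[2])
  if (!length(sel)) stop_cfg("empty analysis window")
  if (min(sel) + min(li) < 1L || max(sel) + max(li) > length(times)) {
    stop_cfg("lag range exceeds the epoch margin around the window")
  }
  n_lag <- length(li)
  coh <- matrix(0, n_lag, length(fi))
  for (k in seq_along(fi)) {
    f <- fi[k]
    us <- analytic$values[trials, seed_channel, f, , drop = TRUE]
    ut <- analytic$values[trials, target_channel, f, , drop = TRUE]
    if (is.null(dim(us))) { us <- matrix(us, 1L); ut <- matrix(ut, 1L) }
    us <- us / Mod(us); ut <- ut / Mod(ut)
    for (g in seq_len(n_lag)) {
      D <- us[, sel, drop = FALSE] * Conj(ut[, sel + li[g], drop = FALSE])
      coh[g, k] <- mean(Mod(rowMeans(D)))
    }
  }
  curve <- rowMeans(coh)
  cand <- which(curve >= max(curve) - 1e-12)
  cand <- cand[order(abs(lags_s[cand]), -sign(lags_s[cand]))]
  peak <- lags_s[cand[1]]
  structure(
    list(
      lags = lags_s, coherence = curve, peak_lag = peak,
      freqs = analytic$freqs[fi], window = window, n_trials = length(trials)
    ),
    class = "lag_coherence_curve"
  )
}

#' Paired test of peak-lag shifts between optimal and non-optimal trials
#'
#' Extracts the peak of each subject's lag-coherence curve in optimal and
#' non-optimal phase trials and compares them with a paired t test (computed
#' from its definition). Positive shifts mean the seed leads more strongly
#' in optimal-phase trials. Subjects with a flat curve (no peak) in either
#' condition are excluded with a warning.
#'
#' @param optimal,non_optimal lists of `lag_coherence_curve`s, one per
#'   subject, in matching order (at least 3 subjects).
#' @return list: per-subject peak lags, `diff`, `t`, `df`, `p` (two-sided),
#'   `excluded` subject indices.
#' @export
directionality_shift_test <- function(optimal, non_optimal) {
  if (length(optimal) != length(non_optimal)) {
    stop_cfg("optimal and non-optimal curve lists must have equal length")
  }
  if (length(optimal) < 3L) stop_cfg("need at least 3 subjects")
  flat <- function(cv) diff(range(cv$coherence)) < 1e-12
  excl <- which(vapply(optimal, flat, logical(1)) |
                  vapply(non_optimal, flat, logical(1)))
  if (length(excl)) {
    warning("excluding ", length(excl), " subject(s) with a flat lag curve")
  }
  keep <- setdiff(seq_along(optimal), excl)
  if (length(keep) < 3L) stop_cfg("fewer than 3 subjects with a defined peak")
  po <- vapply(optimal[keep], `[[`, numeric(1), "peak_lag")
  pn <- vapply(non_optimal[keep], `[[`, numeric(1), "peak_lag")
  tt <- paired_t(po, pn)
  list(
    peak_optimal = po, peak_non_optimal = pn, diff = po - pn,
    mean_shift = tt$mean_diff, t = tt$t, df = tt$df, p = tt$p,
    excluded = excl
  )
}
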