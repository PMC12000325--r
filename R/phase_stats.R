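#' Inter-trial coherence
#'
#' Modulus of the mean of amplitude-normalised phase vectors,
#' `|sum(w_i / |w_i|)| / n`: 1 when all phases coincide, ~0 when phases are
#' uniformly dispersed. Amplitude never enters the statistic.
#'
#' @param z complex phase vectors, or numeric angles in radians.
#' @return scalar in `[0, 1]`.
#' @export
itc <- function(z) {
  if (length(z) < 1L) stop_cfg("`z` must contain at least one trial")
  if (is.numeric(z)) z <- exp(1i * z)
  m <- Mod(z)
  if (any(m == 0)) {
    stop_cfg("zero-amplitude (undefined-phase) vector present; mask such trials first")
  }
  Mod(sum(z / m)) / length(z)
}

#' Phase opposition product from two phase sets
#'
#' `POP = ITC_A * ITC_B - ITC_ALL^2` where the ITCs are computed within each
#' condition and over the pooled trials. Large when the two conditions
#' cluster at opposite phases; 0 when the two phase multisets coincide.
#'
#' @param phases_a,phases_b angles (radians) or complex phase vectors of the
#'   two conditions.
#' @return scalar POP in `[-1, 1]`.
#' @export
pop_stat <- function(phases_a, phases_b) {
  za <- if (is.numeric(phases_a)) exp(1i * phases_a) else phases_a / Mod(phases_a)
  zb <- if (is.numeric(phases_b)) exp(1i * phases_b) else phases_b / Mod(phases_b)
  na <- length(za); nb <- length(zb)
  if (na < 1L || nb < 1L) stop_cfg("both conditions must be non-empty")
  sa <- sum(za); sb <- sum(zb)
  itc_a <- Mod(sa) / na
  itc_b <- Mod(sb) / nb
  itc_all <- Mod(sa + sb) / (na + nb)
  itc_a * itc_b - itc_all^2
}

#' Phase opposition product map over frequency and time
#'
#' Computes POP and its constituent ITCs at every (frequency, time) point of
#' an analytic map for one channel, contrasting "high" vs "low" labels.
#'
#' @param analytic an `analytic_map`.
#' @param labels a [label_set()] or character vector (high/low/excluded),
#'   one per trial; excluded trials are dropped.
#' @param channel channel index.
#' @return list of class `pop_map`: matrices `pop`, `itc_all`, `itc_a`,
#'   `itc_b` (frequencies x times), counts `n`, `n_a`, `n_b`, plus `freqs`
#'   and `times`.
#' @export
pop <- function(analytic, labels, channel = 1L) {
  stopifnot(inherits(analytic, "analytic_map"))
  d <- dim(analytic$values)
  lab <- as_label_vector(labels, d[1])
  ia <- which(lab == "high"); ib <- which(lab == "low")
  if (length(ia) < 2L || length(ib) < 2L) {
    stop_cfg("need at least 2 trials per condition")
  }
  u <- unit_phasors(analytic, channel)
  sa <- colSums(u[ia, , drop = FALSE])
  sb <- colSums(u[ib, , drop = FALSE])
  na <- length(ia); nb <- length(ib)
  itc_a <- Mod(sa) / na
  itc_b <- Mod(sb) / nb
  itc_all <- Mod(sa + sb) / (na + nb)
  shape <- c(d[3], d[4])
  structure(
    list(
      pop = matrix(itc_a * itc_b - itc_all^2, shape[1], shape[2]),
      itc_all = matrix(itc_all, shape[1], shape[2]),
      itc_a = matrix(itc_a, shape[1], shape[2]),
      itc_b = matrix(itc_b, shape[1], shape[2]),
      n = na + nb, n_a = na, n_b = nb,
      freqs = analytic$freqs, times = analytic$times
    ),
    class = "pop_map"
  )
}

# trials x (freq*time) matrix of unit phasors for one channel.
unit_phasors <- function(analytic, channel) {
  d <- dim(analytic$values)
  v <- analytic$values[, channel, , , drop = FALSE]
  dim(v) <- c(d[1], d[3] * d[4])
  m <- Mod(v)
  if (any(m == 0)) {
    stop_cfg("zero-amplitude samples in analytic map; phase undefined")
  }
  v / m
}

#' Optimal phase angle from high- and low-condition phases
#'
#' Circular mean of the high-condition mean angle and the antiphase of the
#' low-condition mean angle, averaging the two direction estimates as unit
#' vectors (no weighting by trial count or resultant length).
#'
#' @param high_phases,low_phases angles in radians.
#' @return optimal angle in `(-pi, pi]`.
#' @export
optimal_phase_angle <- function(high_phases, low_phases) {
  mh <- circ_mean(high_phases)
  ml <- circ_mean(low_phases)
  circ_mean(c(mh, wrap_angle(ml + pi)))
}

#' Partition trials into optimal and non-optimal phase groups
#'
#' Optimal trials lie strictly within `half_width` of `optimal_angle`;
#' non-optimal trials strictly within `half_width` of the antiphase
#' `optimal_angle + pi`. Boundary trials (distance exactly equal to
#' `half_width`) and all others are excluded. With uniform phases and the
#' default pi/3 half-width each group captures about one third of trials.
#'
#' @param phases per-trial angles, radians.
#' @param optimal_angle centre of the optimal window, radians.
#' @param half_width window half-width, radians (default pi/3).
#' @return list of class `phase_partition` with integer index vectors
#'   `optimal`, `non_optimal`, `excluded`, plus the window parameters.
#' @export
select_phase_trials <- function(phases, optimal_angle, half_width = pi / 3) {
  d_opt <- circular_distance(phases, optimal_angle)
  d_non <- circular_distance(phases, optimal_angle + pi)
  opt <- which(d_opt < half_width)
  non <- which(d_non < half_width)
  structure(
    list(
      optimal = opt, non_optimal = non,
      excluded = setdiff(seq_along(phases), c(opt, non)),
      optimal_angle = wrap_angle(optimal_angle), half_width = half_width
    ),
    class = "phase_partition"
  )
}

#' Outcome probability binned by circular distance from a reference phase
#'
#' Bins trials by the circular distance of their phase from
#' `reference_angle` (equal-width bins spanning `[0, pi]`) and reports the
#' per-bin probability of a positive outcome with Clopper-Pearson 66%
#' binomial confidence intervals. Empty bins yield `NA` and are flagged.
#'
#' @param phases per-trial angles, radians.
#' @param outcomes binary outcomes (0/1 or logical), one per trial.
#' @param n_bins number of distance bins (>= 2).
#' @param reference_angle reference (optimal) phase, radians.
#' @param conf confidence level for the binomial interval.
#' @return data.frame: bin centre (distance, radians), n, successes,
#'   probability, ci_lower, ci_upper, empty flag.
#' @export
phase_binned_outcome_probability <- function(phases, outcomes, n_bins = 6L,
                                             reference_angle = 0, conf = 0.66) {
  if (n_bins < 2L) stop_cfg("`n_bins` must be >= 2")
  y <- as.integer(outcomes)
  stopifnot(length(y) == length(phases), all(y %in% c(0L, 1L)))
  d <- circular_distance(phases, reference_angle)
  breaks <- seq(0, pi, length.out = n_bins + 1L)
  bin <- pmin(findInterval(d, breaks, rightmost.closed = TRUE), n_bins)
  n <- tabulate(bin, n_bins)
  succ <- vapply(seq_len(n_bins), function(b) sum(y[bin == b]), integer(1))
  p <- ifelse(n > 0, succ / n, NA_real_)
  ci <- matrix(NA_real_, n_bins, 2L)
  nz <- n > 0
  if (any(nz)) ci[nz, ] <- binom_ci(succ[nz], n[nz], conf)
  data.frame(
    distance = (breaks[-1] + breaks[-(n_bins + 1L)]) / 2,
    n = n, successes = succ, probability = p,
    ci_lower = ci[, 1], ci_upper = ci[, 2], empty = !nz
  )
}

#' Bootstrap contrast of matched vs mismatched circular distances
#'
#' For two experiments A and B, each with high/low phase sets per timepoint,
#' compares the "matched" distance (mean of d(A_high, B_high) and
#' d(A_low, B_low), distances between resultant-mean angles) with the
#' "mismatched" distance (A_high vs B_low and A_low vs B_high). Standard
#' errors and two-sided p-values per timepoint come from resampling trials
#' with replacement.
#'
#' @param a_high,a_low,b_high,b_low phase matrices `trials x timepoints`
#'   (vectors are treated as a single timepoint).
#' @param n_boot bootstrap resamples (warning below 100).
#' @param seed integer seed.
#' @return list with per-timepoint `matched`, `mismatched`, standard errors
#'   and two-sided bootstrap `p`.
#' @export
bootstrap_circular_distance_contrast <- function(a_high, a_low, b_high, b_low,
                                                 n_boot = 1000L, seed = 1L) {
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 1L)
  ah <- as_mat(a_high); al <- as_mat(a_low)
  bh <- as_mat(b_high); bl <- as_mat(b_low)
  ntp <- ncol(ah)
  stopifnot(ncol(al) == ntp, ncol(bh) == ntp, ncol(bl) == ntp)
  if (min(nrow(ah), nrow(al), nrow(bh), nrow(bl)) < 1L) {
    stop_cfg("all four phase sets must be non-empty")
  }
  if (n_boot < 100L) warning("fewer than 100 bootstrap resamples; p-values unstable")
  mean_ang <- function(m, idx) {
    vapply(seq_len(ncol(m)), function(j) Arg(sum(exp(1i * m[idx, j]))), numeric(1))
  }
  contrast <- function(ih, il, jh, jl) {
    mah <- mean_ang(ah, ih); mal <- mean_ang(al, il)
    mbh <- mean_ang(bh, jh); mbl <- mean_ang(bl, jl)
    matched <- (circular_distance(mah, mbh) + circular_distance(mal, mbl)) / 2
    mismatched <- (circular_distance(mah, mbl) + circular_distance(mal, mbh)) / 2
    list(matched = matched, mismatched = mismatched)
  }
  obs <- contrast(seq_len(nrow(ah)), seq_len(nrow(al)),
                  seq_len(nrow(bh)), seq_len(nrow(bl)))
  set.seed(seed)
  bm <- matrix(0, n_boot, ntp); bx <- matrix(0, n_boot, ntp)
  for (b in seq_len(n_boot)) {
    r <- contrast(
      sample.int(nrow(ah), replace = TRUE), sample.int(nrow(al), replace = TRUE),
      sample.int(nrow(bh), replace = TRUE), sample.int(nrow(bl), replace = TRUE)
    )
    bm[b, ] <- r$matched; bx[b, ] <- r$mismatched
  }
  dif <- bx - bm
  p_lo <- (1 + colSums(dif <= 0)) / (n_boot + 1)
  p_hi <- (1 + colSums(dif >= 0)) / (n_boot + 1)
  list(
    matched = obs$matched, mismatched = obs$mismatched,
    se_matched = apply(bm, 2, sd), se_mismatched = apply(bx, 2, sd),
    p = pmin(1, 2 * pmin(p_lo, p_hi))
  )
}

#' Remove the linear effect of movement delay from agency ratings
#'
#' Residuals of a within-participant least-squares straight-line fit of
#' rating on delay. With constant delays the fit is degenerate and residuals
#' reduce to mean-centred ratings (flagged via the `degenerate` attribute).
#'
#' @param ratings numeric ratings (e.g. 1-9).
#' @param delays go-cue to movement delays, seconds.
#' @return residual ratings, with attributes `slope` and `degenerate`.
#' @export
detrend_ratings_by_delay <- function(ratings, delays) {
  if (length(ratings) < 3L) stop_cfg("need at least 3 trials to detrend")
  stopifnot(length(ratings) == length(delays))
  if (sd(delays) == 0) {
    out <- ratings - mean(ratings)
    attr(out, "slope") <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fit <- lm(ratings ~ delays)
  out <- as.numeric(resid(fit))
  attr(out, "slope") <- unname(coef(fit)[2])
  attr(out, "degenerate") <- FALSE
  out
}

#' Split detrended ratings into extreme-third high/low labels
#'
#' The highest `frac` of ratings become "high", the lowest `frac` "low", the
#' middle is excluded. Ties are broken by original trial order.
#'
#' @param ratings numeric (typically delay-detrended) ratings.
#' @param frac fraction per extreme (default 1/3).
#' @return a [label_set()] carrying the ratings.
#' @export
split_rating_extremes <- function(ratings, frac = 1 / 3) {
  n <- length(ratings)
  k <- floor(n * frac)
  if (k < 2L) stop_cfg("too few trials for an extreme split")
  ord <- order(ratings) # ties: original order
  lab <- rep("excluded", n)
  lab[ord[seq_len(k)]] <- "low"
  lab[ord[(n - k + 1L):n]] <- "high"
  label_set(lab, rating = ratings)
}
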