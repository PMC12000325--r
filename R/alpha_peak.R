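#' Fit the 1/f background of a power spectrum
#'
#' Least-squares straight line in log-power vs log-frequency over the fit
#' range (default 5-30 Hz); the residual is the raw power minus the
#' back-transformed power-law background `a * f^-b`.
#'
#' @param spectrum a [trial_power_spectrum()] result (or a list with `freq`
#'   and `power`).
#' @param range fit range `c(f_lo, f_hi)` Hz; needs >= 10 bins.
#' @return list of class `spectrum_fit`: `freq`, `power`, `background`,
#'   `residual` (all on the fit range), `amplitude`, `exponent`, `range`.
#' @export
fit_background_one_over_f <- function(spectrum, range = c(5, 30)) {
  keep <- spectrum$freq >= range[1] - 1e-9 & spectrum$freq <= range[2] + 1e-9 &
    spectrum$freq > 0
  f <- spectrum$freq[keep]
  p <- spectrum$power[keep]
  if (length(f) < 10L) stop_cfg("need at least 10 frequency bins in the fit range")
  if (any(p <= 0)) stop_cfg("non-positive power bins in the fit range")
  fit <- lm(log(p) ~ log(f))
  bg <- exp(fitted(fit))
  structure(
    list(
      freq = f, power = p, background = as.numeric(bg),
      residual = p - as.numeric(bg),
      amplitude = exp(unname(coef(fit)[1])),
      exponent = -unname(coef(fit)[2]),
      range = range
    ),
    class = "spectrum_fit"
  )
}

#' Individual alpha peak from a 1/f-corrected spectrum
#'
#' The alpha peak is the point of maximum convexity of the residual
#' (background-subtracted) power in the alpha band: the interior local
#' maximum with the most negative discrete second difference, after light
#' smoothing (default 3-bin moving average). Band-edge maxima are rejected.
#' A candidate must also be prominent — its residual must exceed
#' `min_prominence` robust standard deviations of the out-of-band residual
#' (the estimator's definition of a genuine bump, as opposed to spectral
#' estimation noise). If no such peak exists the result is `NA` ("no peak").
#'
#' @param fit a [fit_background_one_over_f()] result.
#' @param band search band `c(f_lo, f_hi)` Hz (default 8-13), inside the
#'   fit range.
#' @param smooth moving-average window (bins) applied before differencing.
#' @param min_prominence prominence threshold in robust (MAD-based) SDs of
#'   the residual outside the band.
#' @return peak frequency in Hz, or `NA_real_` when no peak exists.
#' @export
individual_alpha_peak <- function(fit, band = c(8, 13), smooth = 3L,
                                  min_prominence = 4) {
  stopifnot(inherits(fit, "spectrum_fit"))
  if (band[1] < fit$range[1] - 1e-9 || band[2] > fit$range[2] + 1e-9) {
    stop_cfg("`band` must lie within the background fit range")
  }
  r <- moving_average(fit$residual, smooth)
  n <- length(r)
  inband <- which(fit$freq > band[1] & fit$freq < band[2]) # open interior
  inband <- inband[inband > 1L & inband < n]
  if (!length(inband)) return(NA_real_)
  is_max <- r[inband] > r[inband - 1L] & r[inband] >= r[inband + 1L]
  cand <- inband[is_max]
  if (!length(cand)) return(NA_real_)
  # prominence on the relative residual (power/background - 1), whose
  # estimation noise is homoscedastic across frequency
  rr <- moving_average(fit$residual / fit$background, smooth)
  out_band <- fit$freq < band[1] | fit$freq > band[2]
  scale <- stats::mad(rr[out_band])
  cand <- cand[rr[cand] > max(min_prominence * scale, 1e-6)]
  if (!length(cand)) return(NA_real_)
  d2 <- r[cand + 1L] - 2 * r[cand] + r[cand - 1L]
  fit$freq[cand[which.min(d2)]]
}

#' Per-subject frequency of strongest phase opposition
#'
#' Averages the observed statistic (POP) over the time window within each
#' frequency, computes its permutation p-value against the identically
#' window-averaged null maps, and returns the frequency of minimum p.
#' When the permutation count saturates several frequencies at the minimal
#' attainable p, ties are broken by the larger window-averaged observed
#' statistic, then by the lower frequency. The `significant` attribute
#' flags whether the winning frequency reached p < 0.05 (under a flat null
#' the returned frequency is a seed-dependent pick).
#'
#' @param perm_result a [permutation_pvalues()] result.
#' @param time_window `c(t_min, t_max)` seconds (default the pre-movement
#'   half second).
#' @return frequency (Hz) with attributes `significant` and `p` (the
#'   per-frequency p-value of the winner).
#' @export
peak_pop_frequency <- function(perm_result, time_window = c(-0.5, 0)) {
  stopifnot(inherits(perm_result, "permutation_result"))
  tm <- perm_result$times >= time_window[1] & perm_result$times < time_window[2]
  if (!any(tm)) stop_cfg("empty time window")
  nf <- length(perm_result$freqs)
  obs <- rowMeans(perm_result$observed[, tm, drop = FALSE])
  # window-average each null map the same way
  n_perm <- perm_result$n_perm
  null <- perm_result$null # n_perm x (nf*nt)
  dim(null) <- c(n_perm, nf, length(perm_result$times))
  null_stat <- apply(null[, , tm, drop = FALSE], c(1, 2), mean)
  pf <- vapply(seq_len(nf), function(f) {
    (1 + sum(null_stat[, f] >= obs[f])) / (1 + n_perm)
  }, numeric(1))
  best <- order(pf, -obs, perm_result$freqs)[1]
  out <- perm_result$freqs[best]
  attr(out, "significant") <- pf[best] < 0.05
  attr(out, "p") <- pf[best]
  out
}

#' Regression of POP-peak frequency on individual alpha peak
#'
#' Least-squares line and Pearson correlation between the per-subject alpha
#' peak and the per-subject frequency of strongest phase opposition.
#'
#' @param alpha_peaks per-subject alpha peaks, Hz (NA allowed; pairs with
#'   any NA are dropped).
#' @param pop_peaks per-subject POP-peak frequencies, Hz.
#' @return list: `slope`, `intercept`, `correlation`, `n`.
#' @export
peak_alignment_regression <- function(alpha_peaks, pop_peaks) {
  stopifnot(length(alpha_peaks) == length(pop_peaks))
  keep <- complete.cases(alpha_peaks, pop_peaks)
  x <- alpha_peaks[keep]
  y <- as.numeric(pop_peaks[keep])
  if (length(x) < 3L) stop_cfg("need at least 3 subjects with defined peaks")
  fit <- lm(y ~ x)
  list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    correlation = stats::cor(x, y),
    n = length(x)
  )
}
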