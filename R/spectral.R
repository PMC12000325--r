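#' Analytic map container
#'
#' Complex `trials x channels x frequencies x samples` array: modulus is
#' instantaneous amplitude, argument is instantaneous phase. Carries the
#' frequency grid, the time axis of the source trials and a per-(frequency,
#' sample) validity mask flagging edge-contaminated samples.
#'
#' @keywords internal
new_analytic_map <- function(values, freqs, times, fs, method, valid, params = list()) {
  structure(
    list(
      values = values, freqs = freqs, times = times, fs = fs,
      method = method, valid = valid, params = params
    ),
    class = "analytic_map"
  )
}

#' @export
print.analytic_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<analytic_map:%s> %d trials x %d channels x %d freqs x %d samples (%g-%g Hz)\n",
    x$method, d[1], d[2], d[3], d[4], min(x$freqs), max(x$freqs)
  ))
  invisible(x)
}

# FFT convolution of every column of `x` (samples x series) with complex
# kernel `h`; returns the centred (mode = "same") or causal (mode = "causal")
# portion aligned with the input samples.
fft_convolve <- function(x, h, mode = c("same", "causal")) {
  mode <- match.arg(mode)
  ns <- nrow(x)
  L <- length(h)
  nfft <- nextn(ns + L - 1L, 2)
  H <- fft(c(h, rep(0, nfft - L)))
  X <- mvfft(rbind(x, matrix(0, nfft - ns, ncol(x))))
  y <- mvfft(X * H, inverse = TRUE) / nfft
  if (mode == "same") {
    half <- (L - 1L) %/% 2L
    y[(half + 1L):(half + ns), , drop = FALSE]
  } else {
    y[seq_len(ns), , drop = FALSE]
  }
}

#' Morlet wavelet analytic signal extraction
#'
#' Convolves each trial/channel with complex Morlet wavelets. The wavelet at
#' frequency f has Gaussian envelope SD `n_cycles / (2 * pi * f)` in time;
#' the default width of `2 * pi` cycles (about 6.28) matches the LFP
#' analysis, `4 * pi` the lower-SNR EEG variant. Amplitude is normalised so
#' that a pure sinusoid of amplitude A yields modulus A at its frequency.
#' Samples closer than 3.5 envelope SDs to either epoch edge are flagged
#' invalid in the per-frequency mask.
#'
#' @param trials a [trial_set()].
#' @param freqs frequency grid, Hz; default 10 linearly spaced frequencies
#'   from 4 to 13 Hz.
#' @param n_cycles wavelet width in cycles (positive scalar).
#' @return an `analytic_map` with method `"morlet"`.
#' @export
morlet_analytic <- function(trials, freqs = seq(4, 13, length.out = 10),
                            n_cycles = 2 * pi) {
  stopifnot(inherits(trials, "trial_set"))
  if (any(freqs <= 0)) stop_cfg("frequencies must be positive")
  if (n_cycles <= 0) stop_cfg("`n_cycles` must be positive")
  fs <- trials$fs
  d <- dim(trials$data)
  ns <- d[3]
  nf <- length(freqs)
  x <- matrix(aperm(trials$data, c(3, 1, 2)), nrow = ns) # samples x (trials*channels)
  values <- array(complex(real = 0), dim = c(d[1], d[2], nf, ns))
  valid <- matrix(FALSE, nf, ns)
  for (k in seq_len(nf)) {
    f <- freqs[k]
    sigma <- n_cycles / (2 * pi * f)
    hw <- ceiling(3.5 * sigma * fs)
    if (2L * hw + 1L > ns) {
      stop_cfg(sprintf("wavelet at %.3g Hz (%.3g s support) exceeds the epoch", f,
                       (2 * hw + 1) / fs))
    }
    tw <- (-hw:hw) / fs
    env <- exp(-tw^2 / (2 * sigma^2))
    w <- (2 / sum(env)) * env * exp(1i * 2 * pi * f * tw)
    w <- w - sum(w) / length(w) # zero DC gain: offsets cannot leak into phase
    y <- fft_convolve(x, w, mode = "same")
    values[, , k, ] <- aperm(array(t(y), dim = c(d[1], d[2], ns)), c(1, 2, 3))
    valid[k, ] <- seq_len(ns) > hw & seq_len(ns) <= ns - hw
  }
  new_analytic_map(values, freqs, trial_times(trials), fs, "morlet", valid,
                   params = list(n_cycles = n_cycles))
}

#' Causal band-pass analytic signal extraction
#'
#' One-pass complex FIR demodulation: a linear-phase low-pass prototype
#' (Hamming-windowed, via [signal::fir1()]) modulated to the band centre,
#' applied as a strictly causal convolution. The output phase at time t
#' therefore depends only on samples at or before t, and tracks the
#' band-centre phase with a fixed group delay of `order / (2 * fs)` seconds
#' (reported in `params$group_delay_s`). The first `order` samples (filter
#' startup) are flagged invalid.
#'
#' @param trials a [trial_set()].
#' @param band `c(f_lo, f_hi)` Hz, inside (0, fs/2).
#' @param order FIR order (even); default two cycles of `f_lo`.
#' @return an `analytic_map` with method `"causal_hilbert"` and a single
#'   frequency at the band centre.
#' @export
causal_analytic <- function(trials, band = c(8, 13), order = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  fs <- trials$fs
  if (length(band) != 2L || band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2]) {
    stop_cfg("`band` must satisfy 0 < f_lo < f_hi < fs/2")
  }
  d <- dim(trials$data)
  ns <- d[3]
  order <- order %||% (2L * round(fs / band[1]))
  if (order %% 2L != 0L) order <- order + 1L
  if (order + 1L > ns) stop_cfg("filter longer than the epoch; reduce `order`")
  fc <- mean(band)
  h_lp <- signal::fir1(order, (band[2] - band[1]) / 2 / (fs / 2), type = "low")
  k <- 0:order
  # modulation centred on the filter midpoint: the output is a pure
  # group-delay time shift of the analytic band-passed input
  h <- 2 * h_lp * exp(1i * 2 * pi * fc * (k - order / 2) / fs)
  x <- matrix(aperm(trials$data, c(3, 1, 2)), nrow = ns)
  y <- fft_convolve(x, h, mode = "causal")
  values <- array(complex(real = 0), dim = c(d[1], d[2], 1L, ns))
  values[, , 1L, ] <- aperm(array(t(y), dim = c(d[1], d[2], ns)), c(1, 2, 3))
  valid <- matrix(seq_len(ns) > order, 1L, ns)
  new_analytic_map(
    values, fc, trial_times(trials), fs, "causal_hilbert", valid,
    params = list(band = band, order = order, group_delay_s = order / 2 / fs)
  )
}

#' Subset an analytic map by frequency and/or time
#'
#' @param map an `analytic_map`.
#' @param freqs frequencies to keep (matched to the grid); NULL keeps all.
#' @param times times to keep; NULL keeps all.
#' @param time_decim keep every `time_decim`-th sample (applied after
#'   `times`).
#' @return the subsetted `analytic_map`.
#' @export
subset_analytic <- function(map, freqs = NULL, times = NULL, time_decim = 1L) {
  fi <- if (is.null(freqs)) seq_along(map$freqs) else {
    idx <- match_freqs(freqs, map$freqs)
    idx
  }
  ti <- seq_along(map$times)
  if (!is.null(times)) ti <- ti[map$times >= times[1] & map$times <= times[2]]
  if (time_decim > 1L) ti <- ti[seq(1L, length(ti), by = time_decim)]
  new_analytic_map(
    map$values[, , fi, ti, drop = FALSE], map$freqs[fi], map$times[ti],
    map$fs, map$method, map$valid[fi, ti, drop = FALSE], map$params
  )
}

match_freqs <- function(freqs, grid, tol = 1e-6) {
  idx <- vapply(freqs, function(f) {
    j <- which(abs(grid - f) < tol)
    if (!length(j)) stop_cfg(sprintf("frequency %g Hz not on the analytic grid", f))
    j[1]
  }, integer(1))
  idx
}

#' Trial-averaged power spectrum
#'
#' Periodogram per trial and channel (mean removed), averaged over trials
#' and channels. The native resolution fs/n_samples must be at most 0.5 Hz.
#'
#' @param trials a [trial_set()].
#' @param range `c(f_lo, f_hi)` Hz to retain; must be within Nyquist.
#' @param channels channel indices to average (default all).
#' @return list of class `power_spectrum` with `freq` (Hz) and `power`
#'   (a.u.^2/Hz).
#' @export
trial_power_spectrum <- function(trials, range = NULL, channels = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  fs <- trials$fs
  d <- dim(trials$data)
  ns <- d[3]
  if (fs / ns > 0.5 + 1e-9) {
    stop_cfg("epoch too short: spectral resolution coarser than 0.5 Hz")
  }
  range <- range %||% c(fs / ns, fs / 2)
  if (range[2] > fs / 2 + 1e-9) stop_cfg("`range` exceeds the Nyquist frequency")
  channels <- channels %||% seq_len(d[2])
  x <- matrix(aperm(trials$data[, channels, , drop = FALSE], c(3, 1, 2)), nrow = ns)
  x <- sweep(x, 2, colMeans(x))
  P <- Mod(mvfft(x))^2 / (ns * fs)
  nk <- floor(ns / 2) + 1L
  freq <- (seq_len(nk) - 1L) * fs / ns
  power <- rowMeans(P[seq_len(nk), , drop = FALSE])
  keep <- freq >= range[1] - 1e-9 & freq <= range[2] + 1e-9
  structure(list(freq = freq[keep], power = power[keep], fs = fs),
            class = "power_spectrum")
}
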