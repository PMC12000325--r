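#' Configuration for phase-coded synthetic trials
#'
#' Describes a two-condition experiment in which a planted oscillation at
#' `f0` has its instantaneous phase at the pre-movement time `t_lock` drawn
#' from a von Mises distribution: centre `mu_high` for condition "high" and
#' `mu_high + pi` (pure phase opposition) for condition "low". The
#' oscillation rides on 1/f background noise.
#'
#' @param n_trials_per_condition trials per condition (balanced design).
#' @param n_channels number of channels; the oscillation phase is shared
#'   across channels of a trial, noise is channel-independent.
#' @param fs sampling rate, Hz.
#' @param epoch `c(t_start, t_end)` seconds, movement onset at t = 0;
#'   requires `t_start < t_lock < 0 <= t_end`.
#' @param f0 planted frequency, Hz.
#' @param t_lock planted (pre-movement, negative) time at which the phase is
#'   pinned, seconds.
#' @param mu_high phase centre of condition "high" at `(f0, t_lock)`, radians.
#' @param kappa von Mises concentration (>= 0); 0 plants no effect.
#' @param osc_amplitude oscillation amplitude (a.u.).
#' @param noise_exponent spectral exponent of the 1/f background.
#' @param noise_amplitude noise standard deviation (a.u.).
#' @param seed integer seed; all draws come from one generator seeded here.
#' @return a validated list of class `synth_trial_config`.
#' @export
synth_trial_config <- function(n_trials_per_condition = 100L, n_channels = 1L,
                               fs = 250, epoch = c(-1.5, 1), f0 = 8,
                               t_lock = -0.256, mu_high = 3 * pi / 4, kappa = 5,
                               osc_amplitude = 1, noise_exponent = 1,
                               noise_amplitude = 1, seed = 1L) {
  cfg <- list(
    n_trials_per_condition = as.integer(n_trials_per_condition),
    n_channels = as.integer(n_channels), fs = fs, epoch = epoch, f0 = f0,
    t_lock = t_lock, mu_high = mu_high, kappa = kappa,
    osc_amplitude = osc_amplitude, noise_exponent = noise_exponent,
    noise_amplitude = noise_amplitude, seed = as.integer(seed)
  )
  if (cfg$fs <= 0) stop_cfg("`fs` must be positive")
  if (length(epoch) != 2L || epoch[1] >= epoch[2]) {
    stop_cfg("`epoch` must be c(t_start, t_end) with t_start < t_end")
  }
  if (!(epoch[1] < t_lock && t_lock < 0 && 0 <= epoch[2])) {
    stop_cfg("invalid epoch bounds: need t_start < t_lock < 0 <= t_end")
  }
  if (kappa < 0) stop_cfg("`kappa` must be >= 0")
  if (f0 <= 0) stop_cfg("`f0` must be positive")
  if (osc_amplitude < 0 || noise_amplitude < 0) {
    stop_cfg("amplitudes must be non-negative")
  }
  class(cfg) <- "synth_trial_config"
  cfg
}

# 1/f^exponent noise by spectral shaping of white noise; columns are
# independent series, each standardised to unit variance.
one_over_f_noise <- function(n, fs, exponent = 1, n_series = 1L) {
  w <- matrix(rnorm(n * n_series), n, n_series)
  if (exponent == 0) return(w)
  k <- seq_len(n) - 1L
  f <- fs * pmin(k, n - k) / n
  g <- c(0, 1 / f[-1]^(exponent / 2)) # zero out DC
  x <- Re(mvfft(mvfft(w) * g, inverse = TRUE)) / n
  s <- apply(x, 2, sd)
  sweep(x, 2, ifelse(s > 0, s, 1), "/")
}

# Time grid guaranteed to contain t = 0 exactly.
epoch_times <- function(epoch, fs) {
  (round(epoch[1] * fs):round(epoch[2] * fs)) / fs
}

#' Generate phase-coded trials with a planted phase opposition
#'
#' Each trial is 1/f noise plus a sinusoid at `f0` whose phase at
#' `(f0, t_lock)` is von Mises around `mu_high` for "high" trials and around
#' `mu_high + pi` for "low" trials. The oscillation is continuous across the
#' whole epoch with the phase pinned at `t_lock` (constant-frequency
#' back-propagation), so the planted effect lives at a known
#' (frequency, time) point. Labels are exactly balanced.
#'
#' @param cfg a [synth_trial_config()].
#' @return list with elements `trials` (a [trial_set()] whose `truth` field
#'   records the per-trial locked phase and all planted parameters) and
#'   `labels` (a [label_set()]).
#' @export
make_phase_coded_trials <- function(cfg) {
  stopifnot(inherits(cfg, "synth_trial_config"))
  set.seed(cfg$seed)
  n <- cfg$n_trials_per_condition
  tt <- epoch_times(cfg$epoch, cfg$fs)
  ns <- length(tt)
  nt <- 2L * n
  phase <- c(
    rvonmises(n, cfg$mu_high, cfg$kappa),
    rvonmises(n, wrap_angle(cfg$mu_high + pi), cfg$kappa)
  )
  labels <- rep(c("high", "low"), each = n)
  data <- array(0, dim = c(nt, cfg$n_channels, ns))
  # planted oscillation: phase(t) = 2*pi*f0*(t - t_lock) + phase_i
  osc <- outer(phase, 2 * pi * cfg$f0 * (tt - cfg$t_lock), `+`)
  osc <- cfg$osc_amplitude * cos(osc) # nt x ns
  for (ch in seq_len(cfg$n_channels)) {
    noise <- t(one_over_f_noise(ns, cfg$fs, cfg$noise_exponent, nt))
    data[, ch, ] <- osc + cfg$noise_amplitude * noise
  }
  ts <- trial_set(
    data, cfg$fs, t0_index = which(tt == 0),
    truth = list(
      f0 = cfg$f0, t_lock = cfg$t_lock, mu_high = cfg$mu_high,
      kappa = cfg$kappa, phase_at_lock = phase, label = labels,
      seed = cfg$seed
    )
  )
  list(trials = ts, labels = label_set(labels))
}

#' Draw binary agency labels from trial phases through a cosine link
#'
#' `P(high | phase) = p0 + beta * cos(phase - phi_opt)`: the probability of a
#' "high" outcome is maximal at the optimal phase `phi_opt` and minimal at
#' its antiphase.
#'
#' @param phases per-trial phases, radians.
#' @param p0 base probability.
#' @param beta modulation depth; `p0 +/- beta` must stay in `[0, 1]`.
#' @param phi_opt optimal phase, radians.
#' @param seed integer seed.
#' @return a [label_set()] with an additional integer `outcome` column (1 =
#'   high agency reported).
#' @export
make_agency_labels_from_phase <- function(phases, p0 = 0.5, beta = 0.3,
                                          phi_opt = 0, seed = 1L) {
  if (p0 + beta > 1 + 1e-12 || p0 - beta < -1e-12) {
    stop_cfg("link probability p0 +/- beta outside [0, 1]")
  }
  set.seed(seed)
  p <- pmin(1, pmax(0, p0 + beta * cos(phases - phi_opt)))
  y <- rbinom(length(phases), 1L, p)
  out <- label_set(ifelse(y == 1L, "high", "low"))
  out$outcome <- y
  out
}

#' Configuration for phase-modulated Poisson spiking
#'
#' @param base_rate mean firing rate, Hz (>= 0).
#' @param mod_depth modulation depth m in `[0, 1]`: the rate is
#'   `base_rate * (1 + m * cos(phase - preferred_phase))`.
#' @param preferred_phase phase of maximal firing, radians.
#' @param n_units number of units.
#' @param seed integer seed.
#' @return list of class `spike_synth_config`.
#' @export
spike_synth_config <- function(base_rate = 20, mod_depth = 0.5,
                               preferred_phase = 4 * pi / 3, n_units = 20L,
                               seed = 1L) {
  if (base_rate < 0) stop_cfg("`base_rate` must be >= 0")
  if (mod_depth < 0 || mod_depth > 1) stop_cfg("`mod_depth` must be in [0, 1]")
  structure(
    list(
      base_rate = base_rate, mod_depth = mod_depth,
      preferred_phase = wrap_angle(preferred_phase),
      n_units = as.integer(n_units), seed = as.integer(seed)
    ),
    class = "spike_synth_config"
  )
}

#' Generate spike trains phase-coupled to the planted oscillation
#'
#' Inhomogeneous Poisson process per (unit, trial) with instantaneous rate
#' `base_rate * (1 + m * cos(phi(t) - preferred_phase))`, where `phi(t)` is
#' the planted oscillation phase of that trial (from the `truth` metadata of
#' a [make_phase_coded_trials()] trial set). Simulated by thinning.
#'
#' @param trials a `trial_set` carrying planted truth.
#' @param cfg a [spike_synth_config()].
#' @param f0 oscillation frequency; defaults to the planted `truth$f0`.
#' @return a `data.frame` of class `spike_train_set` with columns `unit`,
#'   `trial`, `time_s` (relative to movement onset).
#' @export
make_spike_trains <- function(trials, cfg, f0 = NULL) {
  stopifnot(inherits(trials, "trial_set"), inherits(cfg, "spike_synth_config"))
  truth <- trials$truth
  if (is.null(truth$phase_at_lock)) {
    stop_cfg("`trials` carries no planted phase truth; generate with make_phase_coded_trials()")
  }
  f0 <- f0 %||% truth$f0
  set.seed(cfg$seed)
  tt <- trial_times(trials)
  t0 <- tt[1]; t1 <- tt[length(tt)]
  len <- t1 - t0
  if (cfg$base_rate * len < 1) {
    warning("expected spike count per trial below 1; spike statistics will be noisy")
  }
  nt <- dim(trials)[1]
  lmax <- cfg$base_rate * (1 + cfg$mod_depth)
  res <- vector("list", cfg$n_units * nt)
  k <- 0L
  for (u in seq_len(cfg$n_units)) {
    for (tr in seq_len(nt)) {
      n_cand <- rpois(1L, lmax * len)
      if (n_cand == 0L) next
      tc <- sort(runif(n_cand, t0, t1))
      phi <- 2 * pi * f0 * (tc - truth$t_lock) + truth$phase_at_lock[tr]
      rate <- cfg$base_rate * (1 + cfg$mod_depth * cos(phi - cfg$preferred_phase))
      keep <- runif(n_cand) < rate / lmax
      if (!any(keep)) next
      k <- k + 1L
      res[[k]] <- data.frame(unit = u, trial = tr, time_s = tc[keep])
    }
  }
  out <- if (k > 0L) do.call(rbind, res[seq_len(k)]) else {
    data.frame(unit = integer(), trial = integer(), time_s = numeric())
  }
  rownames(out) <- NULL
  attr(out, "truth") <- c(cfg, list(f0 = f0))
  class(out) <- c("spike_train_set", "data.frame")
  out
}

#' Configuration for a phase-gated coupled source pair
#'
#' Two oscillatory channels ("seed", "target") whose lagged coupling
#' direction depends on the seed's pre-movement phase: trials whose seed
#' phase at `t_lock` falls within pi/3 of `gate_phase` couple seed -> target
#' at `+coupling_lag`; all other trials couple target -> seed.
#'
#' @param band `c(f_lo, f_hi)` Hz; the oscillation is placed at the band
#'   centre.
#' @param coupling_lag lag in seconds (0 < lag < 1/f_lo).
#' @param coupling_gain amplitude of the lagged copy in the receiving
#'   channel, in `[0, 1]`.
#' @param ungated_gain coupling gain on ungated (target-drives) trials;
#'   `NULL` (default) uses `coupling_gain`, i.e. a pure direction flip with
#'   equal strength. Set lower to additionally plant a connectivity-strength
#'   difference between optimal- and non-optimal-phase trials.
#' @param gate_phase seed phase (radians) at `t_lock` that selects
#'   seed -> target coupling.
#' @param fs sampling rate, Hz.
#' @param epoch `c(t_start, t_end)` seconds.
#' @param t_lock gating time, seconds (pre-movement).
#' @param osc_amplitude,noise_amplitude,noise_exponent signal and 1/f noise
#'   levels.
#' @param phase_diffusion phase random-walk diffusion of the oscillation,
#'   rad^2/s. A finite coherence time is what makes the lag of maximal
#'   phase coherence identifiable; 0 would give a perfectly stationary
#'   sinusoid whose lagged copies are indistinguishable.
#' @param seed integer seed.
#' @return list of class `coupled_pair_config`.
#' @export
coupled_pair_config <- function(band = c(9, 12), coupling_lag = 0.03,
                                coupling_gain = 0.9, gate_phase = 0,
                                ungated_gain = NULL,
                                fs = 250, epoch = c(-1, 1.4),
                                t_lock = -0.256, osc_amplitude = 1,
                                noise_amplitude = 0.3, noise_exponent = 1,
                                phase_diffusion = 15, seed = 1L) {
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2]) {
    stop_cfg("`band` must be c(f_lo, f_hi) with 0 < f_lo < f_hi")
  }
  if (coupling_lag <= 0 || coupling_lag >= 1 / band[1]) {
    stop_cfg("`coupling_lag` must satisfy 0 < lag < 1/f_lo")
  }
  if (coupling_lag >= epoch[2] - epoch[1]) {
    stop_cfg("`coupling_lag` must be shorter than the epoch")
  }
  if (coupling_gain < 0 || coupling_gain > 1) {
    stop_cfg("`coupling_gain` must be in [0, 1]")
  }
  ungated_gain <- ungated_gain %||% coupling_gain
  if (ungated_gain < 0 || ungated_gain > 1) {
    stop_cfg("`ungated_gain` must be in [0, 1]")
  }
  if (!(epoch[1] < t_lock && t_lock < 0)) {
    stop_cfg("need t_start < t_lock < 0")
  }
  if (phase_diffusion < 0) stop_cfg("`phase_diffusion` must be >= 0")
  structure(
    list(
      band = band, coupling_lag = coupling_lag, coupling_gain = coupling_gain,
      ungated_gain = ungated_gain,
      gate_phase = wrap_angle(gate_phase), fs = fs, epoch = epoch,
      t_lock = t_lock, osc_amplitude = osc_amplitude,
      noise_amplitude = noise_amplitude, noise_exponent = noise_exponent,
      phase_diffusion = phase_diffusion, seed = as.integer(seed)
    ),
    class = "coupled_pair_config"
  )
}

#' Generate a phase-gated coupled source pair
#'
#' @param cfg a [coupled_pair_config()].
#' @param n_trials number of trials; seed phases at `t_lock` are uniform, so
#'   about one third of trials fall inside the gate.
#' @return list with `trials` (2-channel `trial_set`, channels "seed" and
#'   "target") and `phases` (data.frame: `trial`, `phase_at_lock`, `gated`).
#' @export
make_coupled_source_pair <- function(cfg, n_trials = 100L) {
  stopifnot(inherits(cfg, "coupled_pair_config"))
  set.seed(cfg$seed)
  tt <- epoch_times(cfg$epoch, cfg$fs)
  ns <- length(tt)
  fc <- mean(cfg$band)
  lag <- cfg$coupling_lag
  phase <- wrap_angle(runif(n_trials, -pi, pi))
  gated <- circular_distance(phase, cfg$gate_phase) < pi / 3
  data <- array(0, dim = c(n_trials, 2L, ns))
  A <- cfg$osc_amplitude
  g <- cfg$coupling_gain
  li <- round(lag * cfg$fs) # lag in whole samples
  ilock <- which.min(abs(tt - cfg$t_lock))
  next_ <- length(tt) + li # extended grid: receiver needs li earlier samples
  for (i in seq_len(n_trials)) {
    nz <- cfg$noise_amplitude *
      one_over_f_noise(ns, cfg$fs, cfg$noise_exponent, 2L)
    # phase-diffusing oscillation on the extended grid starting at
    # t_start - lag; the driver occupies indices (li+1):(li+ns), the
    # receiver gets the copy shifted earlier by li samples
    w <- cumsum(rnorm(next_, 0, sqrt(cfg$phase_diffusion / cfg$fs)))
    text <- tt[1] - lag + (seq_len(next_) - 1L) / cfg$fs
    if (gated[i]) {
      # seed drives: pin the walk (and phase[i]) at the seed's t_lock sample
      w <- w - w[li + ilock]
      osc <- A * cos(2 * pi * fc * (text - cfg$t_lock) + phase[i] + w)
      osc_seed <- osc[(li + 1L):(li + ns)]
      osc_target <- g * osc[seq_len(ns)]
    } else {
      # target drives; the seed receives the lagged copy, so its t_lock
      # sample maps to extended index ilock: pin there and advance the
      # carrier so the seed still shows phase[i] at t_lock
      w <- w - w[ilock]
      psi <- phase[i] + 2 * pi * fc * lag
      osc <- A * cos(2 * pi * fc * (text - cfg$t_lock) + psi + w)
      osc_target <- osc[(li + 1L):(li + ns)]
      osc_seed <- cfg$ungated_gain * osc[seq_len(ns)]
    }
    data[i, 1, ] <- osc_seed + nz[, 1]
    data[i, 2, ] <- osc_target + nz[, 2]
  }
  ts <- trial_set(
    data, cfg$fs, t0_index = which(tt == 0),
    channel_ids = c("seed", "target"),
    truth = list(
      fc = fc, band = cfg$band, coupling_lag = lag,
      coupling_gain = g, ungated_gain = cfg$ungated_gain,
      gate_phase = cfg$gate_phase, t_lock = cfg$t_lock,
      phase_at_lock = phase, gated = gated, seed = cfg$seed
    )
  )
  list(trials = ts, phases = data.frame(
    trial = seq_len(n_trials), phase_at_lock = phase, gated = gated
  ))
}

#' Generate a cohort of subjects with individual alpha peaks
#'
#' Each subject gets a planted oscillation frequency (their "alpha bump")
#' drawn uniformly from `alpha_range`, riding on 1/f background noise, with a
#' phase opposition planted at that same frequency. Used to validate the
#' alignment between the individual alpha peak and the per-subject frequency
#' of strongest phase opposition.
#'
#' @param n_subjects number of subjects.
#' @param alpha_range `c(lo, hi)` Hz for the per-subject bump frequency.
#' @param template a [synth_trial_config()] supplying all other parameters.
#' @param seed integer master seed; per-subject seeds are derived from it.
#' @return list of class `subject_cohort`; each element has `trials`,
#'   `labels` and `f0` (the planted bump frequency).
#' @export
make_subject_cohort <- function(n_subjects = 20L, alpha_range = c(8, 13),
                                template = synth_trial_config(), seed = 1L) {
  stopifnot(inherits(template, "synth_trial_config"))
  set.seed(seed)
  f0s <- runif(n_subjects, alpha_range[1], alpha_range[2])
  seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    cfg <- template
    cfg$f0 <- f0s[s]
    cfg$seed <- seeds[s]
    d <- make_phase_coded_trials(cfg)
    out[[s]] <- list(trials = d$trials, labels = d$labels, f0 = f0s[s])
  }
  structure(out, class = "subject_cohort", seed = seed)
}
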