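spike_fixture <- function(seed = 6, m = 1, n = 25, base_rate = 15, n_units = 8) {
  d <- quick_dataset(seed = seed, n = n, kappa = 5,
                     osc_amplitude = 3, noise_amplitude = 0.3)
  cfg <- spike_synth_config(base_rate = base_rate, mod_depth = m,
                            n_units = n_units, seed = seed + 1)
  list(data = d, spikes = make_spike_trains(d$trials, cfg), cfg = cfg)
}

test_that("phases at spikes use the nearest sample with earlier-sample ties", {
  # one trial of a pure oscillation; spikes exactly at its peaks
  fs <- 250
  tt <- phasegate:::epoch_times(c(-1.5, 1), fs)
  x <- array(3 * cos(2 * pi * 10 * tt), dim = c(1, 1, length(tt)))
  ts1 <- trial_set(x, fs, which(tt == 0))
  an <- morlet_analytic(ts1, freqs = 10)
  peaks <- seq(-1, 0.5, by = 0.1) # cos(2 pi 10 t) = 1 at multiples of 0.1 s
  sp <- data.frame(unit = 1L, trial = 1L, time_s = peaks)
  ps <- phases_at_spikes(an, sp, 10)
  expect_lt(max(abs(ps$phase)), 0.1)
  # tie exactly between samples resolves to the earlier sample
  mid <- tt[100] + 0.5 / fs
  idx <- phasegate:::match_freqs(10, an$freqs)
  sp2 <- data.frame(unit = 1L, trial = 1L, time_s = mid)
  ps2 <- phases_at_spikes(an, sp2, 10)
  expect_equal(ps2$phase, Arg(an$values[1, 1, idx, 100]))
  # spikes outside the epoch are dropped and counted
  sp3 <- data.frame(unit = 1L, trial = 1L, time_s = c(0, 99))
  ps3 <- phases_at_spikes(an, sp3, 10)
  expect_identical(attr(ps3, "n_dropped"), 1L)
  expect_error(phases_at_spikes(an, data.frame(unit = 1, trial = 1, time_s = 99),
                                10), "no spikes")
})

test_that("spike-field PLV matches the von Mises Bessel-ratio oracle", {
  expect_equal(spike_field_plv(rep(0.7, 100)), 1)
  expect_equal(spike_field_plv(rep(c(0, pi), 50)), 0, tolerance = 1e-12)
  set.seed(15)
  for (k in c(0.5, 2, 8)) {
    ph <- rvonmises(30000, 1, k)
    expect_lt(abs(spike_field_plv(ph) - besselI(k, 1) / besselI(k, 0)), 0.02)
  }
  expect_warning(spike_field_plv(runif(10)), "fewer than 50")
  expect_error(spike_field_plv(numeric(0)), "no spikes")
})

test_that("PLV spectrum peaks at the planted oscillation frequency", {
  fx <- spike_fixture(seed = 16, m = 0.8)
  an <- morlet_analytic(fx$data$trials, freqs = seq(4, 13, length.out = 10))
  spec <- spike_plv_spectrum(an, fx$spikes)
  expect_identical(nrow(spec), 10L)
  expect_equal(spec$freq[which.max(spec$plv)], 8, tolerance = 1.01)
  # m = 0: PLV near zero everywhere
  fx0 <- spike_fixture(seed = 17, m = 0)
  spec0 <- spike_plv_spectrum(an, fx0$spikes)
  expect_lt(max(spec0$plv), 0.08)
})

test_that("spike-phase histogram matches the analytic 1+cos bin integrals", {
  expect_error(spike_phase_histogram(runif(10), n_bins = 1), "n_bins")
  # uniform phases: all bins ~ 1/5
  set.seed(18)
  h <- spike_phase_histogram(runif(100000, -pi, pi), 5, reference = 0.4)
  expect_equal(sum(h$probability), 1, tolerance = 1e-12)
  expect_true(all(abs(h$probability - 0.2) < 0.01))
  # all spikes in the reference bin
  h1 <- spike_phase_histogram(rep(1.1, 200), 5, reference = 1.1)
  expect_equal(h1$probability[1], 1)
  # density proportional to 1 + cos(phi - mu): closed-form bin integrals
  mu <- 4 * pi / 3
  fx <- spike_fixture(seed = 19, m = 1, n = 40, base_rate = 25, n_units = 10)
  truth <- fx$data$trials$truth
  phi <- 2 * pi * truth$f0 * (fx$spikes$time_s - truth$t_lock) +
    truth$phase_at_lock[fx$spikes$trial]
  h2 <- spike_phase_histogram(wrap_angle(phi), 5, reference = mu)
  w <- 2 * pi / 5
  edges <- (seq_len(6) - 1) * w - w / 2 # bin k centred on (k-1)*w rel. to mu
  expected <- (w + sin(edges[-1]) - sin(edges[-6])) / (2 * pi)
  expect_equal(h2$probability, expected, tolerance = 0.02)
})

test_that("per-unit preferred angles recover the planted preference", {
  fx <- spike_fixture(seed = 20, m = 1, base_rate = 25)
  an <- morlet_analytic(fx$data$trials, freqs = 8)
  ps <- phases_at_spikes(an, fx$spikes, 8)
  ua <- unit_preferred_angles(ps)
  expect_identical(nrow(ua), length(unique(fx$spikes$unit)))
  expect_lt(circular_distance(circ_mean(ua$angle), wrap_angle(4 * pi / 3)), 0.3)
  expect_true(all(ua$resultant > 0.2))
  # pooled PLV equals the spike-count-weighted per-unit resultant
  pooled <- suppressWarnings(spike_field_plv(ps))
  z_units <- complex(modulus = ua$resultant, argument = ua$angle)
  expect_equal(pooled, Mod(sum(ua$n_spikes * z_units)) / sum(ua$n_spikes),
               tolerance = 1e-10)
  # uncoupled units have small resultants
  fx0 <- spike_fixture(seed = 21, m = 0, base_rate = 25)
  ps0 <- phases_at_spikes(morlet_analytic(fx0$data$trials, freqs = 8),
                          fx0$spikes, 8)
  ua0 <- unit_preferred_angles(ps0)
  expect_lt(mean(ua0$resultant), 0.12)
})

test_that("firing-rate contrast finds planted steps and handles empty bins", {
  fx <- spike_fixture(seed = 22, m = 0, n = 30, base_rate = 10, n_units = 6)
  lab <- fx$data$labels
  # null: identical processes, expect no (or non-significant) cluster
  rc0 <- firing_rate_contrast(fx$spikes, lab, fx$data$trials, n_perm = 150,
                              seed = 2)
  expect_true(nrow(rc0$clusters) == 0L ||
                min(rc0$clusters$p_corrected) > 0.05)
  expect_true(all(rc0$rate_high >= 0) && all(rc0$rate_low >= 0))
  # planted step: double the rate for high trials after movement onset
  sp <- fx$spikes
  hi <- which(lab$label[sp$trial] == "high" & sp$time_s > 0)
  extra <- sp[hi, ]
  rc1 <- firing_rate_contrast(rbind(sp, extra), lab, fx$data$trials,
                              n_perm = 150, seed = 3)
  expect_gte(nrow(rc1$clusters), 1L)
  expect_lt(rc1$clusters$p_corrected[1], 0.05)
  sig_bins <- which(rc1$bin_labels[1, ] == rc1$clusters$cluster[1])
  expect_gt(min(rc1$time[sig_bins]), -0.1)
})

test_that("PLV label contrast is antisymmetric and calibrated under the null", {
  fx <- spike_fixture(seed = 23, m = 0.8, n = 30, base_rate = 20)
  an <- morlet_analytic(fx$data$trials, freqs = 8)
  ps <- phases_at_spikes(an, fx$spikes, 8)
  lab <- fx$data$labels
  res <- plv_contrast_by_label(ps, lab, n_perm = 200, seed = 4)
  flipped <- lab
  flipped$label <- ifelse(lab$label == "high", "low", "high")
  res2 <- plv_contrast_by_label(ps, flipped, n_perm = 200, seed = 4)
  expect_equal(res$delta_plv, -res2$delta_plv, tolerance = 1e-12)
  # same coupling in both conditions: difference should not be significant
  expect_gt(res$p, 0.05)
})
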