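test_that("phase-coded trials are balanced, reproducible and pin the planted phase", {
  d <- quick_dataset(seed = 3, n = 25)
  expect_balanced_labels(d$labels, 25L)
  expect_identical(dim(d$trials$data), c(50L, 1L, length(trial_times(d$trials))))
  # bit-identical under the same seed
  d2 <- quick_dataset(seed = 3, n = 25)
  expect_identical(d$trials$data, d2$trials$data)
  expect_identical(d$trials$truth$phase_at_lock, d2$trials$truth$phase_at_lock)
  # different seed differs
  expect_false(identical(d$trials$data, quick_dataset(seed = 4, n = 25)$trials$data))
})

test_that("extracted phase at the planted point matches mu_high under high SNR", {
  cfg <- synth_trial_config(n_trials_per_condition = 120, kappa = 50,
                            osc_amplitude = 10, noise_amplitude = 0.5, seed = 8)
  d <- make_phase_coded_trials(cfg)
  an <- morlet_analytic(d$trials, freqs = seq(4, 13, length.out = 10))
  fi <- which.min(abs(an$freqs - cfg$f0))
  ti <- which.min(abs(an$times - cfg$t_lock))
  ph <- Arg(an$values[, 1, fi, ti])
  lab <- d$labels$label
  expect_lt(circular_distance(circ_mean(ph[lab == "high"]), cfg$mu_high), 0.1)
  expect_lt(circular_distance(circ_mean(ph[lab == "low"]), cfg$mu_high + pi), 0.1)
})

test_that("configuration invariants are enforced", {
  expect_error(synth_trial_config(epoch = c(-0.1, 0.5)), "epoch")
  expect_error(synth_trial_config(t_lock = 0.2), "epoch")
  expect_error(synth_trial_config(kappa = -1), "kappa")
  expect_error(coupled_pair_config(coupling_lag = 0.5, band = c(9, 12)), "lag")
  expect_error(coupled_pair_config(coupling_gain = 1.5), "gain")
  expect_error(spike_synth_config(mod_depth = 2), "mod_depth")
})

test_that("cosine-link agency labels honour the endpoints and the link shape", {
  # endpoints of the link
  hi <- make_agency_labels_from_phase(rep(0, 200), p0 = 0.5, beta = 0.5,
                                      phi_opt = 0, seed = 1)
  expect_true(all(hi$label == "high"))
  lo <- make_agency_labels_from_phase(rep(pi, 200), p0 = 0.5, beta = 0.5,
                                      phi_opt = 0, seed = 1)
  expect_true(all(lo$label == "low"))
  expect_error(make_agency_labels_from_phase(0, p0 = 0.8, beta = 0.5), "probability")
  # beta = 0: frequency ~ p0 independent of phase
  set.seed(2)
  ph <- runif(4000, -pi, pi)
  l0 <- make_agency_labels_from_phase(ph, p0 = 0.3, beta = 0, seed = 5)
  expect_equal(mean(l0$outcome), 0.3, tolerance = 0.025)
  # Monte Carlo: per-bin probability matches the cosine link within binomial CI
  ph <- runif(10000, -pi, pi)
  lb <- make_agency_labels_from_phase(ph, p0 = 0.5, beta = 0.3, phi_opt = 0.7,
                                      seed = 9)
  tab <- phase_binned_outcome_probability(ph, lb$outcome, n_bins = 6,
                                          reference_angle = 0.7, conf = 0.99)
  # expected probability = mean of the link over each distance bin
  for (b in seq_len(6)) {
    lo_b <- (b - 1) * pi / 6; hi_b <- b * pi / 6
    expected <- 0.5 + 0.3 * (sin(hi_b) - sin(lo_b)) / (hi_b - lo_b)
    expect_gt(expected, tab$ci_lower[b])
    expect_lt(expected, tab$ci_upper[b])
  }
})

test_that("spike trains are reproducible, phase-modulated, and warn when sparse", {
  d <- quick_dataset(seed = 6, n = 20, kappa = 5,
                     osc_amplitude = 3, noise_amplitude = 0.3)
  cfg <- spike_synth_config(base_rate = 12, mod_depth = 1, n_units = 6, seed = 4)
  sp <- make_spike_trains(d$trials, cfg)
  sp2 <- make_spike_trains(d$trials, cfg)
  expect_identical(sp, sp2)
  expect_true(all(sp$time_s >= min(trial_times(d$trials))))
  expect_true(all(sp$time_s <= max(trial_times(d$trials))))
  # m = 1: spike-phase density follows 1 + cos; check via planted phase
  truth <- d$trials$truth
  phi <- 2 * pi * truth$f0 * (sp$time_s - truth$t_lock) +
    truth$phase_at_lock[sp$trial]
  rel <- wrap_angle(phi - cfg$preferred_phase)
  # analytic PLV of density (1 + cos)/2pi is 1/2
  expect_equal(Mod(mean(exp(1i * rel))), 0.5, tolerance = 0.02)
  # m = 0 spikes carry no phase preference
  cfg0 <- spike_synth_config(base_rate = 12, mod_depth = 0, n_units = 6, seed = 4)
  sp0 <- make_spike_trains(d$trials, cfg0)
  phi0 <- 2 * pi * truth$f0 * (sp0$time_s - truth$t_lock) +
    truth$phase_at_lock[sp0$trial]
  expect_lt(Mod(mean(exp(1i * phi0))), 0.05)
  expect_warning(
    make_spike_trains(d$trials, spike_synth_config(base_rate = 0.2, seed = 1)),
    "below 1"
  )
})

test_that("coupled pair gating records phases and flips direction on gate swap", {
  cfg <- coupled_pair_config(gate_phase = 0.5, seed = 21)
  pp <- make_coupled_source_pair(cfg, n_trials = 60)
  expect_identical(nrow(pp$phases), 60L)
  expect_identical(pp$phases$gated,
                   circular_distance(pp$phases$phase_at_lock, 0.5) < pi / 3)
  an <- morlet_analytic(pp$trials, freqs = 9:12)
  lc_g <- lag_phase_coherence(an, trials = which(pp$phases$gated))
  lc_u <- lag_phase_coherence(an, trials = which(!pp$phases$gated))
  expect_gt(lc_g$peak_lag, 0)
  expect_lt(lc_u$peak_lag, 0)
})

test_that("subject cohort plants per-subject frequencies reproducibly", {
  tpl <- synth_trial_config(n_trials_per_condition = 5)
  ch <- make_subject_cohort(4, c(8, 13), tpl, seed = 2)
  expect_length(ch, 4L)
  f0s <- vapply(ch, `[[`, numeric(1), "f0")
  expect_true(all(f0s >= 8 & f0s <= 13))
  ch2 <- make_subject_cohort(4, c(8, 13), tpl, seed = 2)
  expect_identical(f0s, vapply(ch2, `[[`, numeric(1), "f0"))
  expect_identical(ch[[2]]$trials$data, ch2[[2]]$trials$data)
})

test_that("planted POP at the locked point is non-decreasing in kappa", {
  kappas <- c(0, 1, 5, 50)
  mean_pop <- vapply(kappas, function(k) {
    vals <- vapply(1:20, function(s) {
      cfg <- synth_trial_config(n_trials_per_condition = 30, kappa = k,
                                seed = 5000 + s)
      d <- make_phase_coded_trials(cfg)
      # phases measured at the planted cell through the package's extractor
      an <- morlet_analytic(d$trials, freqs = 8)
      ti <- which.min(abs(an$times - cfg$t_lock))
      ph <- Arg(an$values[, 1, 1, ti])
      lab <- d$labels$label
      pop_stat(ph[lab == "high"], ph[lab == "low"])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_pop) > -0.01)) # non-decreasing up to MC noise
  expect_lt(mean_pop[1], 0.05)
  expect_gt(mean_pop[4], 0.5)
})
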