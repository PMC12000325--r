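# Build an analytic_map directly from per-trial phase angles (optionally a
# trials x freqs x times array), bypassing signal extraction. Used to feed
# statistics exactly known phase configurations.
analytic_from_phases <- function(phases, freqs = 1, times = 0, fs = 250,
                                 amplitudes = 1) {
  if (is.vector(phases)) phases <- array(phases, dim = c(length(phases), 1, 1))
  d <- dim(phases)
  values <- array(complex(modulus = amplitudes, argument = phases),
                  dim = c(d[1], 1L, d[2], d[3]))
  phasegate:::new_analytic_map(
    values, freqs, times, fs, "synthetic",
    valid = matrix(TRUE, d[2], d[3])
  )
}

# Uniform-phase null analytic map: n trials, nf x nt cells.
null_analytic <- function(n, nf = 10, nt = 20, freqs = seq(4, 13, length.out = nf),
                          times = seq(-0.6, 0.1, length.out = nt)) {
  ph <- array(runif(n * nf * nt, -pi, pi), dim = c(n, nf, nt))
  analytic_from_phases(ph, freqs = freqs, times = times)
}

# Small, fast phase-coded dataset for end-to-end checks.
quick_dataset <- function(seed = 1, n = 40, kappa = 5, ...) {
  cfg <- synth_trial_config(n_trials_per_condition = n, kappa = kappa,
                            seed = seed, ...)
  make_phase_coded_trials(cfg)
}

expect_balanced_labels <- function(labels, n) {
  lab <- labels$label
  expect_identical(sum(lab == "high"), n)
  expect_identical(sum(lab == "low"), n)
}
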