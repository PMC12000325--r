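test_that("ITC handles the canonical configurations", {
  expect_equal(itc(rep(1.3, 10)), 1)
  expect_equal(itc(c(0, pi)), 0, tolerance = 1e-12)
  expect_equal(itc(c(0, pi / 2, pi, 3 * pi / 2)), 0, tolerance = 1e-12)
  expect_error(itc(complex(modulus = c(1, 0), argument = c(0, 0))), "zero-amplitude")
  # amplitude is discarded: scaled vectors give the same ITC
  z <- complex(modulus = c(1, 5, 0.2), argument = c(0.3, 0.5, 0.1))
  expect_equal(itc(z), itc(z / Mod(z)))
})

test_that("expected ITC of uniform phases follows sqrt(pi)/(2 sqrt(n))", {
  set.seed(7)
  for (n in c(10, 100, 1000)) {
    vals <- vapply(1:600, function(i) itc(runif(n, -pi, pi)), numeric(1))
    expected <- sqrt(pi) / (2 * sqrt(n))
    # 5% asymptotic-formula slack plus 3 Monte Carlo standard errors
    tol <- 0.05 * expected + 3 * sqrt((4 - pi) / (4 * n)) / sqrt(600)
    expect_lt(abs(mean(vals) - expected), tol)
  }
})

test_that("POP matches the closed-form constituents", {
  # identical multisets: POP exactly 0
  ph <- c(0.3, 1.2, -2, 0.5)
  expect_equal(pop_stat(ph, ph), 0, tolerance = 1e-12)
  # perfect opposition: 1*1 - 0^2 = 1
  expect_equal(pop_stat(rep(0, 10), rep(pi, 10)), 1, tolerance = 1e-12)
  # quarter-turn offset: 1 - |(1 + i)/2|^2 = 0.5
  expect_equal(pop_stat(rep(0, 10), rep(pi / 2, 10)), 0.5, tolerance = 1e-12)
})

test_that("POP map agrees with the scalar oracle cell by cell", {
  set.seed(3)
  n <- 16
  ph <- array(runif(n * 3 * 4, -pi, pi), dim = c(n, 3, 4))
  an <- analytic_from_phases(ph, freqs = c(5, 8, 11), times = c(1, 2, 3, 4))
  lab <- rep(c("high", "low"), each = n / 2)
  pm <- pop(an, lab)
  for (f in 1:3) for (t in 1:4) {
    expect_equal(pm$pop[f, t],
                 pop_stat(ph[lab == "high", f, t], ph[lab == "low", f, t]),
                 tolerance = 1e-12)
  }
  expect_identical(pm$n, as.integer(n))
  expect_true(all(pm$itc_all >= 0 & pm$itc_all <= 1))
})

test_that("POP is invariant to global rotation and label exchange", {
  set.seed(5)
  a <- rvonmises(40, 1, 3); b <- rvonmises(40, 1 + pi, 3)
  base <- pop_stat(a, b)
  expect_equal(pop_stat(a + 2.1, b + 2.1), base, tolerance = 1e-12)
  expect_equal(pop_stat(b, a), base, tolerance = 1e-12)
  expect_true(base >= -1 && base <= 1)
})

test_that("optimal angle averages the two direction estimates", {
  expect_equal(optimal_phase_angle(rep(0, 5), rep(pi, 5)), 0, tolerance = 1e-12)
  expect_equal(optimal_phase_angle(rep(pi / 2, 5), rep(3 * pi / 2, 5)), pi / 2,
               tolerance = 1e-12)
  set.seed(12)
  high <- rvonmises(500, 1, 5); low <- rvonmises(500, 1 + pi, 5)
  expect_lt(circular_distance(optimal_phase_angle(high, low), 1), 0.1)
  expect_error(optimal_phase_angle(c(0, pi), rep(1, 3)), "undefined")
})

test_that("phase partition selects thirds with strict boundaries", {
  set.seed(8)
  ph <- runif(10000, -pi, pi)
  part <- select_phase_trials(ph, 0.9)
  expect_equal(length(part$optimal) / 10000, 1 / 3, tolerance = 0.015)
  expect_equal(length(part$non_optimal) / 10000, 1 / 3, tolerance = 0.015)
  expect_length(intersect(part$optimal, part$non_optimal), 0)
  expect_identical(sort(c(part$optimal, part$non_optimal, part$excluded)),
                   seq_along(ph))
  # all at the optimal angle: everything optimal
  p2 <- select_phase_trials(rep(0.9, 50), 0.9)
  expect_length(p2$optimal, 50L)
  expect_length(p2$non_optimal, 0L)
  # boundary phase exactly pi/3 away is excluded (strict inequality)
  p3 <- select_phase_trials(c(pi / 3, -pi / 3), 0)
  expect_length(p3$optimal, 0L)
  expect_length(p3$excluded, 2L)
})

test_that("phase-binned outcome probability flags empty bins and tracks the link", {
  ph <- c(0.01, 0.02, -0.01) # all near reference: far bins empty
  tab <- phase_binned_outcome_probability(ph, c(1, 1, 1), n_bins = 4,
                                          reference_angle = 0)
  expect_equal(tab$probability[1], 1)
  expect_true(all(tab$empty[-1]))
  expect_true(all(is.na(tab$probability[-1])))
  # null outcomes: all bins near 0.5
  set.seed(10)
  ph <- runif(6000, -pi, pi)
  y <- rbinom(6000, 1, 0.5)
  tab <- phase_binned_outcome_probability(ph, y, n_bins = 5, reference_angle = 1)
  expect_true(all(abs(tab$probability - 0.5) < 0.05))
  # cosine link: monotone decrease with distance from the optimal phase
  lb <- make_agency_labels_from_phase(ph, p0 = 0.5, beta = 0.4, phi_opt = 1,
                                      seed = 3)
  tab2 <- phase_binned_outcome_probability(ph, lb$outcome, n_bins = 5,
                                           reference_angle = 1)
  expect_true(all(diff(tab2$probability) < 0))
})

test_that("bootstrap circular-distance contrast separates matched and mismatched", {
  set.seed(6)
  a_high <- rvonmises(80, 0.5, 8); a_low <- rvonmises(80, 0.5 + pi, 8)
  res <- bootstrap_circular_distance_contrast(a_high, a_low, a_high, a_low,
                                              n_boot = 400, seed = 2)
  expect_lt(res$matched, 0.2)
  expect_gt(res$mismatched, pi - 0.2)
  expect_lt(res$p, 0.01)
  # all four sets identical: no contrast
  res0 <- bootstrap_circular_distance_contrast(a_high, a_high, a_high, a_high,
                                               n_boot = 400, seed = 2)
  expect_equal(res0$matched, res0$mismatched, tolerance = 1e-12)
  expect_warning(
    bootstrap_circular_distance_contrast(a_high, a_low, a_high, a_low,
                                         n_boot = 50, seed = 1),
    "100"
  )
})

test_that("delay detrending removes linear trends and recovers slopes", {
  r <- c(5, 6, 7, 8)
  out <- detrend_ratings_by_delay(r, c(1, 1, 1, 1))
  expect_equal(as.numeric(out), r - mean(r))
  expect_true(attr(out, "degenerate"))
  # exact linear dependence: residuals all zero
  delays <- seq(0.5, 2, length.out = 20)
  out2 <- detrend_ratings_by_delay(9 - 2 * delays, delays)
  expect_lt(max(abs(out2)), 1e-10)
  expect_equal(attr(out2, "slope"), -2, tolerance = 1e-10)
  # noisy slope recovery
  set.seed(13)
  delays <- runif(200, 0.5, 3)
  ratings <- 7 - delays + rnorm(200, 0, 0.5)
  out3 <- detrend_ratings_by_delay(ratings, delays)
  expect_equal(attr(out3, "slope"), -1, tolerance = 0.1)
  expect_error(detrend_ratings_by_delay(c(1, 2), c(1, 2)), "3 trials")
})

test_that("rating extreme split takes thirds and excludes the middle", {
  lb <- split_rating_extremes(c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  expect_identical(sum(lb$label == "high"), 3L)
  expect_identical(sum(lb$label == "low"), 3L)
  expect_identical(lb$label[5], "excluded")
  expect_identical(lb$label[1], "low")
  expect_identical(lb$label[9], "high")
})
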