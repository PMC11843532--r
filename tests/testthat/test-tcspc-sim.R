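test_that("gaussian IRF is normalized, centered, and has the requested width", {
  cfg <- acq_config(n_bins = 4096)
  irf <- make_gaussian_irf(0.2, 1, cfg)
  expect_equal(sum(irf$weights), 1, tolerance = 1e-12)
  expect_equal(which.max(irf$weights),
               findInterval(1, c(0, cfg$bin_centers_ns + cfg$bin_width_ns / 2)))

  # brute-force scan of the half-maximum crossings
  half <- max(irf$weights) / 2
  above <- which(irf$weights >= half)
  fwhm_emp <- (max(above) - min(above) + 1) * cfg$bin_width_ns
  expect_lt(abs(fwhm_emp - 0.2), cfg$bin_width_ns)

  expect_error(make_gaussian_irf(-0.1, 1, cfg), "fwhm")
  expect_error(make_gaussian_irf(0.2, cfg$window_ns, cfg), "center")
})

test_that("expected_curve matches the geometric pulse-tail closed form", {
  cfg <- test_config()
  m <- decay_model(1, 1)
  cur <- expected_curve(m, test_delta_irf(cfg), cfg)
  ref <- exp(-cfg$bin_centers_ns / 1) / (1 - exp(-cfg$window_ns / 1))
  expect_lt(max(abs(cur / ref - 1)), 1e-9)
})

test_that("expected_curve is linear and superposes components", {
  cfg <- test_config(256)
  irf <- make_gaussian_irf(0.2, 1, cfg)
  m1 <- decay_model(0.7, 0.4)
  m2 <- decay_model(0.3, 2.1)
  both <- decay_model(c(0.7, 0.3), c(0.4, 2.1))
  expect_equal(expected_curve(both, irf, cfg),
               expected_curve(m1, irf, cfg) + expected_curve(m2, irf, cfg),
               tolerance = 1e-12)
  scaled <- decay_model(3.5 * m1$amplitudes, m1$lifetimes_ns)
  expect_equal(expected_curve(scaled, irf, cfg),
               3.5 * expected_curve(m1, irf, cfg), tolerance = 1e-12)
  cfg_other <- test_config(128)
  expect_error(expected_curve(m1, make_gaussian_irf(0.2, 1, cfg_other), cfg),
               "binning")
})

test_that("periodic curve converges to single-pulse decay for long periods", {
  # window is 25x the lifetime: inter-pulse carryover must be negligible
  cfg <- test_config()
  tau <- cfg$window_ns / 25
  cur <- expected_curve(decay_model(1, tau), test_delta_irf(cfg), cfg)
  single <- exp(-cfg$bin_centers_ns / tau)
  # compare where the curve is numerically meaningful; far in the tail the
  # FFT round-off (~1e-14 of the peak) dominates the comparison
  idx <- single > 1e-6
  expect_lt(max(abs(cur[idx] / single[idx] - 1)), 1e-6)
})

test_that("simulate_decay draws seeded Poisson counts around the curve", {
  cfg <- test_config(256)
  irf <- make_gaussian_irf(0.2, 1, cfg)
  m <- decay_model(1, 1)

  empty <- simulate_decay(m, irf, cfg, 0, seed = 1)
  expect_true(all(empty$counts == 0))

  h <- simulate_decay(m, irf, cfg, 1e6, seed = 11)
  expect_gt(sum(h$counts) / 1e6, 0.99)
  expect_lt(sum(h$counts) / 1e6, 1.01)

  expect_identical(simulate_decay(m, irf, cfg, 1e4, seed = 3)$counts,
                   simulate_decay(m, irf, cfg, 1e4, seed = 3)$counts)
  expect_false(identical(simulate_decay(m, irf, cfg, 1e4, seed = 3)$counts,
                         simulate_decay(m, irf, cfg, 1e4, seed = 4)$counts))
})

test_that("per-bin means of simulated counts track the expected curve", {
  cfg <- test_config(128)
  irf <- make_gaussian_irf(0.3, 1, cfg)
  m <- decay_model(c(0.6, 0.4), c(0.4, 1.8))
  mu <- expected_curve(m, irf, cfg)
  mu <- mu * (1e5 / sum(mu))
  sims <- vapply(1:200, function(s) {
    simulate_decay(m, irf, cfg, 1e5, seed = s)$counts
  }, numeric(cfg$n_bins))
  mean_counts <- rowMeans(sims)
  se <- sqrt(mu / 200)
  frac_ok <- mean(abs(mean_counts - mu) <= 4 * se)
  expect_gte(frac_ok, 0.99)
})

test_that("sum_pixel_decays pools photons bin-wise", {
  cfg <- test_config(256)
  irf <- make_gaussian_irf(0.2, 1, cfg)
  m <- decay_model(1, 1)
  h <- simulate_decay(m, irf, cfg, 1e4, seed = 5)

  expect_equal(sum_pixel_decays(list(h))$counts, h$counts)
  doubled <- sum_pixel_decays(list(h, h))
  expect_equal(doubled$counts, 2 * h$counts)
  expect_equal(doubled$meta$n_pixels, 2)

  other <- simulate_decay(m, make_gaussian_irf(0.2, 1, test_config(128)),
                          test_config(128), 1e4, seed = 5)
  expect_error(sum_pixel_decays(list(h, other)), "configuration")
})

test_that("fitting the sum of many dim pixels recovers the lifetime", {
  cfg <- test_config()
  irf <- make_gaussian_irf(0.2, 1, cfg)
  m <- decay_model(1, 1)
  pixels <- lapply(1:100, function(i) {
    simulate_decay(m, irf, cfg, 1e3, seed = subseed(77, i))
  })
  pooled <- sum_pixel_decays(pixels)
  fit <- fit_decay(pooled, irf, n = 1, seed = 1)
  expect_lt(abs(fit$model$lifetimes_ns - 1), 0.02)
})
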