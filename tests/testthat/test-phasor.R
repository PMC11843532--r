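omega80 <- 2 * pi * 80 / 1000 # rad/ns at 80 MHz

test_that("closed-form monoexponential phasors match the printed forms", {
  expect_equal(phasor_from_lifetime(0, omega80)$g, 1)
  expect_equal(phasor_from_lifetime(0, omega80)$s, 0)

  p <- phasor_from_lifetime(1 / omega80, omega80) # omega*tau = 1
  expect_equal(p$g, 0.5, tolerance = 1e-12)
  expect_equal(p$s, 0.5, tolerance = 1e-12)

  long <- phasor_from_lifetime(1e3 / omega80, omega80)
  expect_lt(abs(long$g), 1e-5)
  expect_lt(abs(long$s), 2e-3) # s ~ 1/(omega*tau) = 1e-3

  expect_error(phasor_from_lifetime(-1, omega80), ">= 0")
})

test_that("monoexponential phasors sit exactly on the universal circle", {
  taus <- exp(seq(log(0.01), log(100), length.out = 50))
  d <- vapply(taus, function(tau) {
    universal_circle_distance(phasor_from_lifetime(tau, omega80))
  }, numeric(1))
  expect_lt(max(abs(d - 0.5)), 1e-12)
  expect_equal(universal_circle_distance(phasor_point(1, 0)), 0.5)
  expect_equal(universal_circle_distance(phasor_point(0.5, 0)), 0)
})

test_that("two-component phasors lie strictly inside the circle", {
  taus1 <- c(0.05, 0.2, 0.5, 1)
  taus2 <- c(1.5, 2.5, 4, 8)
  for (t1 in taus1) for (t2 in taus2) for (a1 in c(0.2, 0.5, 0.8)) {
    m <- decay_model(c(a1, 1 - a1), c(t1, t2))
    p <- synflim:::phasor_from_model(m, omega80)
    expect_lt(universal_circle_distance(p), 0.5 - 1e-6)
  }
})

test_that("histogram phasors agree with closed forms on fine noiseless curves", {
  cfg <- acq_config(n_bins = 16384)
  for (tau in c(0.1, 0.5, 1, 2.5, 5)) {
    h <- noiseless_histogram(decay_model(1, tau), cfg)
    p <- phasor_from_histogram(h)
    q <- phasor_from_lifetime(tau, cfg$angular_frequency)
    expect_lt(abs(p$g - q$g), 1e-3)
    expect_lt(abs(p$s - q$s), 1e-3)
  }
})

test_that("degenerate histograms give the expected phasors", {
  cfg <- test_config(4096)
  counts <- numeric(cfg$n_bins); counts[1] <- 1000
  p <- phasor_from_histogram(decay_histogram(counts, cfg))
  expect_lt(abs(p$g - 1), 1e-3)
  expect_lt(abs(p$s - 0), 1e-3)

  flat <- phasor_from_histogram(decay_histogram(rep(7, cfg$n_bins), cfg))
  expect_lt(abs(flat$g), 1e-3)
  expect_lt(abs(flat$s), 1e-3)

  expect_error(phasor_from_histogram(decay_histogram(numeric(cfg$n_bins), cfg)),
               "zero total")
})

test_that("phasors are invariant to count rescaling and linear in mixing", {
  cfg <- test_config()
  h <- noiseless_histogram(decay_model(c(0.4, 0.6), c(0.3, 1.7)), cfg,
                           total = 1e6)
  p1 <- phasor_from_histogram(h)
  p3 <- phasor_from_histogram(decay_histogram(3 * h$counts, cfg))
  expect_equal(p1$g, p3$g, tolerance = 1e-12)
  expect_equal(p1$s, p3$s, tolerance = 1e-12)

  # count-wise sum of histograms = total-count-weighted phasor mean (exact)
  h2 <- noiseless_histogram(decay_model(1, 2.2), cfg, total = 3e6)
  pooled <- phasor_from_histogram(decay_histogram(h$counts + h2$counts, cfg))
  w <- c(sum(h$counts), sum(h2$counts))
  p2 <- phasor_from_histogram(h2)
  mix <- mixture_phasor(list(p1, p2), w)
  expect_equal(pooled$g, mix$g, tolerance = 1e-12)
  expect_equal(pooled$s, mix$s, tolerance = 1e-12)
})

test_that("mixture_phasor averages with intensity weights", {
  a <- phasor_point(1, 0)
  b <- phasor_point(0, 0)
  expect_equal(mixture_phasor(list(a), 2)$g, 1)
  mid <- mixture_phasor(list(a, b), c(1, 1))
  expect_equal(mid$g, 0.5)
  expect_equal(mid$s, 0)
  expect_error(mixture_phasor(list(a, b), c(0, 0)), "zero")
})

test_that("two-component decay phasor equals alpha*tau weighted mixture", {
  cfg <- acq_config(n_bins = 8192)
  m <- decay_model(c(0.55, 0.45), c(0.4, 2.0))
  p <- phasor_from_histogram(noiseless_histogram(m, cfg))
  comp <- lapply(m$lifetimes_ns, phasor_from_lifetime,
                 omega = cfg$angular_frequency)
  mix <- mixture_phasor(comp, m$amplitudes * m$lifetimes_ns)
  expect_lt(abs(p$g - mix$g), 1e-3)
  expect_lt(abs(p$s - mix$s), 1e-3)
})

test_that("bootstrap phasor errors shrink with photons and are seeded", {
  cfg <- test_config(512)
  irf <- make_gaussian_irf(0.2, 1, cfg)
  m <- decay_model(1, 1.2)
  h_hi <- simulate_decay(m, irf, cfg, 1e6, seed = 8)
  h_lo <- simulate_decay(m, irf, cfg, 1e4, seed = 9)
  u_hi <- phasor_uncertainty(h_hi, n_replicates = 50, seed = 21)
  u_lo <- phasor_uncertainty(h_lo, n_replicates = 50, seed = 22)
  expect_gt(u_hi$g_err, 0)
  expect_gt(u_hi$s_err, 0)
  expect_lt(u_hi$g_err, u_lo$g_err)
  expect_lt(u_hi$s_err, u_lo$s_err)

  again <- phasor_uncertainty(h_hi, n_replicates = 50, seed = 21)
  expect_identical(u_hi$g_err, again$g_err)
  expect_identical(u_hi$s_err, again$s_err)
  expect_error(phasor_uncertainty(h_hi, n_replicates = 5, seed = 1), ">= 10")
})
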