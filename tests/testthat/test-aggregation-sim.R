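test_that("kinetics with all rates zero leave the monomer untouched", {
  st <- integrate_kinetics(kinetic_params(0, 0, 0), 50, c(0, 1, 10, 100))
  expect_true(all(st$monomer == 50))
  expect_true(all(st$typeA == 0 & st$typeB == 0 & st$fibril == 0))
  expect_error(kinetic_params(-0.1, 0.2, 0.3), ">= 0")
})

test_that("the integrator matches the Bateman closed form without feedback", {
  tp <- seq(0, 100, length.out = 100)
  st <- integrate_kinetics(kinetic_params(0.15, 0.10, 0.055), 100, tp)
  oracle <- bateman_chain(0.15, 0.10, 0.055, 100, tp)
  err <- max(abs(as.matrix(st[, c("monomer", "typeA", "typeB", "fibril")]) -
                 oracle)) / 100
  expect_lt(err, 1e-6)
})

test_that("monomer-equivalent mass is conserved, with and without feedback", {
  tp <- seq(0, 80, by = 0.5)
  for (p in list(kinetic_params(0.3, 0.2, 0.05),
                 kinetic_params(0.05, 0.1, 0.02, ke = 0.002))) {
    st <- integrate_kinetics(p, 100, tp)
    total <- rowSums(st[, c("monomer", "typeA", "typeB", "fibril")])
    expect_lt(max(abs(total - 100)) / 100, 1e-6)
  }
})

test_that("species mixtures map to normalized photon-weighted decay models", {
  prof <- preset("wt_like")$profile

  pure <- species_to_decay(c(monomer = 10, typeA = 0, typeB = 0, fibril = 0),
                           prof)
  expect_equal(sum(pure$amplitudes), 1)
  expect_equal(pure$lifetimes_ns, prof$decays$monomer$lifetimes_ns)

  # two single-lifetime species contributing equal photons: amplitudes 0.5/0.5
  prof2 <- optical_profile(
    decays = list(monomer = decay_model(1, 0.1), typeA = decay_model(1, 0.5),
                  typeB = decay_model(1, 1.0), fibril = decay_model(1, 2.0)),
    photon_weights = c(monomer = 1, typeA = 0, typeB = 2, fibril = 0),
    intensity_brightness = c(monomer = 0, typeA = 0, typeB = 0, fibril = 1)
  )
  mix <- species_to_decay(c(monomer = 10, typeA = 0, typeB = 5, fibril = 0),
                          prof2)
  expect_equal(mix$amplitudes, c(0.5, 0.5))

  expect_error(
    species_to_decay(c(monomer = 0, typeA = 1, typeB = 0, fibril = 0), prof2),
    "zero")
})

test_that("mixture tau_m interpolates between the pure species", {
  prof <- preset("wt_like")$profile
  tau_mono <- amplitude_weighted_lifetime(prof$decays$monomer)
  tau_fib <- amplitude_weighted_lifetime(prof$decays$fibril)
  st <- integrate_kinetics(preset("wt_like")$params, 100, c(0, 12))[2, ]
  tm <- amplitude_weighted_lifetime(species_to_decay(st, prof))
  expect_gt(tm, tau_mono)
  expect_lt(tm, tau_fib)
})

test_that("tau_m responds continuously to concentration perturbations", {
  prof <- preset("wt_like")$profile
  base <- c(monomer = 40, typeA = 20, typeB = 30, fibril = 10)
  tm0 <- amplitude_weighted_lifetime(species_to_decay(base, prof))
  for (eps in c(1e-3, 1e-5)) {
    pert <- base + c(0, 0, eps, 0)
    tm1 <- amplitude_weighted_lifetime(species_to_decay(pert, prof))
    expect_lt(abs(tm1 - tm0), 0.1 * eps) # |d tau_m / d c| is O(0.01)/uM here
  }
})

test_that("bulk intensity is linear in concentrations and fibril-gated", {
  prof <- preset("wt_like")$profile
  zero <- c(monomer = 0, typeA = 0, typeB = 0, fibril = 0)
  expect_equal(species_to_intensity(zero, prof), 0)
  lag <- c(monomer = 80, typeA = 20, typeB = 0, fibril = 0)
  expect_equal(species_to_intensity(lag, prof), 0)
  st <- c(monomer = 10, typeA = 10, typeB = 40, fibril = 40)
  expect_equal(species_to_intensity(2 * st, prof),
               2 * species_to_intensity(st, prof))
})

test_that("presets encode the variant phenotypes by construction", {
  wt <- preset("wt_like")
  a30p <- preset("a30p_like")
  dp1 <- preset("dp1_like")
  expect_equal(a30p$params$k1, wt$params$k1)
  expect_equal(a30p$params$k2, wt$params$k2)
  expect_lt(a30p$params$k3, wt$params$k3)
  expect_lt(dp1$params$k1, wt$params$k1)
  expect_lt(dp1$params$k2, wt$params$k2)
  expect_lt(dp1$params$k3, a30p$params$k3)
  expect_error(preset("unknown"), "arg")
})

test_that("simulated experiments are seeded and reproducible", {
  cfg <- test_config(256)
  p <- preset("wt_like")
  tp <- seq(0, 40, by = 5)
  t1 <- simulate_experiment(p$params, p$profile, tp, cfg, 1e4, seed = 5)
  t2 <- simulate_experiment(p$params, p$profile, tp, cfg, 1e4, seed = 5)
  expect_identical(lapply(t1$decays, `[[`, "counts"),
                   lapply(t2$decays, `[[`, "counts"))
  t3 <- simulate_experiment(p$params, p$profile, tp, cfg, 1e4, seed = 6)
  expect_false(identical(lapply(t1$decays, `[[`, "counts"),
                         lapply(t3$decays, `[[`, "counts")))
})

test_that("fitted tau_m rises monotonically along a WT-like run", {
  cfg <- test_config(512)
  p <- preset("wt_like")
  tp <- seq(0, 60, by = 3)
  tr <- simulate_experiment(p$params, p$profile, tp, cfg, 3e5, seed = 12)
  irf <- tr$irf
  tau_fit <- vapply(seq_along(tp), function(i) {
    fit_decay(tr$decays[[i]], irf, n = 2, seed = 1)$tau_m
  }, numeric(1))
  rho <- stats::cor(tau_fit, tp, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("noiseless traces carry ground-truth lifetimes and intensities", {
  cfg <- test_config(256)
  p <- preset("a30p_like")
  tp <- seq(0, 100, by = 2)
  tr <- simulate_experiment(p$params, p$profile, tp, cfg, 0, seed = 1)
  expect_null(tr$decays)
  expect_true(all(diff(tr$tau_m) > -1e-9))
  expect_true(all(tr$intensity >= 0))
  expect_equal(length(tr$phasors), length(tp))
})
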