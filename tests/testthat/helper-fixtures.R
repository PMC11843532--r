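# Shared fixtures: small acquisition geometries, a delta IRF, and the
# Bateman closed form used as the independent kinetics oracle.

test_config <- function(n_bins = 1024L, rep_rate_mhz = 80) {
  acq_config(rep_rate_mhz = rep_rate_mhz, n_bins = n_bins)
}

test_delta_irf <- function(config) {
  w <- numeric(config$n_bins)
  w[1] <- 1
  irf_profile(w, config)
}

# Noiseless integer histogram of a decay model (expected curve scaled to a
# large photon total and rounded).
noiseless_histogram <- function(model, config, irf = test_delta_irf(config),
                                total = 1e7) {
  mu <- expected_curve(model, irf, config)
  decay_histogram(round(mu * total / sum(mu)), config)
}

# Independent closed-form solution of the irreversible linear chain
# M -> A -> B -> F (distinct rates assumed). Written directly from the
# classical first-order-chain solution, not via the package integrator.
bateman_chain <- function(k1, k2, k3, m0, t) {
  M <- m0 * exp(-k1 * t)
  A <- m0 * k1 * (exp(-k1 * t) - exp(-k2 * t)) / (k2 - k1)
  B <- m0 * k1 * k2 * (
    exp(-k1 * t) / ((k2 - k1) * (k3 - k1)) +
    exp(-k2 * t) / ((k1 - k2) * (k3 - k2)) +
    exp(-k3 * t) / ((k1 - k3) * (k2 - k3))
  )
  cbind(monomer = M, typeA = A, typeB = B, fibril = m0 - M - A - B)
}

# Reference phasor set of n points centered at `centers` (2-column matrix)
# with fixed error bars; used for classification threshold fixtures.
fixture_reference <- function(centers, g_err = 0.05, s_err = 0.05,
                              label = "fibril") {
  pts <- lapply(seq_len(nrow(centers)), function(i) {
    phasor_point(centers[i, 1], centers[i, 2], g_err, s_err)
  })
  reference_phasor_set(label, pts, seq_len(nrow(centers)))
}
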