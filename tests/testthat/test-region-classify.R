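test_that("overlap requires intersection in both error-bar directions", {
  a <- phasor_point(0.5, 0.5, 0.05, 0.05)
  expect_true(points_overlap(a, a))

  # separated in g beyond summed errors, coincident in s: not overlapping
  b <- phasor_point(0.65, 0.5, 0.05, 0.05)
  expect_false(points_overlap(a, b))

  # interval arithmetic: gaps 0.08 <= 0.10 in g and 0.04 <= 0.10 in s
  p <- phasor_point(0.30, 0.40, 0.05, 0.05)
  q <- phasor_point(0.38, 0.44, 0.05, 0.05)
  expect_true(points_overlap(p, q))

  expect_error(points_overlap(phasor_point(0.3, 0.4), phasor_point(0.3, 0.4)),
               "error bars")
})

test_that("points_overlap is symmetric and reflexive", {
  set.seed(7)
  for (i in 1:30) {
    p <- phasor_point(runif(1), runif(1), runif(1, 0.01, 0.1),
                      runif(1, 0.01, 0.1))
    q <- phasor_point(runif(1), runif(1), runif(1, 0.01, 0.1),
                      runif(1, 0.01, 0.1))
    expect_true(points_overlap(p, p))
    expect_identical(points_overlap(p, q), points_overlap(q, p))
  }
})

test_that("overlap_fraction counts exactly", {
  ref <- fixture_reference(cbind(c(0.5, 0.52, 0.48), c(0.5, 0.5, 0.5)))
  far <- lapply(1:5, function(i) phasor_point(0.9, 0.05, 0.01, 0.01))
  expect_equal(overlap_fraction(far, ref), 0)

  seg <- c(lapply(1:3, function(i) phasor_point(0.5, 0.5, 0.01, 0.01)),
           lapply(1:2, function(i) phasor_point(0.9, 0.05, 0.01, 0.01)))
  expect_equal(overlap_fraction(seg, ref), 0.6)

  for (k in 0:10) {
    seg <- c(lapply(seq_len(k), function(i) phasor_point(0.5, 0.5, 0.01, 0.01)),
             lapply(seq_len(10 - k), function(i) {
               phasor_point(0.9, 0.05, 0.01, 0.01)
             }))
    expect_equal(overlap_fraction(seg, ref), k / 10)
  }
  expect_error(overlap_fraction(list(), ref), "non-empty")
})

test_that("the fibrillar label switches exactly at 60% overlap", {
  ref <- fixture_reference(cbind(c(0.5, 0.52, 0.48), c(0.5, 0.5, 0.5)))
  labels <- vapply(0:10, function(k) {
    traj <- c(lapply(seq_len(k), function(i) phasor_point(0.5, 0.5, 0.01, 0.01)),
              lapply(seq_len(10 - k), function(i) {
                phasor_point(0.9, 0.05, 0.01, 0.01)
              }))
    assign_regions(traj, ref, window = 10)$label
  }, character(1))
  expect_equal(labels[0:10 >= 6], rep("fibrillar", 5))
  expect_false(any(labels[0:10 < 6] == "fibrillar"))
})

test_that("segments deviating from both references are Type-A", {
  fib <- fixture_reference(cbind(c(0.30, 0.32, 0.28), c(0.60, 0.60, 0.60)))
  oli <- fixture_reference(cbind(c(0.55, 0.57, 0.53), c(0.62, 0.62, 0.62)),
                           label = "stabilized_oligomer")
  traj <- lapply(1:5, function(i) phasor_point(0.95, 0.10, 0.01, 0.01))
  out <- assign_regions(traj, fib, oli, window = 5)
  expect_equal(out$label, "type_a_oligomeric")
  expect_equal(out$overlap_fibril, 0)
  expect_equal(out$overlap_oligomer, 0)

  on_fib <- lapply(1:5, function(i) phasor_point(0.30, 0.60, 0.01, 0.01))
  expect_equal(assign_regions(on_fib, fib, oli, window = 5)$label, "fibrillar")

  on_oli <- lapply(1:5, function(i) phasor_point(0.55, 0.62, 0.01, 0.01))
  expect_equal(assign_regions(on_oli, fib, oli, window = 5)$label,
               "type_b_oligomeric")
})

test_that("double qualification resolves to fibrillar and reports the tie", {
  fib <- fixture_reference(cbind(c(0.40, 0.42, 0.38), c(0.60, 0.60, 0.60)))
  oli <- fixture_reference(cbind(c(0.42, 0.44, 0.40), c(0.61, 0.61, 0.61)),
                           label = "stabilized_oligomer")
  traj <- lapply(1:5, function(i) phasor_point(0.41, 0.605, 0.03, 0.03))
  out <- assign_regions(traj, fib, oli, window = 5)
  expect_equal(out$label, "fibrillar")
  expect_true(out$tie)
  expect_gte(out$overlap_oligomer, 0.6)
})

test_that("classification is invariant to reference ordering and count scale", {
  set.seed(42)
  centers <- cbind(runif(8, 0.3, 0.5), runif(8, 0.5, 0.65))
  fib <- fixture_reference(centers)
  fib_shuffled <- reference_phasor_set(
    "fibril", rev(fib$points), rev(fib$concentrations_uM))
  traj <- lapply(1:10, function(i) {
    phasor_point(runif(1, 0.25, 0.6), runif(1, 0.45, 0.7), 0.02, 0.02)
  })
  expect_equal(assign_regions(traj, fib, window = 5)$label,
               assign_regions(traj, fib_shuffled, window = 5)$label)
})

test_that("segments partition the trajectory and preconditions hold", {
  fib <- fixture_reference(cbind(c(0.3, 0.32, 0.28), c(0.6, 0.6, 0.6)))
  traj <- lapply(1:13, function(i) phasor_point(0.9, 0.1, 0.01, 0.01))
  out <- assign_regions(traj, fib, window = 5)
  expect_equal(out$segment_start, c(1, 6))
  expect_equal(out$segment_end, c(5, 13)) # remainder merged into last
  expect_error(assign_regions(traj[1:3], fib, window = 5), "shorter")
  expect_error(assign_regions(traj, fib, window = 2), ">= 3")
})

test_that("overlap fraction grows with reference error bars", {
  traj <- lapply(seq(0.3, 0.7, length.out = 8), function(g) {
    phasor_point(g, 0.55, 0.005, 0.005)
  })
  centers <- cbind(c(0.5, 0.5, 0.5), c(0.55, 0.55, 0.55))
  fracs <- vapply(c(0.01, 0.05, 0.1, 0.2), function(e) {
    overlap_fraction(traj, fixture_reference(centers, g_err = e, s_err = e))
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  expect_gt(fracs[4], fracs[1])
})

test_that("simulated titration references span the chord with errors", {
  cfg <- test_config(512)
  prof <- preset("wt_like")$profile
  ref <- simulate_reference_set("fibril", prof, cfg, photons = 2e4,
                                seed = 3)
  expect_s3_class(ref, "reference_phasor_set")
  expect_equal(ref$label, "fibril")
  expect_true(all(vapply(ref$points, `[[`, numeric(1), "g_err") > 0))
  gs <- vapply(ref$points, `[[`, numeric(1), "g")
  # the points march down the chord in g as the titrated fraction grows
  expect_lt(stats::cor(gs, seq_along(gs)), -0.9)
})
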