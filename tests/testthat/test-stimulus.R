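# Skin-patch geometry, moving-edge kinematics, patch noise, and clocks.

test_that("build_grid produces the expected lattices and rejects bad input", {
  g <- build_grid(12, 12, 0.1)
  expect_equal(nrow(g$positions), 121^2)
  expect_equal(g$positions[1, ], c(x = 0, y = 0))
  expect_equal(g$positions[2, ], c(x = 0.1, y = 0))  # row-major: x fastest
  expect_true(all(g$positions[, 1] <= 12 & g$positions[, 2] <= 12))

  g2 <- build_grid(0.1, 0.1, 0.1)
  expect_equal(nrow(g2$positions), 4)

  expect_error(build_grid(12, 12, -1), "invalid-argument")
  expect_error(build_grid(12, 11.95, 0.1), "invalid-argument")
})

test_that("edge_distance matches analytic point-line geometry", {
  patch <- PATCH12
  # 0 deg edge: line perpendicular to motion; find t where line is at x = 5
  sw <- sweep_interval(edge_stimulus(0), patch)
  v <- 30 / 1000
  t_at5 <- (5 - sw$stimulus$s0) / v
  expect_equal(edge_distance(c(6, 0), sw$stimulus, t_at5), 1.0)
  expect_equal(edge_distance(c(5, 7.3), sw$stimulus, t_at5), 0)

  # 45 deg edge through (5, 0): perpendicular distance to (6, 0) is sqrt(2)/2
  sw45 <- sweep_interval(edge_stimulus(45), patch)
  n <- sw45$stimulus$normal
  t_through <- (sum(c(5, 0) * n) - sw45$stimulus$s0) / (v * n[1])
  expect_equal(edge_distance(c(6, 0), sw45$stimulus, t_through),
               sqrt(2) / 2, tolerance = 1e-12)
})

test_that("edge distance is invariant along the edge direction", {
  set.seed(42)
  for (i in 1:20) {
    th <- runif(1, -80, 80)
    sw <- sweep_interval(edge_stimulus(th), PATCH12)
    e_dir <- c(-sin(th * pi / 180), cos(th * pi / 180))
    pt <- runif(2, 0, 12)
    t <- runif(1, 0, sw$clock$t_end)
    d0 <- edge_distance(pt, sw$stimulus, t)
    d1 <- edge_distance(pt + runif(1, -5, 5) * e_dir, sw$stimulus, t)
    expect_equal(d0, d1, tolerance = 1e-9)
  }
})

test_that("sweep_interval covers the stated travel", {
  # window T ms at 30 mm/s -> speed * T of travel centred on the patch
  for (w in c(5, 50)) {
    sw <- sweep_interval(edge_stimulus(0, window_ms = w), PATCH12)
    travel <- (30 / 1000) * (sw$clock$t_end - sw$clock$t_start)
    expect_equal(travel, 30 / 1000 * w)
    mid_s <- sw$stimulus$s0 + (30 / 1000) * (sw$clock$t_end / 2)
    expect_equal(mid_s, 6, tolerance = 1e-9)  # centred on the patch
  }
  # unlimited with 2 mm margin on a 12 mm patch: 16 mm ~ 533 ms at 30 mm/s
  sw <- sweep_interval(edge_stimulus(0), PATCH12, margin = 2)
  expect_equal(sw$clock$t_end, ceiling(16 / 0.03))
  expect_equal(sw$stimulus$s0, -2)
})

test_that("windowed trajectories are sub-segments of the unlimited one", {
  swu <- sweep_interval(edge_stimulus(10), PATCH12)
  for (w in c(5, 20, 50)) {
    sww <- sweep_interval(edge_stimulus(10, window_ms = w), PATCH12)
    v <- (30 / 1000) * sww$stimulus$normal[1]
    expect_gt(sww$stimulus$s0, swu$stimulus$s0)
    expect_lt(sww$stimulus$s0 + v * sww$clock$t_end,
              swu$stimulus$s0 + v * swu$clock$t_end)
  }
})

test_that("noise fields are bounded, seeded, and vanish at level 0", {
  nf0 <- make_noise_field(0, PATCH12, seed = 3)
  expect_true(all(nf0$offsets == 0))
  expect_equal(local_amplitude(cbind(runif(5, 0, 12), runif(5, 0, 12)), 0.5, nf0),
               rep(0.5, 5))

  nf <- make_noise_field(10, PATCH12, seed = 7)
  expect_equal(dim(nf$offsets), c(30, 30))
  expect_true(all(abs(nf$offsets) <= 0.05))
  nf2 <- make_noise_field(10, PATCH12, seed = 7)
  expect_identical(nf$offsets, nf2$offsets)
  expect_false(identical(nf$offsets, make_noise_field(10, PATCH12, seed = 8)$offsets))

  # empirical bound at 5%: many draws never exceed 5% of the 0.5 mm
  # amplitude, i.e. 0.025 mm
  set.seed(123)
  big <- replicate(30, max(abs(make_noise_field(
    5, PATCH12, seed = sample.int(1e6, 1))$offsets)))
  expect_true(all(big <= 0.025))

  expect_error(make_noise_field(-1, PATCH12), "invalid-argument")
})

test_that("local_amplitude clamps at zero and rejects outside points", {
  nf <- make_noise_field(10, PATCH12, seed = 1)
  nf$offsets[1, 1] <- -0.6   # hypothetical huge negative offset
  expect_equal(local_amplitude(c(0.1, 0.1), 0.5, nf), 0)
  expect_error(local_amplitude(c(13, 1), 0.5, nf), "out-of-bounds")
})

test_that("a level-0 noise field reproduces the noiseless response exactly", {
  n <- make_synthetic_neuron(n_mr = 8, seed = 2)
  sw <- sweep_interval(edge_stimulus(22.5), PATCH12)
  nf0 <- make_noise_field(0, PATCH12, seed = 99)
  expect_identical(simulate_neuron(n, sw$stimulus, sw$clock)$times,
                   simulate_neuron(n, sw$stimulus, sw$clock, noise = nf0)$times)
})
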