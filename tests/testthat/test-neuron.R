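# The FA-1 model neuron: input equation, branch stepping, spiking schemes,
# rate curves, and the dot-scan receptive-field boundary.

test_that("mr_input follows the sigmoidal responsivity equation", {
  p <- responsivity_params(0.5, 0.5, 100)
  expect_equal(mr_input(1.5 + 1e-9, 0.5, p), 0)          # beyond r1 + r2
  expect_equal(mr_input(0.5, 0.5, p), 25)                # half drive at d = r1
  expect_equal(mr_input(0, 0.5, p), 0.5 * 100 * (1 - 1 / (1 + exp(5))),
               tolerance = 1e-9)
  # against an independent transcription, over a distance sweep
  d <- seq(0, 2, by = 0.05)
  expect_equal(mr_input(d, 0.5, p), eq1_reference(d, 0.5, 100, 0.5, 0.5))
  expect_error(mr_input(-0.1, 0.5, p), "invalid-argument")
})

test_that("effective indentation gates spiking at 0.01 mm", {
  p <- responsivity_params(0.5, 0.5, 100)
  expect_equal(effective_indentation(0, 0.5, p),
               0.5 * (1 - 1 / (1 + exp(5))), tolerance = 1e-9)
  expect_lt(effective_indentation(0, 0.005, p), 0.01)    # silent branch
  expect_equal(effective_indentation(1.6, 0.5, p), 0)
  # an amplitude below 0.01 / sigmoid(0) can never evoke spikes
  n <- make_synthetic_neuron(n_mr = 5, seed = 1)
  sw <- sweep_interval(edge_stimulus(0, amplitude = 0.005), PATCH12)
  expect_length(simulate_neuron(n, sw$stimulus, sw$clock)$times, 0)
})

test_that("step_branch implements accumulate / adapt / saturate", {
  st <- branch_rest_state()
  # zero input: never fires, state frozen
  for (i in 1:5) {
    r <- step_branch(st, 0, 1, 100)
    expect_false(r$spike)
    st <- r$state
  }
  # constant input after onset: one primed onset spike, then adaptation
  st <- branch_rest_state()
  r <- step_branch(st, 50, 1, 100, eff = 0.5)
  expect_true(r$spike)
  for (i in 1:20) {
    r <- step_branch(r$state, 50, 1, 100, eff = 0.5)
    expect_false(r$spike)
  }
  # strictly increasing ramp at saturation: ISI approaches 1000 / max_rate
  st <- branch_rest_state()
  spikes <- c()
  I <- 200
  for (t in 1:200) {
    I <- I + 1                       # increasing, saturated at max_rate = 100
    r <- step_branch(st, I, 1, 100, eff = 0.5)
    if (r$spike) spikes <- c(spikes, t)
    st <- r$state
  }
  expect_equal(tail(diff(spikes), 3), rep(10, 3))   # 1000 / 100 Hz
})

test_that("compiled simulation matches the brute-force oracle exactly", {
  set.seed(7)
  for (scheme in c("reset", "mixing", "summation")) {
    for (rep in 1:4) {
      nmr <- sample(1:3, 1)
      n <- neuron_model(cbind(runif(nmr, 5, 7), runif(nmr, 5, 7)),
                        responsivity_params(runif(1, 0.2, 0.8),
                                            runif(1, 0.2, 0.8), 200),
                        max_rate = 100, scheme = scheme)
      sw <- sweep_interval(edge_stimulus(runif(1, -45, 45)), PATCH12)
      clock <- simulation_clock(0, 50 + 250, 1)
      sw$stimulus$s0 <- 5 - 0.03 * 150 * sw$stimulus$normal[1]  # near the MRs
      fast <- simulate_neuron(n, sw$stimulus, clock)
      slow <- brute_force_simulate(n, sw$stimulus, clock)
      expect_identical(fast$times, slow$times)
    }
  }
})

test_that("reset output is invariant to MR order and duplication", {
  n <- make_synthetic_neuron(n_mr = 6, seed = 11)
  sw <- sweep_interval(edge_stimulus(-22.5), PATCH12)
  base <- simulate_neuron(n, sw$stimulus, sw$clock)$times
  perm <- n
  perm$mr_locations <- perm$mr_locations[sample(6), ]
  expect_identical(simulate_neuron(perm, sw$stimulus, sw$clock)$times, base)
  dup <- n
  dup$mr_locations <- rbind(dup$mr_locations, dup$mr_locations[3, ])
  expect_identical(simulate_neuron(dup, sw$stimulus, sw$clock)$times, base)
})

test_that("schemes coincide for single-MR neurons and mixing >= reset", {
  loc <- matrix(c(6, 6), ncol = 2)
  p <- responsivity_params(0.5, 0.5, 240)
  sw <- sweep_interval(edge_stimulus(5), PATCH12)
  trains <- lapply(c("reset", "mixing", "summation"), function(s) {
    simulate_neuron(neuron_model(loc, p, 120, s), sw$stimulus, sw$clock)$times
  })
  expect_identical(trains[[1]], trains[[2]])
  expect_identical(trains[[1]], trains[[3]])

  n2 <- neuron_model(rbind(c(5.5, 6), c(6.5, 6)), p, 120)
  m2 <- n2; m2$scheme <- "mixing"
  expect_gte(length(simulate_neuron(m2, sw$stimulus, sw$clock)$times),
             length(simulate_neuron(n2, sw$stimulus, sw$clock)$times))
})

test_that("instantaneous rate never exceeds max_rate after onset", {
  set.seed(13)
  for (rep in 1:5) {
    n <- make_synthetic_neuron(n_mr = sample(3:12, 1), max_rate = 80,
                               seed = rep)
    sw <- sweep_interval(edge_stimulus(runif(1, -45, 45)), PATCH12)
    nf <- make_noise_field(10, PATCH12, seed = rep)
    t <- simulate_neuron(n, sw$stimulus, sw$clock, noise = nf)$times
    if (length(t) > 2) {
      expect_gte(min(diff(t[-1])), floor(1000 / 80))
    }
  }
})

test_that("no spikes once the edge has receded from all MRs", {
  n <- make_synthetic_neuron(n_mr = 10, seed = 3)
  sw <- sweep_interval(edge_stimulus(0), PATCH12)
  t <- simulate_neuron(n, sw$stimulus, sw$clock)$times
  # time at which the line passes the last MR's reach
  reach <- n$responsivity$r1 + n$responsivity$r2
  b_max <- max(n$mr_locations %*% sw$stimulus$normal)
  t_gone <- (b_max + reach - sw$stimulus$s0) / 0.03
  expect_true(all(t <= t_gone))
})

test_that("rate_curve integrates to the spike count and peaks in between", {
  empty <- spike_train(numeric(0), 300)
  expect_true(all(rate_curve(empty)$rate == 0))

  one <- spike_train(150, 300)
  rc1 <- rate_curve(one, smoothing_sigma = 5)
  expect_equal(sum(rc1$rate) * 1e-3, 1, tolerance = 1e-6)

  two <- spike_train(c(148, 152), 300)
  rc2 <- rate_curve(two, smoothing_sigma = 5)
  # direct kernel summation at the midpoint and integral = 2
  expect_equal(sum(rc2$rate) * 1e-3, 2, tolerance = 1e-6)
  expect_equal(which.max(rc2$rate) - 1, 150)
  ref <- sum(dnorm(c(-2, 2), sd = 5)) / sum(dnorm(seq(-30, 30), sd = 5)) * 1000
  expect_equal(max(rc2$rate), ref, tolerance = 1e-6)
})

test_that("simple-RF neurons have the prescribed responsivity", {
  n <- make_simple_rf_neuron(c(6, 6), max_rate = 100)
  # reach r1 + r2 = 1.5 mm, the average recorded RF size
  expect_equal(n$responsivity$r1 + n$responsivity$r2, 1.5)
  expect_equal(n$responsivity$w_mr, 200)
  # half-maximal drive at d = r1; zero beyond the reach
  expect_equal(mr_input(n$responsivity$r1, 0.5, n$responsivity), 0.5 * 200 / 2)
  expect_equal(mr_input(2, 0.5, n$responsivity), 0)
  # the profile is genuinely extended: substantial drive at 1 mm
  expect_gt(mr_input(1, 0.5, n$responsivity), 0.25 * 0.5 * 200)
})

test_that("dot-scan boundary approximates the responsive disc union", {
  # r2 < 0.78 * r1 so the indentation threshold cuts nothing: the responsive
  # region is the full r1 + r2 disc around each MR
  p <- responsivity_params(0.8, 0.6, 240)
  n1 <- neuron_model(matrix(c(6, 6), ncol = 2), p, 120)
  b <- rf_boundary_from_dot_scan(n1, PATCH12, scan_spacing = 0.15)
  d <- sqrt(rowSums(sweep(b$points, 2, c(6, 6))^2))
  expect_lt(max(d), 1.4 + 0.15)            # never outside the reach disc
  expect_gt(max(d), 1.4 * 0.75)            # fills most of it

  # two distant MRs: responsive points cluster around both
  n2 <- neuron_model(rbind(c(3.5, 6), c(8.5, 6)), p, 120)
  b2 <- rf_boundary_from_dot_scan(n2, PATCH12, scan_spacing = 0.15)
  d1 <- sqrt(rowSums(sweep(b2$points, 2, c(3.5, 6))^2))
  d2 <- sqrt(rowSums(sweep(b2$points, 2, c(8.5, 6))^2))
  expect_true(all(pmin(d1, d2) < 1.4 + 0.15))
  expect_true(any(d1 < 1.0) && any(d2 < 1.0))

  expect_error(rf_boundary_from_dot_scan(n1, PATCH12, dot_amplitude = 0),
               "empty-region")
})

test_that("region membership and sampling respect the boundary", {
  n <- make_synthetic_neuron(n_mr = 10, seed = 3)
  b <- rf_boundary_from_dot_scan(n, PATCH12)
  set.seed(1)
  pts <- sample_in_region(b, 40)
  expect_true(all(region_contains(b, pts)))
  expect_false(any(region_contains(b, rbind(c(0.2, 0.2), c(11.8, 11.8)))))
})
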