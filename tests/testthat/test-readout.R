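# PSP kernels, convolution, unit responses, classification, GA training.

test_that("psp_kernel matches the closed-form difference of exponentials", {
  k <- psp_kernel(tau_rise = 0.5, tau_decay = 3, dt = 0.01,
                  normalization = "raw")
  expect_equal(k$values[1], 0)                       # exponentials cancel at 0
  t_star <- log(3 / 0.5) / (1 / 0.5 - 1 / 3)         # analytic peak location
  expect_equal(t_star, 1.075056, tolerance = 1e-6)
  expect_equal(k$times[which.max(k$values)], t_star, tolerance = 0.011)
  # raw kernel areas: integral = tau_decay - tau_rise
  a3 <- sum(k$values) * 0.01
  k65 <- psp_kernel(tau_decay = 65, dt = 0.01, normalization = "raw")
  a65 <- sum(k65$values) * 0.01
  expect_equal(a3, 3 - 0.5, tolerance = 1e-2)
  expect_gt(a65, a3)
  # peak1 normalization
  kp <- psp_kernel(tau_decay = 3)
  expect_equal(max(kp$values), 1)
  expect_error(psp_kernel(tau_rise = 3, tau_decay = 3), "invalid-argument")
})

test_that("convolution equals the brute-force shifted-kernel sum", {
  set.seed(5)
  k <- psp_kernel(tau_decay = 3)
  for (rep in 1:5) {
    times <- sort(sample(0:180, sample(1:12, 1)))
    tr <- spike_train(times, 200)
    trace <- convolve_psp(tr, k, 220)
    ref <- numeric(220)
    for (ts in times) {
      shifted <- c(rep(0, ts), k$values)[1:220]
      shifted[is.na(shifted)] <- 0
      ref <- ref + shifted
    }
    expect_equal(trace, ref, tolerance = 1e-12)
  }
  expect_equal(convolve_psp(spike_train(numeric(0), 100), k), numeric(101))
  one <- convolve_psp(spike_train(40, 100), k)
  expect_equal(one[41:65], k$values[1:25])
})

test_that("NMDA dominates AMPA late under peak normalization", {
  ka <- psp_kernel(tau_decay = 3)
  kn <- psp_kernel(tau_decay = 65)
  tr <- spike_train(c(10, 30), 100)
  a <- convolve_psp(tr, ka, 400)
  n <- convolve_psp(tr, kn, 400)
  t_peak_a <- which.max(a)
  expect_true(all(n[t_peak_a:400] >= a[t_peak_a:400] - 1e-12))
})

test_that("unit responses are homogeneous and classification scale-free", {
  fx <- make_separable_fixture(seed = 2)
  f <- fx$features[[1]]
  w <- runif(ncol(f), -1, 1)
  expect_equal(unit_response(f, 2.5 * w), 2.5 * unit_response(f, w),
               tolerance = 1e-12)
  expect_equal(unit_response(f, rep(0, ncol(f))), 0)
  expect_error(unit_response(f, w[-1]), "invalid-argument")

  clf <- train_classifier(fx$features, fx$labels, fx$theta,
                          ga_config(population_size = 20, iterations = 20,
                                    seed = 3))
  scaled <- clf
  scaled$weights <- 0.5 * clf$weights
  labs <- vapply(fx$features, classify_trial, numeric(1), clf = clf)
  labs2 <- vapply(fx$features, classify_trial, numeric(1), clf = scaled)
  expect_identical(labs, labs2)
})

test_that("classify_trial picks the stronger unit and randomizes ties", {
  fx <- make_separable_fixture(seed = 4)
  clf <- classifier(fx$truth_weights, "ampa", fx$theta,
                    n_neurons = nrow(fx$truth_weights))
  labs <- vapply(fx$features, classify_trial, numeric(1), clf = clf)
  expect_identical(labs, fx$labels)     # truth weights separate perfectly
  zero <- clf
  zero$weights[] <- 0
  set.seed(1)
  expect_message(z <- classify_trial(fx$features[[1]], zero), "tie")
  expect_true(z %in% c(-fx$theta, fx$theta))
})

test_that("training on the separable fixture recovers perfect weights", {
  fx <- make_separable_fixture(n_trials = 10, seed = 6)
  clf <- train_classifier(fx$features, fx$labels, fx$theta,
                          ga_config(population_size = 30, iterations = 40,
                                    seed = 7))
  expect_equal(clf$train_success, 1)
  expect_equal(classifier_success(clf, fx$features, fx$labels), 1)
  expect_true(all(abs(clf$weights) <= 1))   # bounds respected
  expect_error(train_classifier(fx$features[-1], fx$labels[-1], fx$theta),
               "invalid-argument")          # unbalanced
})
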