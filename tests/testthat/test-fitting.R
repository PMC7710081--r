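# R^2 fitness, GA machinery, model selection, null models, baselines.

test_that("r2_score reproduces hand computations and flags degeneracy", {
  expect_equal(as.numeric(r2_score(c(1, 2, 3), c(1, 2, 3))), 1)
  o <- c(0, 10, 20, 10)
  expect_equal(as.numeric(r2_score(rep(mean(o), 4), o)), 0)
  m <- c(0, 10, 10, 10)
  # by hand: residual 100/4 = 25, total variance 50, ratio 0.5
  s <- r2_score(m, o)
  expect_equal(as.numeric(s), 0.5)
  expect_equal(attr(s, "raw_ratio"), 0.5)
  expect_error(r2_score(c(1, 2), c(3, 3)), "undefined-variance")
  expect_error(r2_score(c(1, 2), c(1, 2, 3)), "invalid-argument")
})

test_that("ga_optimize recovers a known optimum and is reproducible", {
  target <- c(0.3, -0.6)
  obj <- function(g) -sum((g - target)^2)
  cfg <- ga_config(population_size = 30, iterations = 200, seed = 17)
  run <- function() {
    ga_optimize(
      obj,
      init_fn = function() runif(2, -1, 1),
      mutate_fn = function(g) pmin(1, pmax(-1, g + rnorm(2, 0, 0.1))),
      crossover_fn = function(a, b) ifelse(runif(2) < 0.5, a, b),
      config = cfg)
  }
  r1 <- run()
  expect_lt(sqrt(-r1$fitness), 0.02 * 2)   # within 1% of the [-1, 1] range
  expect_true(all(diff(r1$trace) >= 0))    # running max is non-decreasing
  r2 <- run()
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best, r2$best)
  expect_error(ga_config(population_size = 1), "invalid-argument")
})

test_that("pure selection (no mutation/crossover) still improves fitness", {
  obj <- function(g) -abs(g)
  cfg <- ga_config(population_size = 20, mutation_p = 0, crossover_p = 0,
                   iterations = 20, seed = 2)
  r <- ga_optimize(obj, function() runif(1, -1, 1), identity,
                   function(a, b) a, cfg)
  expect_true(all(diff(r$trace) >= 0))
})

test_that("fitness over orientations is exact for the generating neuron", {
  ds <- synth_recordings(make_synthetic_neuron(n_mr = 6, seed = 4),
                         n_trials = 2, jitter = jitter_model(0, 0), seed = 9)
  expect_equal(fitness_over_orientations(ds$truth, ds), 1, tolerance = 1e-9)
})

test_that("select_model applies the three filters in order", {
  fake <- function(train, cv, n_mr) {
    structure(list(model = NULL, n_mr = n_mr,
                   train_fitness = rep(train, 4),
                   mean_train_fitness = train,
                   crossval_fitness = cv, test_fitness = NA_real_),
              class = "candidate_model")
  }
  # single candidate -> itself
  one <- fake(0.9, 0.8, 10)
  expect_identical(select_model(list(one)), one)
  # equal fits, 10 vs 40 MRs -> the 10-MR model wins via the count filter
  a <- fake(0.9, 0.8, 10); b <- fake(0.9, 0.8, 40)
  expect_identical(select_model(list(b, a)), a)
  # a candidate failing the per-orientation 5% filter loses even with the
  # best cross-validation accuracy
  good <- fake(0.9, 0.7, 20)
  bad <- fake(0.7, 0.95, 20)
  expect_identical(select_model(list(bad, good)), good)
  # order independence
  expect_identical(select_model(list(good, bad)), good)
  expect_error(select_model(list()), "invalid-argument")
})

test_that("null models preserve structure but shuffle locations", {
  ds <- synth_recordings(make_synthetic_neuron(n_mr = 8, seed = 5),
                         n_trials = 2, jitter = jitter_model(0, 0), seed = 2)
  null <- make_null_model(ds$truth, ds$boundary, seed = 3)
  expect_equal(nrow(null$mr_locations), 8)
  expect_identical(null$responsivity, ds$truth$responsivity)
  expect_true(all(region_contains(ds$boundary, null$mr_locations)))
  expect_false(isTRUE(all.equal(null$mr_locations, ds$truth$mr_locations)))
  expect_identical(make_null_model(ds$truth, ds$boundary, seed = 3)$mr_locations,
                   null$mr_locations)
})

test_that("nearest-edge baseline behaves on constructed responses", {
  ds <- synth_recordings(make_synthetic_neuron(n_mr = 6, seed = 4),
                         n_trials = 2, jitter = jitter_model(0, 0), seed = 9)
  # identical responses at both orientations -> 1.0
  ds_same <- ds
  ds_same$mean_rates[["22.5"]] <- ds_same$mean_rates[["30"]]
  expect_equal(as.numeric(nearest_edge_prediction(ds_same)), 1)
  # a time-shifted copy scores below 1
  shifted <- ds$mean_rates[["30"]]
  shifted$rate <- c(rep(0, 25), shifted$rate[seq_len(length(shifted$rate) - 25)])
  ds_shift <- ds
  ds_shift$mean_rates[["22.5"]] <- shifted
  expect_lt(as.numeric(nearest_edge_prediction(ds_shift)), 1)
  # constant test response -> undefined variance
  ds_const <- ds
  ds_const$mean_rates[["30"]]$rate <- rep(2, length(ds_const$mean_rates[["30"]]$rate))
  expect_error(nearest_edge_prediction(ds_const), "undefined-variance")
})

test_that("fitting a small synthetic neuron recovers its response", {
  # reduced GA on a 5-MR jitter-free target; checks the recovery pathway
  # end to end (the full-size recovery is exercised in the acceptance suite)
  ds <- synth_recordings(make_synthetic_neuron(n_mr = 5, seed = 21),
                         n_trials = 2, jitter = jitter_model(0, 0), seed = 22)
  expect_warning(
    cand <- fit_neuron(ds, n_mr = 5,
                       config = ga_config(population_size = 30,
                                          iterations = 60, seed = 23)),
    "published ladder")
  expect_gt(cand$mean_train_fitness, 0.5)
  expect_true(all(region_contains(ds$boundary, cand$model$mr_locations)))
  expect_true(all(diff(cand$trace) >= 0))
})
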