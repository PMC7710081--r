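# Fitting model neurons to multi-trial spike recordings: the R^2 fitness over
# the four training orientations, the GA over mechanoreceptor locations and
# (r1, r2), the model-selection ladder with cross-validation, shuffled null
# models, and the nearest-edge baseline predictor.

TRAIN_ORIENTATIONS <- c(-22.5, 22.5, -45, 45)
CROSSVAL_ORIENTATION <- 0
TEST_ORIENTATION <- 30

R1_LIMITS <- c(0.05, 1)
R2_LIMITS <- c(0.2, 1)

orient_key <- function(x) sprintf("%g", x)

#' Coefficient of determination between two rate curves
#'
#' `1 - <(SR_m - SR_o)^2> / <(SR_o - mean(SR_o))^2>`; the raw residual/total
#' variance ratio is attached as attribute `"raw_ratio"`. May be negative.
#'
#' @param model_rate,observed_rate `rate_curve` objects (or numeric vectors)
#'   on identical grids.
#' @return R^2 (dimensionless), with attribute `raw_ratio`.
#' @export
r2_score <- function(model_rate, observed_rate) {
  m <- if (inherits(model_rate, "rate_curve")) model_rate$rate else model_rate
  o <- if (inherits(observed_rate, "rate_curve")) observed_rate$rate else observed_rate
  if (length(m) != length(o)) {
    stop("invalid-argument: rate curves must share one time grid", call. = FALSE)
  }
  denom <- mean((o - mean(o))^2)
  if (denom < 1e-12) {
    stop("undefined-variance: observed rate curve is constant", call. = FALSE)
  }
  ratio <- mean((m - o)^2) / denom
  structure(1 - ratio, raw_ratio = ratio)
}

#' Assemble a fitting dataset
#'
#' @param trains Named list (orientation as printed by `sprintf("%g", x)`) of
#'   lists of [spike_train()]s, covering at least the four training
#'   orientations, the 0 deg cross-validation orientation and the 30 deg test
#'   orientation.
#' @param boundary An `rf_region` delimiting admissible MR locations.
#' @param patch Skin patch (extents list or `mr_grid`).
#' @param smoothing_sigma Rate-curve kernel width, ms.
#' @param speed,amplitude Stimulus parameters shared by all recordings.
#' @param margin Sweep margin, mm.
#' @return A `fit_dataset`: trial trains, per-orientation positioned stimuli
#'   and clocks, trial-mean rate curves, the maximal observed smoothed rate
#'   (sets `max_rate` and `w_mr = 2 * max_rate` of fitted models).
#' @export
fit_dataset <- function(trains, boundary, patch, smoothing_sigma = 5,
                        speed = 30, amplitude = 0.5, margin = 2) {
  need <- orient_key(c(TRAIN_ORIENTATIONS, CROSSVAL_ORIENTATION, TEST_ORIENTATION))
  missing <- setdiff(need, names(trains))
  if (length(missing)) {
    stop("invalid-argument: missing orientations: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stimuli <- lapply(names(trains), function(k) {
    sweep_interval(edge_stimulus(as.numeric(k), speed = speed,
                                 amplitude = amplitude), patch, margin)
  })
  names(stimuli) <- names(trains)
  mean_rates <- lapply(trains, mean_rate_curve, smoothing_sigma = smoothing_sigma)
  max_rate <- max(vapply(orient_key(TRAIN_ORIENTATIONS),
                         function(k) max(mean_rates[[k]]$rate), numeric(1)))
  structure(list(trains = trains, stimuli = stimuli, mean_rates = mean_rates,
                 boundary = boundary, patch = patch, max_rate = max_rate,
                 smoothing_sigma = smoothing_sigma),
            class = "fit_dataset")
}

# Simulate a candidate on one stored stimulus and score it against the
# trial-mean observed rate.
score_orientation <- function(model, dataset, key) {
  st <- dataset$stimuli[[key]]
  train <- simulate_neuron(model, st$stimulus, st$clock)
  r2_score(rate_curve(train, dataset$smoothing_sigma),
           dataset$mean_rates[[key]])
}

#' Mean fitness over the four training orientations
#'
#' @param model A [neuron_model()].
#' @param dataset A [fit_dataset()].
#' @return Mean R^2 over the training orientations (model rate vs the
#'   trial-mean observed rate).
#' @export
fitness_over_orientations <- function(model, dataset) {
  mean(vapply(orient_key(TRAIN_ORIENTATIONS),
              function(k) as.numeric(score_orientation(model, dataset, k)),
              numeric(1)))
}

genome_to_model <- function(genome, dataset) {
  neuron_model(genome$locs,
               responsivity_params(genome$r1, genome$r2, 2 * dataset$max_rate),
               dataset$max_rate)
}

#' Fit a model neuron to a dataset with the genetic algorithm
#'
#' Free parameters are the `n_mr` mechanoreceptor locations (initialised
#' uniformly at random inside, and constrained throughout to, the dataset's
#' receptive-field boundary) and the responsivity distances `r1` in
#' `[0.05, 1]`, `r2` in `[0.2, 1]` mm. Mutation perturbs locations with a
#' Gaussian step (sd 0.3 mm, proposals outside the boundary are retried and
#' finally kept in place) and `r1`/`r2` with reflected Gaussian steps;
#' crossover mixes MR slots uniformly.
#'
#' @param dataset A [fit_dataset()].
#' @param n_mr Number of mechanoreceptors; the published protocol uses
#'   10, 20, 30 or 40 (other values are allowed with a warning, for
#'   small-scale tests).
#' @param config A [ga_config()].
#' @param loc_sigma Location mutation step, mm.
#' @return A `candidate_model`: the fitted [neuron_model()], per-orientation
#'   training R^2, cross-validation (0 deg) and test (30 deg) R^2, `n_mr`,
#'   and the GA fitness trace.
#' @export
fit_neuron <- function(dataset, n_mr, config = ga_config(iterations = 500),
                       loc_sigma = 0.3) {
  stopifnot(inherits(dataset, "fit_dataset"))
  if (!n_mr %in% c(10, 20, 30, 40)) {
    warning("n_mr outside the published ladder {10, 20, 30, 40}")
  }
  boundary <- dataset$boundary
  init_fn <- function() {
    list(r1 = runif(1, R1_LIMITS[1], R1_LIMITS[2]),
         r2 = runif(1, R2_LIMITS[1], R2_LIMITS[2]),
         locs = sample_in_region(boundary, n_mr))
  }
  mutate_fn <- function(g) {
    g$r1 <- reflect(g$r1 + rnorm(1, 0, 0.05), R1_LIMITS[1], R1_LIMITS[2])
    g$r2 <- reflect(g$r2 + rnorm(1, 0, 0.05), R2_LIMITS[1], R2_LIMITS[2])
    which_mr <- which(runif(n_mr) < 0.3)
    for (j in which_mr) {
      for (try in 1:8) {
        cand <- g$locs[j, ] + rnorm(2, 0, loc_sigma)
        if (region_contains(boundary, cand)) {
          g$locs[j, ] <- cand
          break
        }
      }
    }
    g
  }
  crossover_fn <- function(a, b) {
    take <- runif(n_mr) < 0.5
    a$locs[take, ] <- b$locs[take, , drop = FALSE]
    if (runif(1) < 0.5) a$r1 <- b$r1
    if (runif(1) < 0.5) a$r2 <- b$r2
    a
  }
  objective <- function(g) {
    fitness_over_orientations(genome_to_model(g, dataset), dataset)
  }
  res <- ga_optimize(objective, init_fn, mutate_fn, crossover_fn, config)
  model <- genome_to_model(res$best, dataset)
  candidate_model(model, dataset, n_mr, trace = res$trace, config = config)
}

#' Score a model on all orientation roles of a dataset
#' @keywords internal
candidate_model <- function(model, dataset, n_mr, trace = NULL, config = NULL) {
  train_fit <- vapply(orient_key(TRAIN_ORIENTATIONS),
                      function(k) as.numeric(score_orientation(model, dataset, k)),
                      numeric(1))
  structure(
    list(model = model, n_mr = n_mr, train_fitness = train_fit,
         mean_train_fitness = mean(train_fit),
         crossval_fitness = as.numeric(
           score_orientation(model, dataset, orient_key(CROSSVAL_ORIENTATION))),
         test_fitness = as.numeric(
           score_orientation(model, dataset, orient_key(TEST_ORIENTATION))),
         trace = trace, config = config),
    class = "candidate_model"
  )
}

#' Select one model from candidates fitted with different MR counts
#'
#' Applies the published three-stage filter: (1) keep models whose training
#' R^2 is within 5% (multiplicative) of the per-orientation maximum for every
#' training orientation; (2) of those, keep models with cross-validation R^2
#' within 5% of the maximum; (3) of those, keep models within 5
#' mechanoreceptors of the minimum count. The survivor with the best
#' cross-validation R^2 is returned. If a stage empties the set it is skipped
#' with a warning.
#'
#' @param candidates List of `candidate_model`s.
#' @return The selected `candidate_model`.
#' @export
select_model <- function(candidates) {
  if (!length(candidates)) {
    stop("invalid-argument: empty candidate list", call. = FALSE)
  }
  keep <- candidates
  # 5% relative slack; for possibly non-positive R^2 the band is one-sided
  within5 <- function(x, mx) x >= mx - 0.05 * abs(mx)
  train_mat <- vapply(keep, `[[`, numeric(4), "train_fitness")
  per_max <- apply(train_mat, 1, max)
  ok <- apply(train_mat, 2, function(col) all(within5(col, per_max)))
  if (any(ok)) keep <- keep[ok] else warning("training-fitness filter empty; skipped")
  cv <- vapply(keep, `[[`, numeric(1), "crossval_fitness")
  ok <- within5(cv, max(cv))
  if (any(ok)) keep <- keep[ok] else warning("cross-validation filter empty; skipped")
  nmr <- vapply(keep, `[[`, numeric(1), "n_mr")
  ok <- nmr <= min(nmr) + 5
  keep <- keep[ok]
  cv <- vapply(keep, `[[`, numeric(1), "crossval_fitness")
  keep[[which.max(cv)]]
}

#' Shuffled-location null model
#'
#' Preserves the fitted model's MR count, responsivity and maximal rate but
#' re-draws all mechanoreceptor locations uniformly inside the receptive-field
#' boundary.
#'
#' @param model A [neuron_model()].
#' @param boundary An `rf_region`.
#' @param seed RNG seed.
#' @export
make_null_model <- function(model, boundary, seed = 1L) {
  locs <- with_seed(seed, sample_in_region(boundary, nrow(model$mr_locations)))
  neuron_model(locs, model$responsivity, model$max_rate, model$scheme)
}

#' Nearest-edge baseline prediction of the test response
#'
#' R^2 of the trial-mean 22.5 deg rate curve against the trial-mean 30 deg
#' rate curve. The two sweeps differ slightly in duration, so both curves are
#' truncated to the shorter grid.
#'
#' @param dataset A [fit_dataset()].
#' @export
nearest_edge_prediction <- function(dataset) {
  near <- dataset$mean_rates[[orient_key(22.5)]]
  test <- dataset$mean_rates[[orient_key(TEST_ORIENTATION)]]
  if (is.null(near) || is.null(test)) {
    stop("invalid-argument: need 22.5 and 30 degree responses", call. = FALSE)
  }
  n <- min(length(near$rate), length(test$rate))
  r2_score(near$rate[seq_len(n)], test$rate[seq_len(n)])
}
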