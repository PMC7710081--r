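# Synthetic stand-in for the microneurography dataset: ground-truth model
# neurons with elliptical receptive fields, multi-trial jittered spike
# "recordings" to the full orientation protocol (+/-22.5 and +/-45 deg for
# training, 0 deg for cross-validation, 30 deg for testing), and a tiny
# separable classification fixture. Downstream code cannot tell synthetic
# datasets from loaded recordings.

#' Ground-truth synthetic neuron
#'
#' Mechanoreceptor locations are drawn uniformly inside an ellipse (axes
#' default 2-5 mm, in the range of recorded receptive-field footprints).
#'
#' @param n_mr Number of mechanoreceptors (the empirical mean is ~20).
#' @param rf_center Ellipse centre (mm).
#' @param rf_axes Semi-axes (mm).
#' @param rf_rotation_deg Ellipse rotation, degrees.
#' @param r1,r2 Responsivity distances, mm (within the fitting search limits
#'   by default).
#' @param max_rate Saturation rate, Hz; `w_mr = 2 * max_rate`.
#' @param seed RNG seed.
#' @return A [neuron_model()].
#' @export
make_synthetic_neuron <- function(n_mr = 10, rf_center = c(6, 6),
                                  rf_axes = c(2.5, 1.5), rf_rotation_deg = 0,
                                  r1 = 0.5, r2 = 0.5, max_rate = 120,
                                  seed = 1L) {
  if (any(rf_axes <= 0)) stop("invalid-argument: ellipse axes must be > 0",
                              call. = FALSE)
  th <- rf_rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  locs <- with_seed(seed, {
    out <- matrix(NA_real_, 0, 2)
    while (nrow(out) < n_mr) {
      u <- matrix(runif(2 * n_mr * 2, -1, 1), ncol = 2)
      u <- u[rowSums(u^2) <= 1, , drop = FALSE]
      out <- rbind(out, u)
    }
    out <- out[seq_len(n_mr), , drop = FALSE]
    sweep(sweep(out, 2, rf_axes, `*`) %*% t(R), 2, rf_center, `+`)
  })
  neuron_model(locs, responsivity_params(r1, r2, 2 * max_rate), max_rate)
}

#' Trial-to-trial variability model
#'
#' Gaussian spike-time jitter plus random spike deletion (thinning). First-
#' order tactile responses show little variability, so defaults are small.
#'
#' @param sigma_ms Jitter SD, ms (>= 0).
#' @param deletion_p Per-spike deletion probability in `[0, 1)`.
#' @export
jitter_model <- function(sigma_ms = 2, deletion_p = 0.05) {
  if (sigma_ms < 0 || deletion_p < 0 || deletion_p > 1) {
    stop("invalid-argument: sigma >= 0 and deletion_p in [0, 1]", call. = FALSE)
  }
  structure(list(sigma_ms = sigma_ms, deletion_p = deletion_p),
            class = "jitter_model")
}

jitter_train <- function(train, jm) {
  t <- train$times
  if (length(t)) {
    if (jm$deletion_p > 0) t <- t[runif(length(t)) >= jm$deletion_p]
    if (jm$sigma_ms > 0 && length(t)) {
      t <- t + rnorm(length(t), 0, jm$sigma_ms)
      t <- round(t / train$dt) * train$dt
      t <- sort(unique(pmin(pmax(t, 0), train$duration)))
    }
  }
  spike_train(t, train$duration, train$dt)
}

#' Synthetic multi-trial recordings from a ground-truth neuron
#'
#' Simulates the ground-truth neuron for every orientation of the protocol
#' and derives jittered trials; the receptive-field boundary comes from a
#' moving-dot scan of the ground truth. 7 trials at the 30 deg test
#' orientation mirror the protocol used for the inter-trial reliability
#' statistic.
#'
#' @param neuron Ground-truth [neuron_model()].
#' @param patch Skin patch (default 12 x 12 mm extents).
#' @param n_trials Trials per orientation (test orientation gets
#'   `max(n_trials, 7)`).
#' @param jitter A [jitter_model()].
#' @param seed RNG seed.
#' @param smoothing_sigma Rate-curve width for the dataset, ms.
#' @return A [fit_dataset()] with the extra fields `truth` (the generator
#'   neuron) and `seed`.
#' @export
synth_recordings <- function(neuron, patch = list(extent_x = 12, extent_y = 12),
                             n_trials = 7, jitter = jitter_model(),
                             seed = 1L, smoothing_sigma = 5) {
  if (n_trials < 1) stop("invalid-argument: n_trials >= 1", call. = FALSE)
  oris <- c(TRAIN_ORIENTATIONS, CROSSVAL_ORIENTATION, TEST_ORIENTATION)
  trains <- with_seed(seed, {
    out <- list()
    for (o in oris) {
      sw <- sweep_interval(edge_stimulus(o), patch)
      clean <- simulate_neuron(neuron, sw$stimulus, sw$clock)
      nt <- if (o == TEST_ORIENTATION) max(n_trials, 7) else n_trials
      out[[orient_key(o)]] <- lapply(seq_len(nt), function(i) {
        jitter_train(clean, jitter)
      })
    }
    out
  })
  boundary <- rf_boundary_from_dot_scan(neuron, patch)
  ds <- fit_dataset(trains, boundary, patch, smoothing_sigma = smoothing_sigma)
  ds$truth <- neuron
  ds$seed <- as.integer(seed)
  ds
}

#' Inter-trial reliability of the test-orientation response
#'
#' Mean pairwise R^2 between the single-trial rate curves at 30 deg (the
#' statistic the recordings report over 7 trials).
#'
#' @param dataset A [synth_recordings()] / [fit_dataset()] result.
#' @export
intertrial_reliability <- function(dataset) {
  trains <- dataset$trains[[orient_key(TEST_ORIENTATION)]]
  curves <- lapply(trains, rate_curve, smoothing_sigma = dataset$smoothing_sigma)
  n <- length(curves)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      vals <- c(vals, tryCatch(
        as.numeric(r2_score(curves[[i]]$rate, curves[[j]]$rate)),
        error = function(e) NA_real_))
    }
  }
  mean(vals, na.rm = TRUE)
}

#' Tiny perfectly separable classification fixture
#'
#' A miniature "population" of `n_neurons` spike sources where neuron 1 fires
#' a burst only on `+theta` trials and neuron 2 only on `-theta` trials; the
#' rest fire label-independent random background spikes. The sparse
#' ground-truth weights (+1 on the informative neuron of each unit) separate
#' the classes perfectly.
#'
#' @param n_neurons Population size (<= 10).
#' @param n_trials Trials per orientation.
#' @param theta Orientation label magnitude, degrees.
#' @param duration_ms Trial duration.
#' @param channels PSP channels for the features.
#' @param seed RNG seed.
#' @return List with `features`, `labels`, `truth_weights` (features x 2
#'   matrix), `key_neurons`, and `theta`.
#' @export
make_separable_fixture <- function(n_neurons = 6, n_trials = 12, theta = 20,
                                   duration_ms = 200, channels = "ampa",
                                   seed = 1L) {
  stopifnot(n_neurons >= 3, n_neurons <= 10)
  labels <- rep(c(-theta, theta), each = n_trials)
  features <- with_seed(seed, lapply(labels, function(lab) {
    rasters <- lapply(seq_len(n_neurons), function(n) {
      t <- if (n == 1) {
        if (lab > 0) seq(50, 90, by = 10) else numeric(0)
      } else if (n == 2) {
        if (lab < 0) seq(50, 90, by = 10) else numeric(0)
      } else {
        sort(unique(round(runif(3, 0, duration_ms))))
      }
      spike_train(t, duration_ms)
    })
    trial_features(rasters, channels = channels, pad_ms = 20)
  }))
  nch <- length(channels)
  truth <- matrix(0, n_neurons * nch, 2)
  truth[2, 1] <- 1   # unit tuned to -theta listens to neuron 2
  truth[1, 2] <- 1   # unit tuned to +theta listens to neuron 1
  list(features = features, labels = labels, truth_weights = truth,
       key_neurons = c(1L, 2L), theta = theta)
}
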