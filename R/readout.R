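# Synaptic readout of the population: postsynaptic-potential (PSP) kernels,
# convolution of population spike trains into per-neuron PSP channels, the
# two-unit classifier (decision = unit with the larger maximum of its summed
# PSP trace), and GA training of the signed synaptic weights.

PSP_TAU_DECAY <- c(ampa = 3, nmda = 65)  # ms; tau_rise = 0.5 ms for both

#' Difference-of-exponentials PSP kernel
#'
#' `k(t) = exp(-t/tau_decay) - exp(-t/tau_rise)` for `t >= 0`, sampled on the
#' dt grid and truncated at `duration` (default `8 * tau_decay`; the tail
#' beyond is < exp(-8)). With `normalization = "peak1"` (default) the kernel
#' is rescaled to unit peak so that fast (AMPA-like, tau_decay = 3 ms) and
#' slow (NMDA-like, 65 ms) channels carry comparable weight scales.
#'
#' @param tau_rise,tau_decay Time constants, ms (`tau_decay > tau_rise > 0`).
#' @param dt Grid step, ms.
#' @param duration Kernel support, ms (>= `5 * tau_decay` recommended).
#' @param normalization `"peak1"` or `"raw"`.
#' @return A `psp_kernel` object with `times` and `values`.
#' @export
psp_kernel <- function(tau_rise = 0.5, tau_decay = 3, dt = 1,
                       duration = 8 * tau_decay, normalization = "peak1") {
  if (tau_decay <= tau_rise || tau_rise <= 0) {
    stop("invalid-argument: need tau_decay > tau_rise > 0", call. = FALSE)
  }
  normalization <- match.arg(normalization, c("peak1", "raw"))
  t <- seq(0, duration, by = dt)
  v <- exp(-t / tau_decay) - exp(-t / tau_rise)
  if (normalization == "peak1") v <- v / max(v)
  structure(list(times = t, values = v, tau_rise = tau_rise,
                 tau_decay = tau_decay, normalization = normalization,
                 dt = dt),
            class = "psp_kernel")
}

#' Convolve a spike train with a PSP kernel
#'
#' Linear superposition of kernel copies at the spike times, truncated at the
#' trace end.
#'
#' @param train A [spike_train()].
#' @param kernel A [psp_kernel()] on the same dt grid.
#' @param length_out Trace length in ticks; defaults to the train's clock
#'   length.
#' @return Numeric PSP trace.
#' @export
convolve_psp <- function(train, kernel, length_out = NULL) {
  dt <- train$dt
  if (abs(kernel$dt - dt) > 1e-12) {
    stop("invalid-argument: kernel and train must share the dt grid", call. = FALSE)
  }
  if (is.null(length_out)) length_out <- length(seq(0, train$duration, by = dt))
  trace <- numeric(length_out)
  kv <- kernel$values
  kl <- length(kv)
  for (ts in train$times) {
    i0 <- round(ts / dt) + 1L
    if (i0 > length_out) next
    i1 <- min(length_out, i0 + kl - 1L)
    trace[i0:i1] <- trace[i0:i1] + kv[seq_len(i1 - i0 + 1L)]
  }
  trace
}

#' PSP feature matrix for one trial
#'
#' Column layout: channel-major blocks of neurons, i.e. column
#' `(c - 1) * n_neurons + n` holds neuron `n`'s trace through channel `c`.
#'
#' @param rasters List of [spike_train()]s (one per population neuron).
#' @param channels Character subset of `c("ampa", "nmda")`.
#' @param pad_ms Silent tail appended after the clock so PSPs can evolve
#'   beyond short presentation windows.
#' @param normalization Kernel normalization.
#' @return Matrix, (ticks + pad) x (n_neurons * n_channels), with attributes
#'   `channels` and `n_neurons`.
#' @export
trial_features <- function(rasters, channels = "ampa", pad_ms = 50,
                           normalization = "peak1") {
  channels <- match.arg(channels, names(PSP_TAU_DECAY), several.ok = TRUE)
  dt <- rasters[[1]]$dt
  nt <- length(seq(0, rasters[[1]]$duration, by = dt)) + round(pad_ms / dt)
  nn <- length(rasters)
  out <- matrix(0, nt, nn * length(channels))
  for (ci in seq_along(channels)) {
    k <- psp_kernel(tau_decay = PSP_TAU_DECAY[[channels[ci]]], dt = dt,
                    normalization = normalization)
    for (n in seq_len(nn)) {
      if (length(rasters[[n]]$times)) {
        out[, (ci - 1L) * nn + n] <- convolve_psp(rasters[[n]], k, nt)
      }
    }
  }
  structure(out, channels = channels, n_neurons = nn)
}

#' Response of one classifier unit to a trial
#'
#' The maximum over time of the weighted sum of the trial's PSP traces.
#'
#' @param features A [trial_features()] matrix.
#' @param weights Weight vector, one entry per feature column, each in
#'   `[-1, 1]`.
#' @return Scalar response (may be negative).
#' @export
unit_response <- function(features, weights) {
  if (ncol(features) != length(weights)) {
    stop("invalid-argument: weight/feature dimension mismatch", call. = FALSE)
  }
  max(features %*% weights)
}

#' Two-unit PSP classifier
#' @keywords internal
classifier <- function(weights, channels, theta, n_neurons, config = NULL,
                       train_success = NA_real_) {
  structure(list(weights = weights,  # matrix: features x 2 (units -theta, +theta)
                 channels = channels, theta = theta, n_neurons = n_neurons,
                 config = config, train_success = train_success),
            class = "edge_classifier")
}

#' Classify one trial
#'
#' The label of the unit with the larger response; an exact tie is resolved
#' uniformly at random (and reported via a message).
#'
#' @param features A [trial_features()] matrix.
#' @param clf An `edge_classifier` from [train_classifier()].
#' @return `-theta` or `+theta` (numeric label).
#' @export
classify_trial <- function(features, clf) {
  r_neg <- unit_response(features, clf$weights[, 1])
  r_pos <- unit_response(features, clf$weights[, 2])
  if (r_neg == r_pos) {
    message("classify_trial: exact tie, choosing at random")
    return(sample(c(-clf$theta, clf$theta), 1))
  }
  if (r_pos > r_neg) clf$theta else -clf$theta
}

# Stack per-trial feature matrices for the C++ fitness evaluator.
stack_features <- function(features_list) {
  rows <- vapply(features_list, nrow, integer(1))
  F <- do.call(rbind, features_list)
  group <- rep(seq_along(features_list), rows)
  list(F = F, group = group)
}

# success + bounded margin bonus; the bonus (< 1e-3) can never outweigh a
# single-trial success difference but gives the GA a gradient at 100%
eval_weight_population <- function(stacked, is_pos, W) {
  M <- nrow(W) / 2
  res <- classifier_eval_cpp(stacked$F, stacked$group,
                             W[(M + 1):(2 * M), , drop = FALSE],
                             W[1:M, , drop = FALSE], is_pos)
  res$success + 1e-3 * res$margin / (1 + abs(res$margin))
}

#' Train an edge-orientation classifier with the genetic algorithm
#'
#' Optimises one signed weight in `[-1, 1]` per (neuron, channel, unit) to
#' maximise the training discrimination success (ties scored 1/2), with a
#' small classification-margin bonus to break fitness ties.
#'
#' @param features_list List of [trial_features()] matrices (training trials).
#' @param labels Numeric vector of trial labels, `-theta`/`+theta`; must be
#'   balanced.
#' @param theta Orientation magnitude, degrees.
#' @param config A [ga_config()]; the published protocol uses a population of
#'   100, mutation and crossover probability 0.1, and 200 iterations.
#' @param channels Channels present in the features to use (default: all).
#' @return An `edge_classifier`.
#' @export
train_classifier <- function(features_list, labels, theta,
                             config = ga_config(iterations = 200),
                             channels = NULL) {
  is_pos <- labels > 0
  if (sum(is_pos) != sum(!is_pos)) {
    stop("invalid-argument: training trials must be balanced", call. = FALSE)
  }
  feat_channels <- attr(features_list[[1]], "channels")
  nn <- attr(features_list[[1]], "n_neurons")
  if (is.null(channels)) channels <- feat_channels
  sel <- which(feat_channels %in% channels)
  cols <- as.vector(vapply(sel, function(ci) (ci - 1L) * nn + seq_len(nn),
                           integer(nn)))
  stacked <- stack_features(lapply(features_list, function(f) f[, cols, drop = FALSE]))
  M <- length(cols)
  npar <- 2L * M   # unit -theta block then unit +theta block
  init_fn <- function() runif(npar, -1, 1)
  mutate_fn <- function(g) {
    hit <- runif(npar) < 0.2
    g[hit] <- pmin(1, pmax(-1, g[hit] + rnorm(sum(hit), 0, 0.25)))
    g
  }
  crossover_fn <- function(a, b) {
    take <- runif(npar) < 0.5
    a[take] <- b[take]
    a
  }
  objective <- function(pop) {
    eval_weight_population(stacked, is_pos, do.call(cbind, pop))
  }
  res <- ga_optimize(objective, init_fn, mutate_fn, crossover_fn, config,
                     vectorized = TRUE)
  W <- matrix(0, nn * length(feat_channels), 2)
  W[cols, 1] <- res$best[1:M]
  W[cols, 2] <- res$best[(M + 1):npar]
  succ <- classifier_eval_cpp(stacked$F, stacked$group,
                              matrix(res$best[(M + 1):npar], ncol = 1),
                              matrix(res$best[1:M], ncol = 1),
                              is_pos)$success[1]
  classifier(W, channels, theta, nn, config = config, train_success = succ)
}

#' Discrimination success of a classifier on a trial set
#'
#' Ties count 1/2; no randomisation, so the value is deterministic.
#'
#' @param clf An `edge_classifier`.
#' @param features_list List of [trial_features()] matrices.
#' @param labels Trial labels.
#' @return Success rate in `[0, 1]`.
#' @export
classifier_success <- function(clf, features_list, labels) {
  stacked <- stack_features(features_list)
  res <- classifier_eval_cpp(stacked$F, stacked$group,
                             clf$weights[, 2, drop = FALSE],
                             clf$weights[, 1, drop = FALSE],
                             labels > 0)
  res$success[1]
}
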