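# Orchestration of the discrimination experiments: noisy trial generation for
# +/- theta edge pairs, train/test splits, repeated classifier training, and
# sweep summaries (AMPA vs NMDA differences).

#' Configuration of one discrimination experiment
#'
#' Published defaults: 100 trials per orientation, 50 of each picked at
#' random for training, 20 repeats (fresh split + fresh GA seed each, same
#' trials), theta in {1, 3, 5, 10, 15, 20} deg, noise in {0, 1, 5, 10} %,
#' presentation window in {5, 10, 20, 50, Inf} ms.
#'
#' @param theta_deg Orientation magnitude (deg); trials present -theta vs
#'   +theta.
#' @param noise_pct Additive stimulus noise level (percent of amplitude).
#' @param window_ms Presentation window, ms (`Inf` = unlimited sweep).
#' @param channels PSP channels to simulate features for.
#' @param rf_type `"complex"` (fitted multi-MR neurons) or `"simple"`
#'   (single-MR neurons); informational tag used by sweep helpers.
#' @param n_trials_per_orientation,n_train Trial counts (per orientation).
#' @param n_repeats Number of classifier repeats.
#' @param ga GA settings for classifier training ([ga_config()]); its seed is
#'   re-derived per repeat.
#' @param pad_ms PSP tail appended after the presentation window.
#' @param seed Master seed for trial noise and splits.
#' @export
experiment_config <- function(theta_deg, noise_pct = 0, window_ms = Inf,
                              channels = "ampa", rf_type = "complex",
                              n_trials_per_orientation = 100, n_train = 50,
                              n_repeats = 20,
                              ga = ga_config(iterations = 200), pad_ms = 50,
                              seed = 1L) {
  if (n_train >= n_trials_per_orientation) {
    stop("invalid-argument: n_train must be < n_trials_per_orientation",
         call. = FALSE)
  }
  if (n_repeats < 1) stop("invalid-argument: repeats >= 1", call. = FALSE)
  structure(list(theta_deg = theta_deg, noise_pct = noise_pct,
                 window_ms = window_ms, channels = channels,
                 rf_type = match.arg(rf_type, c("complex", "simple")),
                 n_trials_per_orientation = n_trials_per_orientation,
                 n_train = n_train, n_repeats = n_repeats, ga = ga,
                 pad_ms = pad_ms, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Simulate the noisy trial set for a +/- theta discrimination task
#'
#' For each orientation, `n_trials_per_orientation` trials are simulated;
#' every trial draws an independent noise field (same level, fresh seed).
#' At noise 0 all same-label trials are identical, so one simulation per
#' orientation is reused.
#'
#' @param population A [tile_population()] layout.
#' @param config An [experiment_config()].
#' @return A `trial_set`: `features` (list of [trial_features()] matrices),
#'   `labels`, and the config.
#' @export
generate_trials <- function(population, config) {
  patch <- population$patch
  oris <- c(-config$theta_deg, config$theta_deg)
  n_tr <- config$n_trials_per_orientation
  features <- vector("list", 2L * n_tr)
  labels <- numeric(2L * n_tr)
  k <- 0L
  for (oi in seq_along(oris)) {
    sw <- sweep_interval(edge_stimulus(oris[oi], window_ms = config$window_ms),
                         patch)
    shared <- NULL
    for (tr in seq_len(n_tr)) {
      k <- k + 1L
      labels[k] <- oris[oi]
      if (config$noise_pct == 0) {
        if (is.null(shared)) {
          rasters <- simulate_population(population, sw$stimulus, sw$clock)
          shared <- trial_features(rasters, channels = config$channels,
                                   pad_ms = config$pad_ms)
        }
        features[[k]] <- shared
      } else {
        nf <- make_noise_field(config$noise_pct, patch,
                               seed = derive_seed(config$seed, "noise",
                                                  oi * 100000L + tr))
        rasters <- simulate_population(population, sw$stimulus, sw$clock,
                                       noise = nf)
        features[[k]] <- trial_features(rasters, channels = config$channels,
                                        pad_ms = config$pad_ms)
      }
    }
  }
  structure(list(features = features, labels = labels, config = config),
            class = "trial_set")
}

#' Run a discrimination experiment
#'
#' For each repeat, `n_train` trials per orientation are drawn at random for
#' training a fresh classifier (fresh GA seed), the held-out trials form the
#' test set, and the test success rate is recorded. The summary reports the
#' mean and a percentile bootstrap 95% confidence interval over repeats.
#'
#' @param population A population layout (ignored when `trials` is given).
#' @param config An [experiment_config()].
#' @param trials Optional precomputed [generate_trials()] result.
#' @param channels Channel subset used by the classifier (default: the
#'   config's channels).
#' @return A `discrimination_result` with per-repeat train/test success,
#'   means, CI, and the trained classifiers.
#' @export
run_discrimination_experiment <- function(population = NULL, config,
                                          trials = NULL, channels = NULL) {
  if (is.null(trials)) trials <- generate_trials(population, config)
  if (is.null(channels)) channels <- config$channels
  n_tr <- config$n_trials_per_orientation
  idx_neg <- which(trials$labels < 0)
  idx_pos <- which(trials$labels > 0)
  test_rates <- train_rates <- numeric(config$n_repeats)
  classifiers <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    split <- with_seed(derive_seed(config$seed, "split", r), {
      list(neg = sample(idx_neg, config$n_train),
           pos = sample(idx_pos, config$n_train))
    })
    tr_idx <- c(split$neg, split$pos)
    te_idx <- setdiff(seq_along(trials$labels), tr_idx)
    ga <- config$ga
    ga$seed <- derive_seed(config$seed, "ga", r)
    clf <- train_classifier(trials$features[tr_idx], trials$labels[tr_idx],
                            theta = config$theta_deg, config = ga,
                            channels = channels)
    classifiers[[r]] <- clf
    train_rates[r] <- clf$train_success
    test_rates[r] <- classifier_success(clf, trials$features[te_idx],
                                        trials$labels[te_idx])
  }
  ci <- bootstrap_ci_mean(test_rates,
                          seed = derive_seed(config$seed, "ci"))
  structure(list(config = config, channels = channels,
                 train_success = train_rates, test_success = test_rates,
                 mean_test_success = mean(test_rates), ci95 = ci,
                 classifiers = classifiers),
            class = "discrimination_result")
}

# percentile bootstrap CI of a mean
bootstrap_ci_mean <- function(x, n_boot = 1000, alpha = 0.05, seed = 1L) {
  if (length(x) < 2) return(c(lo = min(x), hi = max(x)))
  bm <- with_seed(seed, {
    idx <- matrix(sample.int(length(x), n_boot * length(x), replace = TRUE),
                  n_boot)
    rowMeans(matrix(x[idx], n_boot))
  })
  q <- quantile(bm, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Tabulate a sweep of discrimination results
#'
#' One row per result; when both an AMPA and an NMDA result exist for the
#' same (theta, noise, window) cell, the AMPA - NMDA test-success difference
#' is attached.
#'
#' @param results List of `discrimination_result`s.
#' @return A data.frame with columns theta_deg, noise_pct, window_ms,
#'   channels, rf_type, mean_test_success, ci_lo, ci_hi, and (where matched)
#'   `ampa_minus_nmda`.
#' @export
performance_summary <- function(results) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(theta_deg = r$config$theta_deg,
               noise_pct = r$config$noise_pct,
               window_ms = r$config$window_ms,
               channels = paste(r$channels, collapse = "+"),
               rf_type = r$config$rf_type,
               mean_test_success = r$mean_test_success,
               ci_lo = r$ci95[["lo"]], ci_hi = r$ci95[["hi"]])
  }))
  key <- interaction(df$theta_deg, df$noise_pct, df$window_ms, df$rf_type)
  df$ampa_minus_nmda <- NA_real_
  for (k in unique(key)) {
    rows <- which(key == k)
    a <- rows[df$channels[rows] == "ampa"]
    n <- rows[df$channels[rows] == "nmda"]
    if (length(a) == 1 && length(n) == 1) {
      df$ampa_minus_nmda[c(a, n)] <-
        df$mean_test_success[a] - df$mean_test_success[n]
    }
  }
  df
}
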