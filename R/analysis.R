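# Post-hoc analysis of trained classifier ensembles: key-synapse
# identification by bootstrap with Bonferroni correction, classifier-unit
# receptive-field maps, and weight correlations between oppositely tuned
# units.

#' Collect one unit's weights across an ensemble of trained classifiers
#'
#' @param classifiers List of `edge_classifier`s (typically the 20 repeats of
#'   one [run_discrimination_experiment()]).
#' @param unit 1 = the unit tuned to `-theta`, 2 = `+theta`.
#' @return A `weight_ensemble`: matrix, classifiers x synapses.
#' @export
weight_ensemble <- function(classifiers, unit = 2) {
  W <- t(vapply(classifiers, function(cl) cl$weights[, unit],
                numeric(nrow(classifiers[[1]]$weights))))
  structure(W, class = c("weight_ensemble", class(W)),
            unit = unit, n_neurons = classifiers[[1]]$n_neurons,
            channels = classifiers[[1]]$channels)
}

#' Key synapses by bootstrap CI with Bonferroni correction
#'
#' For each synapse, a percentile bootstrap CI of the mean weight across the
#' ensemble is computed at level `1 - alpha / N` (N = number of synapses;
#' equivalent to multiplying p-values by N). Whole classifiers (rows) are
#' resampled, preserving cross-synapse correlation. A synapse is *key* when
#' its corrected CI excludes 0.
#'
#' @param ensemble A [weight_ensemble()] (or plain matrix, rows =
#'   classifiers).
#' @param n_boot Bootstrap resamples (>= 1000).
#' @param alpha Family-wise error level (default 0.05).
#' @param seed RNG seed.
#' @param method `"studentized"` (default) or `"percentile"`. With only ~20
#'   classifiers the percentile interval's realized tail error at the
#'   Bonferroni-corrected level far exceeds the nominal one (its tails reach
#'   only ~3.8 standard errors where the corrected level demands ~4.7), so
#'   the studentized (bootstrap-t) interval, whose tails are second-order
#'   accurate, is the default.
#' @return A data.frame (synapse, mean, lo, hi, key) with attribute
#'   `n_key`.
#' @export
bootstrap_key_synapses <- function(ensemble, n_boot = 10000, alpha = 0.05,
                                   seed = 1L, method = "studentized") {
  W <- unclass(ensemble)
  if (nrow(W) < 2) stop("invalid-argument: need >= 2 classifiers", call. = FALSE)
  if (n_boot < 1000) stop("invalid-argument: n_boot must be >= 1000", call. = FALSE)
  method <- match.arg(method, c("studentized", "percentile"))
  n <- nrow(W)
  N <- ncol(W)
  # resample whole classifiers (rows) via a count matrix: rows = resamples
  counts <- with_seed(seed, {
    idx <- sample.int(n, n_boot * n, replace = TRUE)
    m <- matrix(0L, n_boot, n)
    for (r in seq_len(n_boot)) {
      m[r, ] <- tabulate(idx[((r - 1) * n + 1):(r * n)], nbins = n)
    }
    m
  })
  bm <- (counts %*% W) / n
  mu <- colMeans(W)
  lvl <- alpha / N                       # Bonferroni: widen to 1 - alpha/N
  if (method == "percentile") {
    lo <- apply(bm, 2, quantile, probs = lvl / 2, names = FALSE)
    hi <- apply(bm, 2, quantile, probs = 1 - lvl / 2, names = FALSE)
  } else {
    e2 <- (counts %*% W^2) / n
    var_star <- pmax(e2 - bm^2, 0) * n / (n - 1)
    se_star <- sqrt(var_star / n)
    se <- sqrt(apply(W, 2, stats::var) / n)
    tstar <- (bm - matrix(mu, n_boot, N, byrow = TRUE)) / se_star
    tstar[se_star == 0] <- 0
    q_lo <- apply(tstar, 2, quantile, probs = lvl / 2, names = FALSE)
    q_hi <- apply(tstar, 2, quantile, probs = 1 - lvl / 2, names = FALSE)
    lo <- mu - q_hi * se
    hi <- mu - q_lo * se
  }
  key <- lo > 0 | hi < 0
  out <- data.frame(synapse = seq_len(N), mean = mu, lo = lo, hi = hi,
                    key = key)
  attr(out, "n_key") <- sum(key)
  out
}

#' Receptive-field map of a classifier unit
#'
#' Each population neuron's synaptic weight is deposited at its
#' mechanoreceptor locations (weight / n_MR per MR) on a raster over the
#' patch, Gaussian-smoothed, and averaged over the classifier ensemble.
#' Weights of multiple channels for one neuron are summed.
#'
#' @param ensemble A [weight_ensemble()] or a single weight vector.
#' @param population The [tile_population()] layout the classifiers read
#'   from.
#' @param smoothing_mm Gaussian smoothing width (default 0.3 mm; display
#'   only).
#' @param res Raster resolution, mm.
#' @return An `rf_map`: list with `x`, `y` grid vectors and the `z` matrix
#'   (x index by y index).
#' @export
unit_rf_map <- function(ensemble, population, smoothing_mm = 0.3, res = 0.1) {
  W <- if (is.matrix(ensemble)) unclass(ensemble) else matrix(ensemble, nrow = 1)
  nn <- length(population$instances)
  if (ncol(W) %% nn != 0) {
    stop("invalid-argument: ensemble does not match the population layout",
         call. = FALSE)
  }
  nch <- ncol(W) %/% nn
  wbar <- colMeans(W)
  per_neuron <- rowSums(matrix(wbar, nn, nch))
  ext <- c(population$patch$extent_x, population$patch$extent_y)
  xs <- seq(0, ext[1], by = res)
  ys <- seq(0, ext[2], by = res)
  z <- matrix(0, length(xs), length(ys))
  for (i in seq_len(nn)) {
    locs <- population$instances[[i]]$model$mr_locations
    w <- per_neuron[i] / nrow(locs)
    if (w == 0) next
    ix <- round(locs[, 1] / res) + 1L
    iy <- round(locs[, 2] / res) + 1L
    ok <- ix >= 1 & ix <= length(xs) & iy >= 1 & iy <= length(ys)
    for (k in which(ok)) z[ix[k], iy[k]] <- z[ix[k], iy[k]] + w
  }
  if (smoothing_mm > 0) {
    half <- ceiling(4 * smoothing_mm / res)
    k1 <- dnorm(seq(-half, half) * res, sd = smoothing_mm)
    k1 <- k1 / sum(k1)
    z <- apply(z, 2, smooth_1d, k1 = k1)
    z <- t(apply(z, 1, smooth_1d, k1 = k1))
  }
  structure(list(x = xs, y = ys, z = z, smoothing_mm = smoothing_mm),
            class = "rf_map")
}

smooth_1d <- function(v, k1) {
  half <- (length(k1) - 1L) %/% 2L
  out <- convolve(v, rev(k1), type = "open")
  out[(half + 1):(half + length(v))]
}

#' Pearson correlation of two units' weights over their key excitatory
#' synapses
#'
#' The restriction set is the union of the two units' key synapses with
#' positive mean weight.
#'
#' @param weights_a,weights_b Weight matrices/ensembles (classifiers x
#'   synapses) for the two units.
#' @param key_a,key_b Optional precomputed [bootstrap_key_synapses()]
#'   reports; computed with defaults when missing.
#' @param seed Seed for the bootstrap when reports are computed here.
#' @return List with `r`, `p`, and the restriction `synapses`.
#' @export
weight_correlation <- function(weights_a, weights_b, key_a = NULL,
                               key_b = NULL, seed = 1L) {
  Wa <- unclass(weights_a)
  Wb <- unclass(weights_b)
  if (is.null(key_a)) key_a <- bootstrap_key_synapses(Wa, seed = seed)
  if (is.null(key_b)) key_b <- bootstrap_key_synapses(Wb, seed = seed + 1L)
  sel <- sort(union(which(key_a$key & key_a$mean > 0),
                    which(key_b$key & key_b$mean > 0)))
  if (length(sel) < 3) {
    stop("invalid-argument: need >= 3 key excitatory synapses", call. = FALSE)
  }
  a <- colMeans(Wa)[sel]
  b <- colMeans(Wb)[sel]
  if (sd(a) < 1e-12 || sd(b) < 1e-12) {
    stop("undefined-correlation: constant weight vector", call. = FALSE)
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, synapses = sel)
}
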