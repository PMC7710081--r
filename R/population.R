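# The fingertip population: randomly-rotated variants of a set of base model
# neurons tiled over a 12 x 12 mm skin patch at 140 neurons/cm^2. The
# published count (330) exceeds patch area x density (~202), implying neurons
# centred outside the patch but innervating it are included; centres are
# therefore sampled over the patch dilated by the maximal receptive-field
# radius, and instances are kept when at least one mechanoreceptor falls
# inside the patch. `target_count` forces an exact population size.

#' Rigidly rotate a model neuron
#'
#' @param model A [neuron_model()].
#' @param angle_deg Rotation angle, degrees counterclockwise.
#' @param pivot 2-D pivot point; defaults to the MR centroid.
#' @return The rotated [neuron_model()] (responsivity and rates unchanged).
#' @export
rotate_neuron <- function(model, angle_deg, pivot = NULL) {
  if (is.null(pivot)) pivot <- colMeans(model$mr_locations)
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  centred <- sweep(model$mr_locations, 2, pivot)
  model$mr_locations <- sweep(centred %*% t(R), 2, pivot, `+`)
  colnames(model$mr_locations) <- c("x", "y")
  model
}

neuron_footprint_radius <- function(model) {
  centred <- sweep(model$mr_locations, 2, colMeans(model$mr_locations))
  max(sqrt(rowSums(centred^2))) + model$responsivity$r1 + model$responsivity$r2
}

#' Tile a skin patch with randomly rotated neuron variants
#'
#' Each instance gets a uniformly random centre in the dilated patch, a
#' uniformly random base model (with replacement) and a uniformly random
#' rotation in `[0, 360)`; its base model is rotated about its MR centroid and
#' translated so the centroid sits at the centre.
#'
#' @param base_models List of [neuron_model()]s (the study uses 15).
#' @param patch Skin patch (`mr_grid` or extents list).
#' @param density Target innervation density, neurons/cm^2 (default 140).
#' @param seed RNG seed.
#' @param target_count If non-`NULL`, draw candidates until exactly this many
#'   retained instances exist (e.g. 330 for the published population).
#' @return A `population_layout` with one `instances` entry per retained
#'   neuron (`base_id`, `rotation_deg`, `center`, realized `model`).
#' @export
tile_population <- function(base_models, patch, density = 140, seed = 1L,
                            target_count = NULL) {
  if (density <= 0) stop("invalid-argument: density must be > 0", call. = FALSE)
  ext <- patch_extents(patch)
  border <- max(vapply(base_models, neuron_footprint_radius, numeric(1)))
  lo <- -border
  hix <- ext[1] + border
  hiy <- ext[2] + border
  area_cm2 <- (hix - lo) * (hiy - lo) / 100
  draw_batch <- function(n) {
    centers <- cbind(runif(n, lo, hix), runif(n, lo, hiy))
    base_id <- sample.int(length(base_models), n, replace = TRUE)
    rot <- runif(n, 0, 360)
    out <- vector("list", n)
    kept <- 0L
    for (i in seq_len(n)) {
      m <- rotate_neuron(base_models[[base_id[i]]], rot[i])
      ctr <- colMeans(m$mr_locations)
      m$mr_locations <- sweep(m$mr_locations, 2, centers[i, ] - ctr, `+`)
      inside <- m$mr_locations[, 1] >= 0 & m$mr_locations[, 1] <= ext[1] &
                m$mr_locations[, 2] >= 0 & m$mr_locations[, 2] <= ext[2]
      if (any(inside)) {
        kept <- kept + 1L
        out[[kept]] <- list(base_id = base_id[i], rotation_deg = rot[i],
                            center = centers[i, ], model = m)
      }
    }
    out[seq_len(kept)]
  }
  instances <- with_seed(seed, {
    if (is.null(target_count)) {
      draw_batch(round(density * area_cm2))
    } else {
      acc <- list()
      guard <- 0L
      while (length(acc) < target_count) {
        acc <- c(acc, draw_batch(max(target_count - length(acc), 32L)))
        guard <- guard + 1L
        if (guard > 1000) stop("infeasible: cannot reach target_count", call. = FALSE)
      }
      acc[seq_len(target_count)]
    }
  })
  structure(list(instances = instances, patch = list(extent_x = ext[1],
                                                     extent_y = ext[2]),
                 density = density, border = border, seed = as.integer(seed)),
            class = "population_layout")
}

#' Simulate every population neuron's response to one stimulus
#'
#' @param population A [tile_population()] layout.
#' @param stimulus A positioned stimulus.
#' @param clock A [simulation_clock()].
#' @param noise Optional noise field.
#' @return List of [spike_train()]s, one per instance.
#' @export
simulate_population <- function(population, stimulus, clock, noise = NULL) {
  lapply(population$instances, function(inst) {
    simulate_neuron(inst$model, stimulus, clock, noise = noise)
  })
}
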