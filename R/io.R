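# Serialization: spike trains as CSV (trial_id, orientation_deg,
# spike_time_ms), models / populations / classifiers as schema-versioned
# JSON, and run manifests.

SCHEMA_NEURON <- "tactopop/neuron-model@1"
SCHEMA_POPULATION <- "tactopop/population@1"
SCHEMA_CLASSIFIER <- "tactopop/classifier@1"

#' Write spike trains to CSV
#'
#' One row per spike, columns `trial_id`, `orientation_deg`,
#' `spike_time_ms`; comma-separated, '.' decimal, UTF-8, header always
#' present (empty collections produce a header-only file).
#'
#' @param trains Named list (orientation key) of lists of [spike_train()]s.
#' @param path Output file.
#' @export
write_spike_trains <- function(trains, path) {
  rows <- list()
  for (k in names(trains)) {
    for (i in seq_along(trains[[k]])) {
      t <- trains[[k]][[i]]$times
      if (length(t)) {
        rows[[length(rows) + 1L]] <- data.frame(
          trial_id = i, orientation_deg = as.numeric(k), spike_time_ms = t)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial_id = integer(), orientation_deg = numeric(),
               spike_time_ms = numeric())
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read spike trains from CSV
#'
#' @param path CSV with columns `trial_id`, `orientation_deg`,
#'   `spike_time_ms`.
#' @param duration Train duration in ms; when `NULL`, the smallest grid
#'   multiple covering the last spike of each orientation is used.
#' @param dt Grid step, ms.
#' @return Named list (orientation) of lists of [spike_train()]s.
#' @export
read_spike_trains <- function(path, duration = NULL, dt = 1) {
  df <- read.csv(path)
  need <- c("trial_id", "orientation_deg", "spike_time_ms")
  if (!all(need %in% names(df))) {
    stop("format error: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  if (any(df$spike_time_ms < 0)) {
    stop("format error: negative spike time at row ",
         which(df$spike_time_ms < 0)[1], call. = FALSE)
  }
  out <- list()
  if (!nrow(df)) return(out)
  for (k in unique(df$orientation_deg)) {
    sub <- df[df$orientation_deg == k, ]
    dur <- if (is.null(duration)) ceiling(max(sub$spike_time_ms) / dt) * dt
           else duration
    out[[sprintf("%g", k)]] <- lapply(sort(unique(sub$trial_id)), function(id) {
      t <- sub$spike_time_ms[sub$trial_id == id]
      if (is.unsorted(t, strictly = TRUE)) {
        bad <- which(diff(t) <= 0)[1]
        row <- which(df$orientation_deg == k & df$trial_id == id)[bad + 1]
        stop("format error: unsorted or duplicate spike time at row ", row,
             call. = FALSE)
      }
      spike_train(t, dur, dt)
    })
  }
  out
}

neuron_to_list <- function(model) {
  list(schema = SCHEMA_NEURON,
       mr_locations = unname(as.matrix(model$mr_locations)),
       r1 = model$responsivity$r1, r2 = model$responsivity$r2,
       w_mr = model$responsivity$w_mr, max_rate = model$max_rate,
       scheme = model$scheme)
}

#' Serialize a model object to JSON
#'
#' Supports [neuron_model()], [tile_population()] layouts and
#' `edge_classifier`s; schema-versioned, lossless round-trip via
#' [read_model()].
#'
#' @param object The object.
#' @param path Output JSON file.
#' @export
write_model <- function(object, path) {
  x <- if (inherits(object, "neuron_model")) {
    neuron_to_list(object)
  } else if (inherits(object, "population_layout")) {
    list(schema = SCHEMA_POPULATION, patch = object$patch,
         density = object$density, border = object$border, seed = object$seed,
         instances = lapply(object$instances, function(inst) {
           list(base_id = inst$base_id, rotation_deg = inst$rotation_deg,
                center = inst$center, model = neuron_to_list(inst$model))
         }))
  } else if (inherits(object, "edge_classifier")) {
    list(schema = SCHEMA_CLASSIFIER, weights = unname(object$weights),
         channels = object$channels, theta = object$theta,
         n_neurons = object$n_neurons, train_success = object$train_success)
  } else {
    stop("invalid-argument: unsupported object class", call. = FALSE)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized model object
#' @param path JSON file written by [write_model()].
#' @return The reconstructed object.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$schema)) stop("version error: missing schema field", call. = FALSE)
  from_rows <- function(rows) {
    matrix(unlist(rows), ncol = 2, byrow = TRUE)
  }
  read_neuron <- function(nx) {
    scheme <- if (is.null(nx$scheme)) "reset" else nx$scheme
    neuron_model(from_rows(nx$mr_locations),
                 responsivity_params(nx$r1, nx$r2, nx$w_mr), nx$max_rate,
                 scheme)
  }
  if (x$schema == SCHEMA_NEURON) {
    read_neuron(x)
  } else if (x$schema == SCHEMA_POPULATION) {
    insts <- lapply(x$instances, function(inst) {
      list(base_id = inst$base_id, rotation_deg = inst$rotation_deg,
           center = as.numeric(unlist(inst$center)),
           model = read_neuron(inst$model))
    })
    structure(list(instances = insts, patch = lapply(x$patch, as.numeric),
                   density = x$density, border = x$border,
                   seed = as.integer(x$seed)),
              class = "population_layout")
  } else if (x$schema == SCHEMA_CLASSIFIER) {
    classifier(matrix(unlist(x$weights), ncol = 2, byrow = TRUE),
               unlist(x$channels), x$theta, x$n_neurons,
               train_success = x$train_success)
  } else {
    stop("version error: unknown schema ", x$schema, call. = FALSE)
  }
}

#' Write a run manifest
#'
#' Records seeds, configuration, package version, timestamp and input/output
#' paths so a run can be reproduced bit-exactly.
#'
#' @param path Output JSON path.
#' @param command Subcommand or label.
#' @param seed Master seed.
#' @param config Named list of configuration values.
#' @param inputs,outputs Character vectors of paths.
#' @export
write_manifest <- function(path, command, seed, config = list(),
                           inputs = character(), outputs = character()) {
  digest_src <- tempfile()
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE), digest_src)
  manifest <- list(
    command = command, seed = seed, config = config,
    config_digest = unname(tools::md5sum(digest_src)),
    package_version = as.character(utils::packageVersion("tactopop")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs, outputs = outputs)
  unlink(digest_src)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
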