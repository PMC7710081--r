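# Generic real-coded genetic algorithm. The published protocol fixes only the
# population size, the per-individual mutation and crossover probabilities and
# the iteration count; the remaining internals (tournament selection of size
# 3, elitism of 1) are package choices, configurable here and logged with
# every result.

#' Genetic-algorithm configuration
#'
#' Defaults follow the published optimisation protocol: a population of 100,
#' mutation probability 0.1, crossover probability 0.1; 500 iterations are
#' used for neuron fitting and 200 for classifier training.
#'
#' @param population_size Number of genomes (>= 2).
#' @param mutation_p,crossover_p Per-offspring probabilities in `[0, 1]`.
#' @param iterations Number of generations.
#' @param seed RNG seed; runs are reproducible from it.
#' @param tournament_k Tournament size for selection.
#' @param elitism Number of best-ever genomes carried over unchanged.
#' @export
ga_config <- function(population_size = 100, mutation_p = 0.1,
                      crossover_p = 0.1, iterations = 500, seed = 1L,
                      tournament_k = 3, elitism = 1) {
  if (population_size < 2) {
    stop("invalid-argument: population_size must be >= 2", call. = FALSE)
  }
  if (mutation_p < 0 || mutation_p > 1 || crossover_p < 0 || crossover_p > 1) {
    stop("invalid-argument: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (iterations < 1) stop("invalid-argument: iterations must be >= 1", call. = FALSE)
  structure(list(population_size = population_size, mutation_p = mutation_p,
                 crossover_p = crossover_p, iterations = iterations,
                 seed = as.integer(seed), tournament_k = tournament_k,
                 elitism = elitism),
            class = "ga_config")
}

#' Maximise an objective with a genetic algorithm
#'
#' @param objective Either `function(genome) -> fitness` or, with
#'   `vectorized = TRUE`, `function(list_of_genomes) -> numeric`.
#' @param init_fn `function() -> genome`; called `population_size` times.
#' @param mutate_fn `function(genome) -> genome`.
#' @param crossover_fn `function(genome_a, genome_b) -> genome`.
#' @param config A [ga_config()].
#' @param vectorized Whether `objective` evaluates a whole generation at once.
#' @return List with `best` genome, its `fitness`, the running-maximum
#'   `trace` (one entry per generation, non-decreasing) and the `config`.
#' @export
ga_optimize <- function(objective, init_fn, mutate_fn, crossover_fn, config,
                        vectorized = FALSE) {
  stopifnot(inherits(config, "ga_config"))
  with_seed(config$seed, {
    P <- config$population_size
    pop <- lapply(seq_len(P), function(i) init_fn())
    best <- NULL
    best_fit <- -Inf
    trace <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      fit <- if (vectorized) objective(pop) else
        vapply(pop, objective, numeric(1))
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best <- pop[[which.max(fit)]]
      }
      trace[it] <- best_fit
      if (it == config$iterations) break
      tournament <- function() {
        idx <- sample.int(P, min(config$tournament_k, P))
        idx[which.max(fit[idx])]
      }
      nxt <- vector("list", P)
      n_elite <- min(config$elitism, P)
      if (n_elite >= 1) nxt[[1]] <- best
      if (n_elite >= 2) {
        ord <- order(fit, decreasing = TRUE)
        for (e in 2:n_elite) nxt[[e]] <- pop[[ord[e - 1]]]
      }
      for (i in seq.int(n_elite + 1, P)) {
        child <- if (runif(1) < config$crossover_p) {
          crossover_fn(pop[[tournament()]], pop[[tournament()]])
        } else {
          pop[[tournament()]]
        }
        if (runif(1) < config$mutation_p) child <- mutate_fn(child)
        nxt[[i]] <- child
      }
      pop <- nxt
    }
    list(best = best, fitness = best_fit, trace = trace, config = config)
  })
}

# reflect a value into [lo, hi]
reflect <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}
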