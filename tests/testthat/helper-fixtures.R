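# Shared fixtures and independent oracles.

PATCH12 <- list(extent_x = 12, extent_y = 12)

# Independent brute-force tick-by-tick simulator built on the exported
# single-branch reference step; deliberately naive, used to cross-check the
# compiled simulation path.
brute_force_simulate <- function(neuron, stimulus, clock, noise = NULL) {
  p <- neuron$responsivity
  locs <- neuron$mr_locations
  nmr <- nrow(locs)
  A <- vapply(seq_len(nmr), function(j) {
    tryCatch(local_amplitude(locs[j, ], stimulus$amplitude, noise),
             error = function(e) stimulus$amplitude)
  }, numeric(1))
  drive_at <- function(j, t) {
    d <- if (inherits(stimulus, "edge_stimulus")) {
      edge_distance(locs[j, ], stimulus, t)
    } else {
      sqrt(sum((locs[j, ] - stimulus$center)^2))
    }
    c(I = mr_input(d, A[j], p),
      eff = effective_indentation(d, A[j], p))
  }
  if (neuron$scheme == "summation") {
    st <- branch_rest_state()
    spikes <- numeric(0)
    for (t in clock$times) {
      tot <- rowSums(vapply(seq_len(nmr), drive_at, numeric(2), t = t))
      res <- step_branch(st, tot[["I"]], clock$dt, neuron$max_rate,
                         tot[["eff"]])
      st <- res$state
      if (res$spike) spikes <- c(spikes, t)
    }
    return(spike_train(spikes, clock$t_end - clock$t_start, clock$dt))
  }
  states <- replicate(nmr, branch_rest_state(), simplify = FALSE)
  spikes <- numeric(0)
  for (t in clock$times) {
    pending <- logical(nmr)
    for (j in seq_len(nmr)) {
      dr <- drive_at(j, t)
      res <- step_branch(states[[j]], dr[["I"]], clock$dt, neuron$max_rate,
                         dr[["eff"]])
      states[[j]] <- res$state
      pending[j] <- res$spike
    }
    if (any(pending)) {
      spikes <- c(spikes, t)   # union: one neuron spike per tick
      if (neuron$scheme == "reset") {
        # the first spiking zone keeps its post-spike phase; the spike
        # retrogradely zeroes initiation at all other zones
        spiker <- which(pending)[1]
        for (j in setdiff(seq_len(nmr), spiker)) states[[j]]$phase <- 0
      }
    }
  }
  spike_train(spikes, clock$t_end - clock$t_start, clock$dt)
}

# Direct evaluation of the published input equation, independent of the
# package's sigmoid helper.
eq1_reference <- function(d, A, w, r1, r2) {
  ifelse(d > r1 + r2, 0, A * w * (1 - 1 / (1 + exp(-5 * (d / r1 - 1)))))
}

small_population <- function(n_base = 3, target = 60, seed = 5) {
  bases <- lapply(seq_len(n_base), function(i) {
    make_synthetic_neuron(n_mr = 10, rf_center = c(6, 6), seed = i)
  })
  tile_population(bases, PATCH12, seed = seed, target_count = target)
}
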