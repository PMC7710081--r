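# FA-1 model neuron: each innervated mechanoreceptor (MR) drives its own
# axonal branch / spike initiation zone; branch spike rate is linear in the
# MR drive (gain 1) with saturation at the neuron's maximal rate; a branch is
# eligible to fire only while its drive is increasing (spike adaptation) and
# the effective indentation exceeds a 0.01 mm threshold. Under the default
# "reset" scheme a spike at one zone retrogradely resets all other zones.

SPIKE_THRESHOLD_MM <- 0.01

scheme_code <- function(scheme) {
  match(match.arg(scheme, c("reset", "mixing", "summation")),
        c("reset", "mixing", "summation")) - 1L
}

#' Mechanoreceptor responsivity parameters
#'
#' Shared by all mechanoreceptors of a neuron. The drive of an MR at distance
#' `d` from the stimulus is
#' `A_local * w_mr * (1 - 1/(1 + exp(-5 (d/r1 - 1))))` for `d <= r1 + r2`,
#' and 0 beyond: `r1` is the sigmoidal half-height distance, `r1 + r2` the
#' extent of responsivity, and `w_mr` (Hz per mm of indentation, conventionally
#' twice the neuron's maximal rate) converts indentation to branch spike rate.
#'
#' @param r1,r2 Distance parameters, mm (> 0).
#' @param w_mr Input weight, Hz/mm (> 0).
#' @return A `responsivity_params` object.
#' @export
responsivity_params <- function(r1, r2, w_mr) {
  if (r1 <= 0 || r2 <= 0 || w_mr <= 0) {
    stop("invalid-argument: r1, r2 and w_mr must be positive", call. = FALSE)
  }
  structure(list(r1 = r1, r2 = r2, w_mr = w_mr),
            class = "responsivity_params")
}

sigmoid_term <- function(d, r1, r2) {
  out <- 1 - 1 / (1 + exp(-5 * (d / r1 - 1)))
  out[d > r1 + r2] <- 0
  out
}

#' Mechanoreceptor drive (Hz)
#'
#' @param d Distance of the stimulus from the MR, mm (>= 0); vectorised.
#' @param A_local Local stimulus amplitude at the MR, mm.
#' @param params A [responsivity_params()].
#' @return Drive in Hz.
#' @export
mr_input <- function(d, A_local, params) {
  if (any(d < 0)) stop("invalid-argument: distance must be >= 0", call. = FALSE)
  A_local * params$w_mr * sigmoid_term(d, params$r1, params$r2)
}

#' Effective indentation at a mechanoreceptor (mm)
#'
#' The drive without the input weight; a branch may spike only when this is
#' at least 0.01 mm.
#' @inheritParams mr_input
#' @export
effective_indentation <- function(d, A_local, params) {
  if (any(d < 0)) stop("invalid-argument: distance must be >= 0", call. = FALSE)
  A_local * sigmoid_term(d, params$r1, params$r2)
}

#' FA-1 model neuron
#'
#' @param mr_locations n x 2 matrix of innervated MR positions (mm).
#' @param responsivity A [responsivity_params()], shared by all MRs.
#' @param max_rate Saturation firing rate, Hz (> 0).
#' @param scheme Spiking scheme: `"reset"` (default; spikes at one zone reset
#'   all others), `"mixing"` (union of branch spike trains) or `"summation"`
#'   (one accumulator driven by the summed MR drive). The alternative schemes
#'   are diagnostic variants only.
#' @return A `neuron_model` object.
#' @export
neuron_model <- function(mr_locations, responsivity, max_rate,
                         scheme = "reset") {
  locs <- if (is.matrix(mr_locations)) mr_locations else matrix(mr_locations, ncol = 2)
  if (nrow(locs) < 1) stop("invalid-argument: need >= 1 mechanoreceptor", call. = FALSE)
  if (max_rate <= 0) stop("invalid-argument: max_rate must be > 0", call. = FALSE)
  scheme <- match.arg(scheme, c("reset", "mixing", "summation"))
  colnames(locs) <- c("x", "y")
  structure(list(mr_locations = locs, responsivity = responsivity,
                 max_rate = max_rate, scheme = scheme),
            class = "neuron_model")
}

#' Single-mechanoreceptor ("simple receptive field") neuron
#'
#' One MR whose responsivity profile decays smoothly to half-height at
#' `r1 = 1.45` mm with total reach `r1 + r2 = 1.5` mm — a symmetric
#' receptive field the size of an average recorded neuron — and `w_mr`
#' twice the maximal rate. (With the half-height distance at 0.05 mm
#' instead, the sigmoid would collapse to a ~0.1 mm point detector, which
#' is neither "the size of an average receptive field" nor a smooth
#' symmetric profile.)
#'
#' @param center MR location (mm).
#' @param max_rate Saturation rate, Hz.
#' @export
make_simple_rf_neuron <- function(center, max_rate) {
  neuron_model(matrix(as.numeric(center), ncol = 2),
               responsivity_params(1.45, 0.05, 2 * max_rate),
               max_rate)
}

#' Spike train on the simulation grid
#'
#' @param times Spike times in ms, strictly increasing, on the dt grid.
#' @param duration Train duration in ms.
#' @param dt Grid step, ms.
#' @export
spike_train <- function(times, duration, dt = 1) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("invalid-argument: spike times must be strictly increasing", call. = FALSE)
  }
  if (length(times) && (min(times) < 0 || max(times) > duration)) {
    stop("invalid-argument: spike times outside [0, duration]", call. = FALSE)
  }
  structure(list(times = times, duration = duration, dt = dt),
            class = "spike_train")
}

#' Resting state of a branch spike-initiation zone
#'
#' At rest the phase accumulator is primed (phase 1): the time from the last
#' spike is infinite at stimulus onset, so the branch can fire an onset
#' transient as soon as its drive is increasing and above the indentation
#' threshold (fast-adapting afferents fire at indentation onset). This is
#' what lets short presentation windows (e.g. 5 ms, less than
#' `1000 / max_rate`) evoke any spikes at all.
#' @export
branch_rest_state <- function() list(phase = 1, prev_input = 0)

#' One tick of a branch spike-initiation zone (reference implementation)
#'
#' Phase-accumulator update: `rate = min(I, max_rate)`, the phase integrates
#' `rate * dt / 1000` and a spike is emitted when the phase reaches 1 while
#' the drive is increasing and the effective indentation is at threshold.
#' While blocked, the phase is held at its ceiling of 1.
#'
#' @param state List with `phase` and `prev_input` (start from
#'   [branch_rest_state()]).
#' @param I Branch drive this tick, Hz.
#' @param dt Tick, ms.
#' @param max_rate Saturation, Hz.
#' @param eff Effective indentation this tick, mm.
#' @param spike_threshold Indentation threshold, mm (default 0.01).
#' @return List with the updated `state` and logical `spike`.
#' @export
step_branch <- function(state, I, dt, max_rate, eff = Inf,
                        spike_threshold = SPIKE_THRESHOLD_MM) {
  if (I < 0) stop("invalid-argument: drive must be >= 0", call. = FALSE)
  phase <- state$phase + min(I, max_rate) * dt / 1000
  spike <- phase >= 1 && I > state$prev_input && eff >= spike_threshold
  if (spike) phase <- phase - 1
  phase <- min(phase, 1)
  list(state = list(phase = phase, prev_input = I), spike = spike)
}

# Per-branch drive and effective indentation matrices for a stimulus over a
# clock: rows = ticks, cols = MRs.
branch_drive <- function(neuron, stimulus, clock, noise = NULL) {
  locs <- neuron$mr_locations
  p <- neuron$responsivity
  A <- amplitude_at(locs, stimulus$amplitude, noise)
  tt <- clock$times
  if (inherits(stimulus, "edge_stimulus")) {
    if (is.na(stimulus$s0)) {
      stop("invalid-argument: stimulus not positioned; call sweep_interval()",
           call. = FALSE)
    }
    b <- drop(locs %*% stimulus$normal)
    s <- stimulus$s0 + (stimulus$speed / 1000) * stimulus$normal[1] * tt
    d <- abs(outer(s, b, function(si, bi) bi - si))
  } else if (inherits(stimulus, "dot_stimulus")) {
    d <- matrix(sqrt((locs[, 1] - stimulus$center[1])^2 +
                     (locs[, 2] - stimulus$center[2])^2),
                nrow = length(tt), ncol = nrow(locs), byrow = TRUE)
  } else {
    stop("invalid-argument: unknown stimulus type", call. = FALSE)
  }
  eff <- sweep(sigmoid_term(d, p$r1, p$r2), 2, A, `*`)
  list(I = eff * p$w_mr, eff = eff)
}

#' Simulate a model neuron's response to a stimulus
#'
#' @param neuron A [neuron_model()].
#' @param stimulus A positioned [edge_stimulus()] (see [sweep_interval()]) or
#'   a [dot_stimulus()].
#' @param clock A [simulation_clock()].
#' @param noise Optional [make_noise_field()]; modulates the stimulus
#'   amplitude experienced at each MR location.
#' @param spike_threshold Indentation threshold, mm.
#' @return A [spike_train()].
#' @export
simulate_neuron <- function(neuron, stimulus, clock, noise = NULL,
                            spike_threshold = SPIKE_THRESHOLD_MM) {
  stopifnot(inherits(neuron, "neuron_model"), inherits(clock, "sim_clock"))
  code <- scheme_code(neuron$scheme)
  p <- neuron$responsivity
  nt <- length(clock$times)
  if (inherits(stimulus, "edge_stimulus")) {
    if (is.na(stimulus$s0)) {
      stop("invalid-argument: stimulus not positioned; call sweep_interval()",
           call. = FALSE)
    }
    A <- amplitude_at(neuron$mr_locations, stimulus$amplitude, noise)
    b <- drop(neuron$mr_locations %*% stimulus$normal)
    s0 <- stimulus$s0 + (stimulus$speed / 1000) * stimulus$normal[1] * clock$t_start
    ticks <- sim_edge_cpp(b, s0, (stimulus$speed / 1000) * stimulus$normal[1],
                          A, p$w_mr, p$r1, p$r2, neuron$max_rate,
                          nt, clock$dt, code, spike_threshold)
  } else {
    dr <- branch_drive(neuron, stimulus, clock, noise)
    ticks <- sim_drive_cpp(dr$I, dr$eff, clock$dt, neuron$max_rate, code,
                           spike_threshold)
  }
  spike_train(clock$times[ticks], duration = clock$t_end - clock$t_start,
              dt = clock$dt)
}

#' Smoothed firing-rate curve of a spike train
#'
#' The spike train is binned on its dt grid and convolved with a unit-area
#' Gaussian kernel (default sigma = 5 ms), yielding a rate in Hz whose time
#' integral approximates the spike count (exactly, for spikes more than ~4
#' sigma from the edges).
#'
#' @param train A [spike_train()].
#' @param smoothing_sigma Kernel width, ms (> 0).
#' @return A `rate_curve` object with `times` (ms) and `rate` (Hz).
#' @export
rate_curve <- function(train, smoothing_sigma = 5) {
  if (smoothing_sigma <= 0) stop("invalid-argument: sigma must be > 0", call. = FALSE)
  dt <- train$dt
  times <- seq(0, train$duration, by = dt)
  counts <- numeric(length(times))
  if (length(train$times)) {
    idx <- round(train$times / dt) + 1L
    for (i in idx) counts[i] <- counts[i] + 1
  }
  half <- ceiling(6 * smoothing_sigma / dt)
  k <- dnorm(seq(-half, half) * dt, sd = smoothing_sigma)
  k <- k / sum(k) * (1000 / dt)           # unit area in seconds -> Hz
  rate <- convolve(counts, rev(k), type = "open")
  rate <- rate[(half + 1):(half + length(times))]
  rate[rate < 0] <- 0                     # FFT round-off
  structure(list(times = times, rate = rate, sigma = smoothing_sigma, dt = dt),
            class = "rate_curve")
}

mean_rate_curve <- function(trains, smoothing_sigma = 5) {
  curves <- lapply(trains, rate_curve, smoothing_sigma = smoothing_sigma)
  out <- curves[[1]]
  if (length(curves) > 1) {
    out$rate <- rowMeans(vapply(curves, `[[`, numeric(length(out$rate)), "rate"))
  }
  out
}

# ---- receptive-field boundary from a moving-dot scan ------------------------

#' Receptive-field region from a moving-dot scan
#'
#' Sweeps a dot stimulus along +x over the patch on scan rows spaced
#' `scan_spacing` apart; every dot position at which the neuron fires is
#' marked responsive. The returned region (the set of responsive positions
#' with a membership raster) delimits admissible mechanoreceptor locations
#' during fitting.
#'
#' @param neuron A [neuron_model()].
#' @param patch An `mr_grid` or extents list.
#' @param dot_amplitude Dot indentation, mm (> 0 required to evoke spikes).
#' @param scan_spacing Row spacing of the scan, mm.
#' @param speed Dot speed, mm/s.
#' @return An `rf_region` object (responsive `points`, membership raster,
#'   convex-hull `polygon`).
#' @export
rf_boundary_from_dot_scan <- function(neuron, patch, dot_amplitude = 0.5,
                                      scan_spacing = 0.2, speed = 30) {
  ext <- patch_extents(patch)
  if (dot_amplitude <= 0) {
    stop("empty-region: dot amplitude must be positive to evoke spikes",
         call. = FALSE)
  }
  reach <- neuron$responsivity$r1 + neuron$responsivity$r2
  v_ms <- speed / 1000
  duration <- (ext[1] + 2 * reach) / v_ms
  tt <- seq(0, duration, by = 1)
  xs <- -reach + v_ms * tt
  pts <- NULL
  p <- neuron$responsivity
  code <- scheme_code(neuron$scheme)
  for (y in seq(0, ext[2], by = scan_spacing)) {
    d <- sqrt(outer(xs, neuron$mr_locations[, 1], `-`)^2 +
              matrix((y - neuron$mr_locations[, 2])^2,
                     nrow = length(xs), ncol = nrow(neuron$mr_locations),
                     byrow = TRUE))
    eff <- dot_amplitude * sigmoid_term(d, p$r1, p$r2)
    ticks <- sim_drive_cpp(eff * p$w_mr, eff, 1, neuron$max_rate, code,
                           SPIKE_THRESHOLD_MM)
    if (length(ticks)) pts <- rbind(pts, cbind(xs[ticks], y))
  }
  if (is.null(pts)) {
    stop("empty-region: no dot position evoked a spike", call. = FALSE)
  }
  rf_region(pts, ext, scan_spacing)
}

# Region object: responsive points + occupancy raster (cell = raster_res mm)
# dilated by `spacing`, for O(1) membership tests.
rf_region <- function(points, extent, spacing, raster_res = 0.1) {
  nx <- ceiling(extent[1] / raster_res) + 1L
  ny <- ceiling(extent[2] / raster_res) + 1L
  occ <- matrix(FALSE, nx, ny)
  rad <- ceiling(spacing / raster_res)
  ix <- round(points[, 1] / raster_res) + 1L
  iy <- round(points[, 2] / raster_res) + 1L
  keep <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  for (k in which(keep)) {
    x0 <- max(1L, ix[k] - rad); x1 <- min(nx, ix[k] + rad)
    y0 <- max(1L, iy[k] - rad); y1 <- min(ny, iy[k] + rad)
    occ[x0:x1, y0:y1] <- TRUE
  }
  hull <- points[grDevices::chull(points), , drop = FALSE]
  structure(list(points = points, extent = extent, spacing = spacing,
                 raster_res = raster_res, raster = occ, polygon = hull),
            class = "rf_region")
}

#' Membership test for an RF region
#' @param region An `rf_region`.
#' @param points n x 2 matrix (mm).
#' @return Logical vector.
#' @export
region_contains <- function(region, points) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 2)
  ix <- round(pts[, 1] / region$raster_res) + 1L
  iy <- round(pts[, 2] / region$raster_res) + 1L
  ok <- ix >= 1 & ix <= nrow(region$raster) & iy >= 1 & iy <= ncol(region$raster)
  out <- logical(nrow(pts))
  out[ok] <- region$raster[cbind(ix[ok], iy[ok])]
  out
}

#' Draw points uniformly inside an RF region (rejection sampling)
#' @param region An `rf_region`.
#' @param n Number of points.
#' @return n x 2 matrix.
#' @export
sample_in_region <- function(region, n) {
  lo <- c(min(region$points[, 1]), min(region$points[, 2]))
  hi <- c(max(region$points[, 1]), max(region$points[, 2]))
  out <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(out) < n) {
    m <- max(4 * (n - nrow(out)), 16)
    cand <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]))
    out <- rbind(out, cand[region_contains(region, cand), , drop = FALSE])
    tries <- tries + 1
    if (tries > 200) stop("infeasible: region too small to sample", call. = FALSE)
  }
  out[seq_len(n), , drop = FALSE]
}
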