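#' @useDynLib tactopop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd quantile cor convolve dnorm setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# ---- coordinate conventions -------------------------------------------------
# Units are mm and ms throughout. The skin patch is [0, extent_x] x
# [0, extent_y], origin at the lower-left corner; edges move along +x at
# `speed` mm/s. Edge orientation theta is the signed angle (degrees, positive
# counterclockwise) between the edge line and the y axis, so theta = 0 means
# the edge is perpendicular to the motion direction. The unit normal of the
# edge line is n = (cos theta, sin theta) and the line's position is its
# signed offset s along n, advancing at speed * cos(theta).

#' Regular mechanoreceptor grid covering a skin patch
#'
#' Mechanoreceptors tile the patch on a square lattice (0.1 mm spacing by
#' default), including both borders, in row-major order (x varies fastest).
#'
#' @param extent_x,extent_y Patch extents in mm; positive multiples of
#'   `spacing`.
#' @param spacing Lattice spacing in mm (default 0.1).
#' @return An object of class `mr_grid` with fields `extent_x`, `extent_y`,
#'   `spacing` and `positions` (an n x 2 matrix of mm coordinates).
#' @export
build_grid <- function(extent_x, extent_y, spacing = 0.1) {
  if (!is.numeric(extent_x) || !is.numeric(extent_y) || !is.numeric(spacing) ||
      extent_x <= 0 || extent_y <= 0 || spacing <= 0) {
    stop("invalid-argument: extents and spacing must be positive", call. = FALSE)
  }
  nx <- extent_x / spacing
  ny <- extent_y / spacing
  if (abs(nx - round(nx)) > 1e-8 || abs(ny - round(ny)) > 1e-8) {
    stop("invalid-argument: extents must be multiples of spacing", call. = FALSE)
  }
  xs <- seq(0, extent_x, by = spacing)
  ys <- seq(0, extent_y, by = spacing)
  positions <- cbind(
    x = rep(xs, times = length(ys)),
    y = rep(ys, each = length(xs))
  )
  structure(
    list(extent_x = extent_x, extent_y = extent_y, spacing = spacing,
         positions = positions),
    class = "mr_grid"
  )
}

#' Moving oriented edge stimulus
#'
#' An infinite zero-width line of indentation `amplitude` translating along +x
#' at `speed`. `window_ms = Inf` means an unlimited presentation: the edge
#' sweeps the whole patch (see [sweep_interval()]).
#'
#' @param orientation_deg Signed angle between the edge and the y axis,
#'   degrees in (-90, 90); 0 = perpendicular to the motion direction.
#' @param speed Sweep speed in mm/s (default 30).
#' @param amplitude Edge indentation in mm (default 0.5).
#' @param window_ms Presentation window in ms, or `Inf` for unlimited.
#' @return An `edge_stimulus` object.
#' @export
edge_stimulus <- function(orientation_deg, speed = 30, amplitude = 0.5,
                          window_ms = Inf) {
  if (!is.numeric(orientation_deg) || orientation_deg <= -90 ||
      orientation_deg >= 90) {
    stop("invalid-argument: orientation must lie in (-90, 90) degrees",
         call. = FALSE)
  }
  if (speed <= 0 || amplitude <= 0 ||
      (is.finite(window_ms) && window_ms <= 0)) {
    stop("invalid-argument: speed, amplitude and window must be positive",
         call. = FALSE)
  }
  th <- orientation_deg * pi / 180
  structure(
    list(orientation_deg = orientation_deg, speed = speed,
         amplitude = amplitude, window_ms = window_ms,
         normal = c(cos(th), sin(th)), s0 = NA_real_),
    class = "edge_stimulus"
  )
}

#' Punctate (dot) stimulus
#'
#' @param center 2-D point (mm).
#' @param amplitude Indentation in mm (> 0).
#' @return A `dot_stimulus` object.
#' @export
dot_stimulus <- function(center, amplitude = 0.5) {
  if (amplitude <= 0) stop("invalid-argument: amplitude must be > 0",
                           call. = FALSE)
  structure(list(center = as.numeric(center), amplitude = amplitude),
            class = "dot_stimulus")
}

#' Simulation clock
#'
#' @param t_start,t_end Start and end times in ms (`t_end > t_start`).
#' @param dt Tick size in ms (default 1).
#' @return A `sim_clock` object with a `times` grid.
#' @export
simulation_clock <- function(t_start, t_end, dt = 1) {
  if (dt <= 0 || t_end <= t_start) {
    stop("invalid-argument: need dt > 0 and t_end > t_start", call. = FALSE)
  }
  structure(list(t_start = t_start, t_end = t_end, dt = dt,
                 times = seq(t_start, t_end, by = dt)),
            class = "sim_clock")
}

patch_extents <- function(patch) {
  if (inherits(patch, "mr_grid")) c(patch$extent_x, patch$extent_y)
  else c(patch$extent_x, patch$extent_y)
}

#' Position an edge sweep over a patch and build its clock
#'
#' For an unlimited window the edge line starts `margin` mm beyond one patch
#' border (along its normal) and ends `margin` beyond the other. For a finite
#' window of T ms the trajectory covers speed x T of travel centred on the
#' patch centre.
#'
#' @param stimulus An [edge_stimulus()].
#' @param patch An `mr_grid` or any list with `extent_x`/`extent_y`.
#' @param margin Extra reach beyond the patch borders, mm (default 2, beyond
#'   the maximal mechanoreceptor responsivity `r1 + r2 = 2` mm search bound).
#' @return List with the positioned `stimulus` (its `s0` line offset at t = 0
#'   set) and the `clock` (t = 0 at sweep start).
#' @export
sweep_interval <- function(stimulus, patch, margin = 2) {
  stopifnot(inherits(stimulus, "edge_stimulus"))
  ext <- patch_extents(patch)
  n <- stimulus$normal
  corners <- rbind(c(0, 0), c(ext[1], 0), c(0, ext[2]), ext)
  proj <- corners %*% n
  v_ms <- stimulus$speed / 1000            # mm per ms along x
  slope <- v_ms * n[1]                     # line-offset advance per ms
  if (is.finite(stimulus$window_ms)) {
    s_center <- sum(ext / 2 * n)
    s_start <- s_center - slope * stimulus$window_ms / 2
    duration <- stimulus$window_ms
  } else {
    s_start <- min(proj) - margin
    duration <- (max(proj) + margin - s_start) / slope
  }
  stimulus$s0 <- s_start
  list(stimulus = stimulus,
       clock = simulation_clock(0, ceiling(duration), dt = 1))
}

#' Perpendicular distance from a point to a moving edge
#'
#' @param point 2-D point (mm) or an n x 2 matrix of points.
#' @param stimulus A positioned [edge_stimulus()] (after [sweep_interval()]).
#' @param t Time in ms (scalar).
#' @return Distance(s) in mm.
#' @export
edge_distance <- function(point, stimulus, t) {
  stopifnot(inherits(stimulus, "edge_stimulus"))
  if (is.na(stimulus$s0)) {
    stop("invalid-argument: stimulus not positioned; call sweep_interval()",
         call. = FALSE)
  }
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  s <- stimulus$s0 + (stimulus$speed / 1000) * stimulus$normal[1] * t
  abs(drop(pts %*% stimulus$normal) - s)
}

# ---- additive patch noise ---------------------------------------------------

#' Additive stimulus noise as a lattice of square patches
#'
#' Noise modulates the stimulus amplitude in fixed `patch_size` x `patch_size`
#' mm tiles anchored at the patch origin; each tile carries one i.i.d. uniform
#' amplitude offset in +/- `level_pct`/100 x `stim_amplitude` mm.
#'
#' @param level_pct Noise level as percent of the stimulus amplitude (0-10 in
#'   the experiments; any non-negative value allowed).
#' @param patch A skin patch (`mr_grid` or extents list).
#' @param patch_size Noise tile edge, mm (default 0.4).
#' @param stim_amplitude Stimulus amplitude the level refers to, mm.
#' @param seed RNG seed; the field is reproducible from it.
#' @return A `noise_field` object.
#' @export
make_noise_field <- function(level_pct, patch, patch_size = 0.4,
                             stim_amplitude = 0.5, seed = 1L) {
  if (!is.numeric(level_pct) || level_pct < 0) {
    stop("invalid-argument: noise level must be >= 0", call. = FALSE)
  }
  ext <- patch_extents(patch)
  nx <- max(1L, ceiling(ext[1] / patch_size - 1e-9))
  ny <- max(1L, ceiling(ext[2] / patch_size - 1e-9))
  bound <- level_pct / 100 * stim_amplitude
  offsets <- matrix(0, nx, ny)
  if (level_pct > 0) {
    offsets <- with_seed(seed, matrix(runif(nx * ny, -bound, bound), nx, ny))
  }
  structure(
    list(level_pct = level_pct, patch_size = patch_size,
         stim_amplitude = stim_amplitude, extent = ext,
         offsets = offsets, seed = seed),
    class = "noise_field"
  )
}

# Evaluate expr under a fixed seed, leaving the caller's RNG state untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Expand one seed into reproducible per-stage child seeds (kept < 2^31).
derive_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(as.character(stage))) %% 1000L
  as.integer((as.double(seed) * 7919 + h * 104729 + index * 271) %% 2147483587)
}

#' Local stimulus amplitude under additive patch noise
#'
#' The amplitude experienced at a skin location is the nominal stimulus
#' amplitude plus the offset of the 0.4 mm noise tile containing it, floored
#' at 0 (the stimulus is forced to be strictly non-negative).
#'
#' @param point 2-D point or n x 2 matrix (mm), inside the patch.
#' @param amplitude Nominal stimulus amplitude, mm.
#' @param noise A [make_noise_field()] result, or `NULL` for no noise.
#' @return Amplitude(s) in mm.
#' @export
local_amplitude <- function(point, amplitude, noise = NULL) {
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  if (is.null(noise)) return(rep(amplitude, nrow(pts)))
  ext <- noise$extent
  eps <- 1e-9
  if (any(pts[, 1] < -eps | pts[, 1] > ext[1] + eps |
          pts[, 2] < -eps | pts[, 2] > ext[2] + eps)) {
    stop("out-of-bounds: point outside the skin patch", call. = FALSE)
  }
  ix <- pmin(pmax(floor(pts[, 1] / noise$patch_size) + 1L, 1L), nrow(noise$offsets))
  iy <- pmin(pmax(floor(pts[, 2] / noise$patch_size) + 1L, 1L), ncol(noise$offsets))
  pmax(0, amplitude + noise$offsets[cbind(ix, iy)])
}

# As local_amplitude(), but points outside the noise lattice (e.g. MRs of
# border neurons in a tiled population) take the unperturbed amplitude.
amplitude_at <- function(points, amplitude, noise = NULL) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 2)
  if (is.null(noise)) return(rep(amplitude, nrow(pts)))
  ext <- noise$extent
  inside <- pts[, 1] >= 0 & pts[, 1] <= ext[1] &
            pts[, 2] >= 0 & pts[, 2] <= ext[2]
  out <- rep(amplitude, nrow(pts))
  if (any(inside)) {
    out[inside] <- local_amplitude(pts[inside, , drop = FALSE], amplitude, noise)
  }
  out
}
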