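#' Condition specification for the pursuit paradigm
#'
#' One cell of the 2 x 2 (motion noise x speed) design: a sinusoidally moving
#' target of given period and amplitude, optionally perturbed by a Gaussian
#' phase random walk, preceded by a static lead and partially hidden by an
#' occluder on the half-plane opposite the start side.
#'
#' @param period Cycle period, seconds (Fast 4.173 s, Slow 5.1 s).
#' @param motion_noise Logical; add the phase random walk?
#' @param noise_variance Variance of the per-millisecond phase-walk increment
#'   (ms^2); exp(-0.5) in the Noisy conditions.
#' @param amplitude_deg Target amplitude, degrees of visual angle (14.4 deg =
#'   half of the 28.8 deg path).
#' @param sample_rate Samples per second.
#' @param n_cycles Full cycles of motion per trial.
#' @param start_side `"right"` (+1) or `"left"` (-1).
#' @param static_lead Stationary lead before motion, seconds.
#' @param condition Optional label.
#' @return Object of class `condition_spec`.
#' @export
condition_spec <- function(period = 4.173, motion_noise = FALSE,
                           noise_variance = if (motion_noise) exp(-0.5) else 0,
                           amplitude_deg = 14.4, sample_rate = 1000,
                           n_cycles = 3, start_side = c("right", "left"),
                           static_lead = 2, condition = NULL) {
  start_side <- match.arg(start_side)
  stopifnot(period > 0, sample_rate > 0, n_cycles >= 1, noise_variance >= 0,
            amplitude_deg > 0, static_lead >= 0)
  structure(list(period = period, motion_noise = motion_noise,
                 noise_variance = noise_variance,
                 amplitude_deg = amplitude_deg, sample_rate = sample_rate,
                 n_cycles = n_cycles, start_side = start_side,
                 static_lead = static_lead,
                 condition = condition %||% sprintf(
                   "%s-%s", if (motion_noise) "Noisy" else "Smooth",
                   if (period < 4.7) "Fast" else "Slow")),
            class = "condition_spec")
}

#' Default occluder for a condition
#'
#' The occluder spans midline to 0.8 of maximal displacement on the half-plane
#' opposite the trial's start position.
#'
#' @param spec A [condition_spec()].
#' @param softness Edge softness passed to [occluder_geometry()].
#' @return An [occluder_geometry()].
#' @export
condition_occluder <- function(spec, softness = 0) {
  if (spec$start_side == "right") occluder_geometry(-0.8, 0, softness)
  else occluder_geometry(0, 0.8, softness)
}

start_sign <- function(spec) if (spec$start_side == "right") 1 else -1

#' Smooth sinusoidal target trajectory
#'
#' Position (normalised amplitude units) is `s * cos(2*pi*(t - lead)/period)`
#' with `s` the start sign, so the trace starts at the trial's start extreme
#' and completes exactly `n_cycles` cycles after the static lead.
#'
#' @param spec A [condition_spec()] with `motion_noise = FALSE`.
#' @param geom Occluder used to flag per-sample visibility; default from
#'   [condition_occluder()].
#' @return A `target_trace`: tibble with columns `time_ms`, `position`
#'   (amplitude units), `carrier` (noiseless position) and `visible`, plus the
#'   spec and geometry as attributes.
#' @export
smooth_target <- function(spec = condition_spec(),
                          geom = condition_occluder(spec)) {
  if (spec$motion_noise) stop("use noisy_target() when motion_noise is TRUE")
  build_target_trace(spec, geom, phase_walk_ms = NULL)
}

#' Noisy sinusoidal target trajectory
#'
#' Adds a Gaussian random walk (variance `noise_variance` per millisecond) to
#' the time argument of the cosine: x(t) = cos(2*pi*f*(t + phi(t))),
#' phi(t) = phi(t-1) + omega(t). The walk is generated at 1 kHz and linearly
#' interpolated to other sample rates; the underlying period is unchanged.
#'
#' @inheritParams smooth_target
#' @param spec A [condition_spec()] with `motion_noise = TRUE`.
#' @param seed Integer seed; the trace is reproducible given the seed.
#' @return A `target_trace` (see [smooth_target()]).
#' @export
noisy_target <- function(spec = condition_spec(motion_noise = TRUE), seed,
                         geom = condition_occluder(spec)) {
  if (!spec$motion_noise) stop("use smooth_target() when motion_noise is FALSE")
  if (missing(seed)) stop("`seed` is required for noisy targets")
  n_ms <- ceiling(spec$n_cycles * spec$period * 1000)
  walk <- with_seed(seed, cumsum(rnorm(n_ms, 0, sqrt(spec$noise_variance))))
  build_target_trace(spec, geom, phase_walk_ms = c(0, walk))
}

# Shared trace builder; phase_walk_ms is the walk on a 1 kHz grid (or NULL).
build_target_trace <- function(spec, geom, phase_walk_ms) {
  dt_ms <- 1000 / spec$sample_rate
  total_ms <- spec$static_lead * 1000 + spec$n_cycles * spec$period * 1000
  time_ms <- seq(0, total_ms, by = dt_ms)
  t_move <- pmax(time_ms - spec$static_lead * 1000, 0) # ms since motion onset
  s <- start_sign(spec)
  f <- 1 / (spec$period * 1000) # cycles per ms
  carrier <- s * cos(2 * pi * f * t_move)
  if (is.null(phase_walk_ms)) {
    position <- carrier
  } else {
    phi <- stats::approx(seq_along(phase_walk_ms) - 1, phase_walk_ms,
                         xout = t_move, rule = 2)$y
    position <- s * cos(2 * pi * f * (t_move + phi))
    position[t_move == 0] <- s # static lead: target at the start extreme
  }
  out <- tibble::tibble(time_ms = time_ms, position = position,
                        carrier = carrier,
                        visible = occluder_visibility(position, geom) > 0.5)
  structure(out, spec = spec, geom = geom,
            class = c("target_trace", class(out)))
}

#' Occlusion windows of a target trace
#'
#' Time intervals during which the noiseless carrier lies inside the occluder
#' window (two per cycle for the standard geometry). Edge times are refined by
#' linear interpolation between samples.
#'
#' @param trace A `target_trace` from [smooth_target()] or [noisy_target()].
#' @param geom Occluder geometry; defaults to the trace's own.
#' @return Tibble with columns `t_start`, `t_end` (ms) and `duration_ms`.
#' @export
occlusion_windows <- function(trace, geom = attr(trace, "geom")) {
  stopifnot(inherits(trace, "target_trace"))
  if (nrow(trace) == 0) stop("empty trace")
  spec <- attr(trace, "spec")
  t <- trace$time_ms
  x <- trace$carrier
  moving <- t > spec$static_lead * 1000
  inside <- x >= geom$lower & x <= geom$upper & moving
  if (!any(inside)) return(tibble::tibble(t_start = numeric(),
                                          t_end = numeric(),
                                          duration_ms = numeric()))
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  edge_time <- function(i0, i1, edge) {
    # linear interpolation of the crossing time of `edge` between samples
    if (i0 < 1 || i1 > length(t) || x[i1] == x[i0]) return(t[max(i0, 1)])
    t[i0] + (edge - x[i0]) / (x[i1] - x[i0]) * (t[i1] - t[i0])
  }
  res <- lapply(keep, function(k) {
    i_a <- starts[k]; i_b <- ends[k]
    # which edge is crossed on entry/exit depends on travel direction
    enter_edge <- if (i_a > 1 && x[i_a - 1] > geom$upper) geom$upper else geom$lower
    exit_edge <- if (i_b < length(x) && x[i_b + 1] > geom$upper) geom$upper else geom$lower
    t0 <- if (i_a > 1 && moving[i_a - 1]) edge_time(i_a - 1, i_a, enter_edge) else t[i_a]
    t1 <- if (i_b < length(x)) edge_time(i_b, i_b + 1, exit_edge) else t[i_b]
    c(t0, t1)
  })
  m <- do.call(rbind, res)
  tibble::tibble(t_start = m[, 1], t_end = m[, 2],
                 duration_ms = m[, 2] - m[, 1])
}

#' Fraction and extent of the path that is occluded
#'
#' @param geom An [occluder_geometry()].
#' @param path_extent_deg Full path length, degrees (28.8 deg by default).
#' @return List with `fraction` (of the 2-amplitude-unit path) and `degrees`.
#' @export
occluded_path_fraction <- function(geom = occluder_geometry(),
                                   path_extent_deg = 28.8) {
  stopifnot(path_extent_deg > 0)
  frac <- min((geom$upper - geom$lower) / 2, 1)
  list(fraction = frac, degrees = frac * path_extent_deg)
}

#' The 2 x 2 condition grid
#'
#' Smooth/Noisy crossed with Slow (period 5.1 s) / Fast (period 4.173 s);
#' Noisy conditions add a phase walk of per-ms variance exp(-0.5); amplitude
#' 14.4 deg (half of the 28.8 deg path).
#'
#' @param ... Passed to every [condition_spec()] (e.g. `n_cycles`,
#'   `start_side`).
#' @return Named list of four `condition_spec`s in the canonical order
#'   Smooth-Slow, Smooth-Fast, Noisy-Slow, Noisy-Fast.
#' @export
condition_grid <- function(...) {
  grid <- list(
    `Smooth-Slow` = condition_spec(period = 5.1, motion_noise = FALSE, ...),
    `Smooth-Fast` = condition_spec(period = 4.173, motion_noise = FALSE, ...),
    `Noisy-Slow`  = condition_spec(period = 5.1, motion_noise = TRUE, ...),
    `Noisy-Fast`  = condition_spec(period = 4.173, motion_noise = TRUE, ...)
  )
  for (nm in names(grid)) grid[[nm]]$condition <- nm
  grid
}

#' Peak target speed of a condition
#' @param spec A [condition_spec()].
#' @return Peak speed of the carrier, degrees per second.
#' @export
peak_target_speed <- function(spec) {
  2 * pi * spec$amplitude_deg / spec$period
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a target trace
#'
#' Delimited text with columns `time_ms`, `position`, `carrier`, `visible`,
#' plus a JSON sidecar `<file>.json` holding the generating
#' [condition_spec()] and occluder geometry.
#'
#' @param trace A `target_trace`.
#' @param file Output path.
#' @return `file` invisibly (writer); the reconstructed `target_trace`
#'   (reader).
#' @export
write_target_trace <- function(trace, file) {
  stopifnot(inherits(trace, "target_trace"))
  readr::write_tsv(as.data.frame(trace), file, progress = FALSE)
  spec <- attr(trace, "spec")
  geom <- attr(trace, "geom")
  jsonlite::write_json(list(spec = unclass(spec), geom = unclass(geom)),
                       paste0(file, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_target_trace
#' @export
read_target_trace <- function(file) {
  out <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  spec <- structure(meta$spec, class = "condition_spec")
  geom <- occluder_geometry(meta$geom$lower, meta$geom$upper,
                            meta$geom$softness)
  structure(out, spec = spec, geom = geom,
            class = c("target_trace", class(out)))
}
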