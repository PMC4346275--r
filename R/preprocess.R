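#' Read a raw eye-trace file
#'
#' Trial files are delimited text with columns `time_ms`, `x` (horizontal eye
#' position, degrees) and optionally `y` and `pupil`. Eyelink-style ASCII
#' sample lines (`timestamp x y pupil`, whitespace-separated, `.` for missing)
#' are read as a thin dialect of the same table.
#'
#' @param file Path to the trace file.
#' @param format `"auto"` (sniff), `"table"` (named delimited columns) or
#'   `"eyelink"` (headerless sample lines).
#' @return Tibble with `time_ms`, `x` and any extra columns; missing samples
#'   are `NA`.
#' @export
read_trace <- function(file, format = c("auto", "table", "eyelink")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(file, n = 1)
    format <- if (grepl("time_ms", first)) "table" else "eyelink"
  }
  if (format == "table") {
    out <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
    stopifnot(all(c("time_ms", "x") %in% names(out)))
    return(out)
  }
  raw <- utils::read.table(file, header = FALSE, na.strings = ".",
                           col.names = c("time_ms", "x", "y", "pupil")[1:4],
                           fill = TRUE)
  tibble::as_tibble(raw)
}

#' Write a raw eye-trace file
#'
#' @param trace Tibble with at least `time_ms` and `x`.
#' @param file Output path (tab-separated, with header).
#' @return `file`, invisibly.
#' @export
write_trace <- function(trace, file) {
  readr::write_tsv(trace, file, progress = FALSE)
  invisible(file)
}

#' Convert between degrees of visual angle and on-screen centimetres
#'
#' Uses the flat-screen tangent mapping at the given viewing distance.
#'
#' @param deg,cm Horizontal displacement from straight ahead.
#' @param distance_cm Viewing distance (paper's setup: 60 cm).
#' @return The converted displacement.
#' @export
deg_to_cm <- function(deg, distance_cm = 60) distance_cm * tan(deg * pi / 180)

#' @rdname deg_to_cm
#' @export
cm_to_deg <- function(cm, distance_cm = 60) atan(cm / distance_cm) * 180 / pi

#' Segment a trial into single target cycles
#'
#' Drops the static lead and cuts the moving part of the trace at carrier
#' phase-zero crossings, yielding one record per full cycle (three per clean
#' trial). The noiseless carrier implied by the condition is attached to every
#' sample.
#'
#' @param trace Tibble with `time_ms` and `x` (degrees).
#' @param spec The trial's [condition_spec()].
#' @param lead_s Static-lead duration for this trial, seconds.
#' @return Tibble with columns `cycle`, `time_ms`, `phase` (cycle fraction),
#'   `eye_deg`, `carrier_deg`; incomplete trailing cycles are dropped. An
#'   empty tibble (with a warning) if the trace is shorter than one cycle.
#' @export
segment_cycles <- function(trace, spec, lead_s = spec$static_lead) {
  stopifnot(all(c("time_ms", "x") %in% names(trace)))
  period_ms <- spec$period * 1000
  t_mv <- trace$time_ms - lead_s * 1000
  keep <- t_mv >= 0
  if (sum(keep) < 2 || max(t_mv) < period_ms) {
    warning("trace shorter than one full cycle; no records")
    return(tibble::tibble(cycle = integer(), time_ms = numeric(),
                          phase = numeric(), eye_deg = numeric(),
                          carrier_deg = numeric()))
  }
  sgn <- start_sign(spec)
  tm <- t_mv[keep]
  out <- tibble::tibble(
    time_ms = trace$time_ms[keep],
    cycle = as.integer(floor(tm / period_ms)) + 1L,
    phase = (tm %% period_ms) / period_ms,
    eye_deg = trace$x[keep],
    carrier_deg = sgn * spec$amplitude_deg * cos(2 * pi * tm / period_ms))
  full <- floor((max(tm) + 1000 / spec$sample_rate) / period_ms)
  dplyr::filter(out, .data$cycle <= full)
}

#' Cycle-level quality filtering
#'
#' Computes the eye-versus-carrier RMSE of every cycle (converted to screen
#' centimetres) and flags cycles exceeding `rmse_threshold_cm` (the screening
#' threshold used on the original recordings, 3.8 cm). A flagged cycle is
#' discarded when it also shows objective damage: a blink gap of at least
#' `gap_ms` of missing samples, or tracking failure (RMSE above twice the
#' threshold). This replaces interactive visual inspection with deterministic
#' rules.
#'
#' @param cycles Output of [segment_cycles()], optionally with extra key
#'   columns (subject, condition, trial) which are preserved.
#' @param rmse_threshold_cm Screening threshold, cm.
#' @param distance_cm Viewing distance for the deg-to-cm conversion.
#' @param gap_ms Minimum run of missing samples that counts as a blink gap.
#' @return List with `kept` and `discarded` (sample tibbles) and `summary`
#'   (one row per cycle: RMSE, gap length, flags) including the overall
#'   `discard_fraction` as an attribute.
#' @export
quality_filter <- function(cycles, rmse_threshold_cm = 3.8,
                           distance_cm = 60, gap_ms = 100) {
  keys <- intersect(c("subject", "condition", "trial", "cycle"),
                    names(cycles))
  summary <- cycles |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      rmse_cm = sqrt(mean((deg_to_cm(.data$eye_deg, distance_cm) -
                             deg_to_cm(.data$carrier_deg, distance_cm))^2,
                          na.rm = TRUE)),
      max_gap_ms = longest_na_run(.data$eye_deg) *
        ifelse(dplyr::n() > 1, stats::median(diff(.data$time_ms)), 1),
      .groups = "drop") |>
    dplyr::mutate(
      flagged = .data$rmse_cm > rmse_threshold_cm,
      discard = .data$flagged & (.data$max_gap_ms >= gap_ms |
                                   .data$rmse_cm > 2 * rmse_threshold_cm))
  joined <- dplyr::left_join(cycles, summary, by = keys)
  kept <- dplyr::select(dplyr::filter(joined, !.data$discard),
                        -"rmse_cm", -"max_gap_ms", -"flagged", -"discard")
  discarded <- dplyr::select(dplyr::filter(joined, .data$discard),
                             -"rmse_cm", -"max_gap_ms", -"flagged",
                             -"discard")
  attr(summary, "discard_fraction") <- mean(summary$discard)
  list(kept = kept, discarded = discarded, summary = summary)
}

longest_na_run <- function(x) {
  if (!anyNA(x)) return(0L)
  r <- rle(is.na(x))
  max(r$lengths[r$values])
}

#' Normalise a cycle to unit amplitude and a common phase grid
#'
#' Divides eye position by the carrier amplitude, flips left-start trials so
#' the carrier is always `cos(2 pi phase)`, linearly bridges missing samples
#' (blink gaps), and resamples to `n_bins` bin centres `(k - 1/2) / n_bins` by
#' linear interpolation. Normalisation makes recordings comparable across
#' screen units and geometries.
#'
#' @param cycles Kept cycles from [quality_filter()] (or [segment_cycles()]).
#' @param spec The [condition_spec()] of these trials.
#' @param n_bins Bins per cycle.
#' @return Tibble with keys, `bin`, `phase`, `eye` (amplitude units) and
#'   `carrier`.
#' @export
normalize_cycle <- function(cycles, spec, n_bins = 128) {
  keys <- intersect(c("subject", "condition", "trial", "cycle"),
                    names(cycles))
  sgn <- start_sign(spec)
  grid <- (seq_len(n_bins) - 0.5) / n_bins
  cycles |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      y <- df$eye_deg
      if (all(is.na(y))) stop("cycle with no valid samples")
      if (anyNA(y)) # bridge blink gaps before resampling
        y <- stats::approx(df$phase[!is.na(y)], y[!is.na(y)],
                           xout = df$phase, rule = 2)$y
      eye <- stats::approx(df$phase, sgn * y / spec$amplitude_deg,
                           xout = grid, rule = 2)$y
      tibble::tibble(bin = seq_len(n_bins), phase = grid, eye = eye,
                     carrier = cos(2 * pi * grid))
    }) |>
    dplyr::ungroup()
}

#' Grand-average normalised cycles
#'
#' Two-stage averaging: bin-wise mean over cycles within each subject, then
#' over subjects with equal weight (the grand-averaging convention of
#' event-related potentials). Position error is the averaged eye minus the
#' unit-amplitude carrier, bin-wise.
#'
#' @param normalized Output of [normalize_cycle()], with `subject` and
#'   `condition` keys (a missing `subject` column is treated as one subject).
#' @return A `grand_average` tibble: `condition`, `bin`, `phase`, `eye`,
#'   `carrier`, `error`, `n_cycles`, `n_subjects`.
#' @export
grand_average <- function(normalized) {
  if (!"subject" %in% names(normalized)) normalized$subject <- 1L
  if (!"condition" %in% names(normalized)) normalized$condition <- "all"
  per_subject <- normalized |>
    dplyr::group_by(.data$condition, .data$subject, .data$bin, .data$phase,
                    .data$carrier) |>
    dplyr::summarise(eye = mean(.data$eye), n_cycles = dplyr::n(),
                     .groups = "drop")
  out <- per_subject |>
    dplyr::group_by(.data$condition, .data$bin, .data$phase, .data$carrier) |>
    dplyr::summarise(eye = mean(.data$eye),
                     n_cycles = sum(.data$n_cycles),
                     n_subjects = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(error = .data$eye - .data$carrier) |>
    dplyr::arrange(.data$condition, .data$bin)
  class(out) <- c("grand_average", class(out))
  out
}

#' Residual pursuit velocity during occlusion
#'
#' Mean eye velocity over the latter half of each occlusion window after
#' excluding saccadic samples: velocity is computed on the raw traces by
#' central differences (then lightly smoothed), samples with speed above
#' `saccade_threshold` deg/s are masked together with a guard band of
#' `guard_ms` on each side, and the retained samples are averaged.
#'
#' @param trace Raw trial tibble (`time_ms`, `x` in degrees).
#' @param spec The trial's [condition_spec()].
#' @param lead_s Static lead of this trial, seconds.
#' @param windows Occlusion windows (tibble with `t_start`, `t_end` in ms on
#'   the trace's clock); default computed from the condition's geometry.
#' @param saccade_threshold Exclusion threshold, deg/s.
#' @param guard_ms Guard band around each saccadic excursion, ms.
#' @param smooth_ms Width of the moving-average velocity smoother, ms.
#' @return Tibble with one row per occlusion window: `window`, `t_start`,
#'   `t_end`, `velocity` (deg/s; `NA` if fully masked) and `n_retained`.
#' @export
residual_pursuit_velocity <- function(trace, spec, lead_s = spec$static_lead,
                                      windows = NULL,
                                      saccade_threshold = 35, guard_ms = 20,
                                      smooth_ms = 11) {
  if (is.null(windows)) {
    tr <- smooth_target(replace_lead(spec, lead_s))
    windows <- occlusion_windows(tr)
  }
  dt_ms <- stats::median(diff(trace$time_ms))
  v <- rep(NA_real_, nrow(trace))
  x <- trace$x
  n <- length(x)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt_ms) * 1000
  k <- max(1L, round(smooth_ms / dt_ms))
  if (k > 1) {
    kern <- rep(1 / k, k)
    v_s <- stats::filter(v, kern, sides = 2)
    v <- as.numeric(v_s)
  }
  sacc <- !is.na(v) & abs(v) > saccade_threshold
  guard <- round(guard_ms / dt_ms)
  if (any(sacc) && guard > 0) {
    idx <- which(sacc)
    for (i in idx) sacc[max(1, i - guard):min(n, i + guard)] <- TRUE
  }
  purrr::pmap_dfr(
    list(seq_len(nrow(windows)), windows$t_start, windows$t_end),
    function(w, t0, t1) {
      mid <- (t0 + t1) / 2
      sel <- trace$time_ms >= mid & trace$time_ms <= t1 & !sacc & !is.na(v)
      tibble::tibble(window = w, t_start = t0, t_end = t1,
                     velocity = if (any(sel)) mean(v[sel]) else NA_real_,
                     n_retained = sum(sel))
    })
}

replace_lead <- function(spec, lead_s) {
  spec$static_lead <- lead_s
  spec
}

#' Write / read a grand average with metadata
#'
#' The table is written as tab-separated text; preprocessing metadata
#' (normalisation, interpolation and filtering rules) goes to a JSON sidecar
#' `<file>.json`.
#'
#' @param ga A `grand_average` tibble.
#' @param file Output path.
#' @param meta Named list of metadata to record.
#' @return `file`, invisibly (for the writer); the tibble (for the reader).
#' @export
write_grand_average <- function(ga, file, meta = list()) {
  readr::write_tsv(ga, file, progress = FALSE)
  meta <- utils::modifyList(list(
    normalisation = "unit amplitude; left-start trials sign-flipped",
    gap_bridging = "linear interpolation before resampling",
    resampling = "linear interpolation to bin centres (k - 1/2) / n_bins"),
    meta)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_grand_average
#' @export
read_grand_average <- function(file) {
  out <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("grand_average", class(out))
  out
}
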