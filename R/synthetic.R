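#' Specification of a synthetic pursuit cohort
#'
#' Describes a multi-subject, multi-trial synthetic data set with known
#' ground-truth parameters: per the experimental design, each subject
#' completes 12 trials (36 cycles) of each of the four conditions, each trial
#' being a 1-3 s static lead followed by three cycles of motion. Measurement
#' noise, saccadic intrusions and blink gaps emulate artefacts of real
#' recordings; their rates are configurable and default to plausible values.
#'
#' @param n_subjects Number of subjects.
#' @param trials_per_condition Trials per condition per subject.
#' @param param_jitter_sd SD of per-subject jitter added to the latent
#'   deviations (0 = identical subjects).
#' @param noise_sd_deg Gaussian measurement noise SD, degrees.
#' @param saccade_rate_hz Rate of saccadic intrusions (Poisson), Hz.
#' @param saccade_amp_deg Mean of the exponential intrusion amplitude, deg.
#' @param saccade_tau_ms Decay time of the intrusion back to the pursuit
#'   trajectory, ms.
#' @param blink_rate_hz Blink rate (Poisson), Hz.
#' @param blink_dur_ms Range (min, max) of blink durations, ms.
#' @param respond_to `"carrier"`: subjects' simulated responses are driven by
#'   the noiseless carrier in all conditions (condition effects enter only
#'   through parameters, matching the deterministic grand-average observation
#'   model); `"stimulus"`: responses are driven by each trial's realised
#'   (possibly phase-noisy) stimulus.
#' @param master_seed Integer master seed; everything derives from it.
#' @param engine [engine_config()] used for the underlying simulations.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 4, trials_per_condition = 12,
                        param_jitter_sd = 0, noise_sd_deg = 0.5,
                        saccade_rate_hz = 0.5, saccade_amp_deg = 1,
                        saccade_tau_ms = 150, blink_rate_hz = 0.1,
                        blink_dur_ms = c(100, 300),
                        respond_to = c("carrier", "stimulus"),
                        master_seed = 1, engine = engine_config()) {
  respond_to <- match.arg(respond_to)
  stopifnot(n_subjects >= 1, trials_per_condition >= 1, param_jitter_sd >= 0,
            noise_sd_deg >= 0, saccade_rate_hz >= 0, blink_rate_hz >= 0,
            length(blink_dur_ms) == 2)
  structure(list(n_subjects = n_subjects,
                 trials_per_condition = trials_per_condition,
                 param_jitter_sd = param_jitter_sd,
                 noise_sd_deg = noise_sd_deg,
                 saccade_rate_hz = saccade_rate_hz,
                 saccade_amp_deg = saccade_amp_deg,
                 saccade_tau_ms = saccade_tau_ms,
                 blink_rate_hz = blink_rate_hz,
                 blink_dur_ms = blink_dur_ms, respond_to = respond_to,
                 master_seed = as.integer(master_seed), engine = engine),
            class = "cohort_spec")
}

# deterministic sub-seed, kept within 32-bit range
sub_seed <- function(master, subject, cond_idx, trial) {
  (master * 1009L + subject * 7919L + cond_idx * 101L + trial) %% 2147483100L
}

#' Simulate one subject's raw trials
#'
#' For each condition and trial: draws the static lead (uniform on 1-3 s),
#' simulates Bayes-optimal pursuit under the subject's condition-specific
#' parameters, rescales to degrees at 1 kHz, and adds measurement noise,
#' saccadic intrusions (transient steps decaying back to the trajectory) and
#' blink gaps (runs of missing samples). With all artefact rates at zero the
#' trace equals the rescaled simulation exactly.
#'
#' @param truth A [design_effects()] object: the generating latent deviations.
#' @param spec A [cohort_spec()].
#' @param subject Subject index (1-based).
#' @param conditions Condition list, default [condition_grid()].
#' @param prior A [parameter_prior()] giving expectations and scale types.
#' @return Tibble with one row per trial: keys, `lead_s`, `seed` and a
#'   list-column `trace` of raw trial tibbles (`time_ms`, `x` in degrees).
#' @export
simulate_subject <- function(truth, spec = cohort_spec(), subject = 1,
                             conditions = condition_grid(),
                             prior = parameter_prior()) {
  purrr::imap_dfr(conditions, function(cond, cname) {
    cond_idx <- match(cname, names(conditions))
    signs <- condition_signs(cname)
    eff <- truth
    if (spec$param_jitter_sd > 0) {
      jseed <- sub_seed(spec$master_seed, subject, cond_idx, 0L)
      jit <- with_seed(jseed, rnorm(length(eff$baseline), 0,
                                    spec$param_jitter_sd))
      eff$baseline <- eff$baseline + jit
    }
    pars <- condition_parameters(prior, eff, noise_sign = signs["noise"],
                                 speed_sign = signs["speed"])
    # one deterministic pursuit simulation per condition (reused over trials
    # when responses are driven by the carrier)
    carrier_sim <- NULL
    purrr::map_dfr(seq_len(spec$trials_per_condition), function(trial) {
      seed <- sub_seed(spec$master_seed, subject, cond_idx, trial)
      lead_s <- with_seed(seed, runif(1, 1, 3))
      cspec <- replace_lead(cond, lead_s)
      if (spec$respond_to == "stimulus" && cond$motion_noise) {
        tr <- noisy_target(cspec, seed = seed + 1L)
        sim <- simulate_pursuit(pars, tr, engine = spec$engine)
      } else {
        if (is.null(carrier_sim)) {
          smooth_spec <- cspec
          smooth_spec$motion_noise <- FALSE
          smooth_spec$noise_variance <- 0
          carrier_sim <<- simulate_pursuit(pars, smooth_target(smooth_spec),
                                           engine = spec$engine)
        }
        sim <- carrier_sim
      }
      trace <- render_trial(sim, cspec, spec, seed)
      tibble::tibble(subject = subject, condition = cname, trial = trial,
                     lead_s = lead_s, seed = seed, trace = list(trace))
    })
  })
}

# Rescale a simulation to a raw 1 kHz trial in degrees and add artefacts.
render_trial <- function(sim, cspec, spec, seed) {
  h_ms <- sim$engine$tau_ms * sim$engine$step
  lead_ms <- cspec$static_lead * 1000
  total_ms <- lead_ms + cspec$n_cycles * cspec$period * 1000
  dt_ms <- 1000 / cspec$sample_rate
  time_ms <- seq(0, total_ms, by = dt_ms)
  sgn <- start_sign(cspec)
  # linear interpolation of the simulated eye onto the 1 kHz grid
  sim_t <- c(0, sim$states$t_ms)
  sim_eye <- c(sgn, sim$states$eye)
  x <- ifelse(time_ms < lead_ms, sgn,
              stats::approx(sim_t + lead_ms, sim_eye, xout = time_ms,
                            rule = 2)$y)
  x <- x * cspec$amplitude_deg
  n <- length(x)
  with_seed(seed + 2L, {
    if (spec$noise_sd_deg > 0) x <- x + rnorm(n, 0, spec$noise_sd_deg)
    dur_s <- total_ms / 1000
    n_sacc <- rpois(1, spec$saccade_rate_hz * dur_s)
    if (n_sacc > 0) {
      for (k in seq_len(n_sacc)) {
        t0 <- runif(1, 0, total_ms)
        amp <- rexp(1, 1 / spec$saccade_amp_deg) * sample(c(-1, 1), 1)
        idx <- which(time_ms >= t0)
        x[idx] <- x[idx] + amp * exp(-(time_ms[idx] - t0) /
                                       spec$saccade_tau_ms)
      }
    }
    n_blink <- rpois(1, spec$blink_rate_hz * dur_s)
    if (n_blink > 0) {
      for (k in seq_len(n_blink)) {
        t0 <- runif(1, 0, total_ms)
        dur <- runif(1, spec$blink_dur_ms[1], spec$blink_dur_ms[2])
        x[time_ms >= t0 & time_ms < t0 + dur] <- NA_real_
      }
    }
  })
  tibble::tibble(time_ms = time_ms, x = x)
}

#' Write a full synthetic cohort to disk
#'
#' Generates the complete 2 x 2 cohort for all subjects and writes one
#' tab-separated trace file per trial plus a manifest
#' (`manifest.tsv`: subject, condition, trial, lead_s, seed, file) and a
#' ground-truth sidecar `truth.json`.
#'
#' @inheritParams simulate_subject
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
make_dataset <- function(truth, spec = cohort_spec(), dir,
                         conditions = condition_grid(),
                         prior = parameter_prior()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map_dfr(seq_len(spec$n_subjects), function(s) {
    trials <- simulate_subject(truth, spec, s, conditions, prior)
    trials$file <- sprintf("sub%02d_%s_trial%02d.tsv", trials$subject,
                           gsub("[^A-Za-z]", "", trials$condition),
                           trials$trial)
    purrr::pwalk(list(trials$trace, trials$file), function(tr, f) {
      write_trace(tr, file.path(dir, f))
    })
    dplyr::select(trials, -"trace")
  })
  readr::write_tsv(rows, file.path(dir, "manifest.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(baseline = as.list(truth$baseline), noise = as.list(truth$noise),
         speed = as.list(truth$speed),
         cohort = unclass(spec)[setdiff(names(unclass(spec)), "engine")],
         engine = unclass(spec$engine)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(rows)
}

#' Preprocess a synthetic (or real) cohort of trials into grand averages
#'
#' Convenience pipeline: segment every trial into cycles, apply the quality
#' filter, normalise, and grand-average per condition.
#'
#' @param trials Tibble with columns `subject`, `condition`, `trial`,
#'   `lead_s` and a `trace` list-column (as from [simulate_subject()]), or a
#'   directory containing a `manifest.tsv` written by [make_dataset()].
#' @param conditions Condition list, default [condition_grid()].
#' @param n_bins Bins per cycle for the normalised averages.
#' @param ... Passed to [quality_filter()].
#' @return List with `grand_average`, the quality `summary`, and the kept
#'   normalised cycles.
#' @export
preprocess_cohort <- function(trials, conditions = condition_grid(),
                              n_bins = 128, ...) {
  if (is.character(trials)) {
    manifest <- readr::read_tsv(file.path(trials, "manifest.tsv"),
                                show_col_types = FALSE, progress = FALSE)
    manifest$trace <- purrr::map(file.path(trials, manifest$file), read_trace)
    trials <- manifest
  }
  segmented <- purrr::pmap_dfr(
    list(trials$subject, trials$condition, trials$trial, trials$lead_s,
         trials$trace),
    function(s, cond, tr, lead, trace) {
      cyc <- segment_cycles(trace, conditions[[cond]], lead)
      if (nrow(cyc) == 0) return(cyc)
      dplyr::mutate(cyc, subject = s, condition = cond, trial = tr,
                    .before = 1)
    })
  qf <- quality_filter(segmented, ...)
  normalized <- purrr::map_dfr(split(qf$kept, qf$kept$condition),
                               function(df) {
    normalize_cycle(df, conditions[[df$condition[1]]], n_bins = n_bins)
  })
  list(grand_average = grand_average(normalized), summary = qf$summary,
       normalized = normalized)
}

#' Condition signs of the 2 x 2 design
#'
#' Maps a condition label to the (noise, speed) contrast signs: +1 with the
#' manipulation (Noisy, Fast), -1 without (Smooth, Slow).
#'
#' @param condition Condition label like `"Noisy-Fast"`.
#' @return Named numeric vector with elements `noise` and `speed`.
#' @export
condition_signs <- function(condition) {
  c(noise = if (grepl("Noisy", condition)) 1 else -1,
    speed = if (grepl("Fast", condition)) 1 else -1)
}
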