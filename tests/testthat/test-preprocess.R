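# a clean synthetic trial: lead + 3 exact carrier cycles at 1 kHz
clean_trial <- function(spec = condition_spec(period = 2, amplitude_deg = 10,
                                              n_cycles = 3),
                        lead_s = 1.2) {
  total_ms <- lead_s * 1000 + spec$n_cycles * spec$period * 1000
  t <- seq(0, total_ms)
  sgn <- if (spec$start_side == "right") 1 else -1
  x <- ifelse(t < lead_s * 1000, sgn * spec$amplitude_deg,
              sgn * spec$amplitude_deg *
                cos(2 * pi * (t - lead_s * 1000) / (spec$period * 1000)))
  tibble::tibble(time_ms = t, x = x)
}

test_that("trials segment into full carrier-aligned cycles", {
  spec <- condition_spec(period = 2, amplitude_deg = 10, n_cycles = 3)
  seg <- segment_cycles(clean_trial(spec), spec, lead_s = 1.2)
  expect_equal(sort(unique(seg$cycle)), 1:3)
  expect_equal(max(abs(seg$eye_deg - seg$carrier_deg)), 0)
  expect_true(all(seg$phase >= 0 & seg$phase < 1))
  # lead-only trace yields no records, with a warning
  short <- tibble::tibble(time_ms = 0:1500, x = rep(10, 1501))
  expect_warning(out <- segment_cycles(short, spec, lead_s = 1.2),
                 "shorter than one")
  expect_equal(nrow(out), 0)
  # partition identity: segments reproduce the post-lead trace in order
  tr <- clean_trial(spec)
  post <- tr$x[tr$time_ms >= 1200 & tr$time_ms < 1200 + 3 * 2000]
  expect_equal(seg$eye_deg, post[seq_len(nrow(seg))])
})

test_that("quality filter keeps clean cycles and discards damaged ones", {
  spec <- condition_spec(period = 2, amplitude_deg = 10, n_cycles = 3)
  seg <- segment_cycles(clean_trial(spec), spec, lead_s = 1.2)
  seg$trial <- 1L
  qf <- quality_filter(seg)
  expect_equal(nrow(qf$discarded), 0)
  expect_false(any(qf$summary$flagged))

  # corrupt one cycle: large offset (high RMSE) plus a 500 ms gap
  bad <- seg
  sel <- bad$cycle == 2
  bad$eye_deg[sel] <- bad$eye_deg[sel] + 15
  gap <- which(sel)[100:599]
  bad$eye_deg[gap] <- NA
  qf2 <- quality_filter(bad)
  expect_true(2 %in% qf2$discarded$cycle)
  expect_false(2 %in% qf2$kept$cycle)
  expect_equal(attr(qf2$summary, "discard_fraction"), 1 / 3)

  # a cohort with standard artefact rates loses fewer than 10% of cycles
  eng <- engine_config(step = 2, n_embed = 3, compute_variance = FALSE)
  cs <- cohort_spec(n_subjects = 2, trials_per_condition = 2,
                    master_seed = 21, engine = eng)
  trials <- purrr::map_dfr(1:2, function(s)
    simulate_subject(design_effects(), cs, s))
  pp <- preprocess_cohort(trials, n_bins = 32)
  expect_lt(attr(pp$summary, "discard_fraction"), 0.10)
})

test_that("normalisation is exact on the grid and unit-invariant", {
  spec <- condition_spec(period = 2, amplitude_deg = 10, n_cycles = 3)
  seg <- segment_cycles(clean_trial(spec), spec, lead_s = 1.2)
  nz <- normalize_cycle(seg, spec, n_bins = 64)
  # resampling error only (the bin-centre grid never hits phase 0 exactly)
  expect_equal(nz$eye, nz$carrier, tolerance = 1e-4)
  # the carrier extreme itself maps to +/- 1 under the normalisation
  extreme <- seg$eye_deg[which.min(abs(seg$phase))]
  expect_equal(extreme / spec$amplitude_deg, 1)

  # invariance to (linear) measurement units: the same trace in screen mm
  tr_mm <- clean_trial(spec)
  tr_mm$x <- tr_mm$x * 2.64
  spec_mm <- spec
  spec_mm$amplitude_deg <- 10 * 2.64
  seg_mm <- segment_cycles(tr_mm, spec_mm, lead_s = 1.2)
  nz_mm <- normalize_cycle(seg_mm, spec_mm, n_bins = 64)
  expect_equal(nz_mm$eye, nz$eye, tolerance = 1e-10)

  # blink gaps are bridged linearly before resampling
  seg_gap <- seg
  seg_gap$eye_deg[seg_gap$cycle == 1][200:350] <- NA
  nz_gap <- normalize_cycle(seg_gap, spec, n_bins = 64)
  expect_false(anyNA(nz_gap$eye))

  expect_error(normalize_cycle(dplyr::mutate(seg, eye_deg = NA_real_), spec),
               "no valid samples")
})

test_that("grand averaging is a two-stage mean with the error identity", {
  spec <- condition_spec(period = 2, amplitude_deg = 10, n_cycles = 3)
  seg <- segment_cycles(clean_trial(spec), spec, lead_s = 1.2)
  nz <- normalize_cycle(seg, spec, n_bins = 32)
  nz$condition <- "c1"
  # identical cycles average to any one cycle
  ga <- grand_average(nz)
  one <- nz[nz$cycle == 1, ]
  expect_equal(ga$eye, one$eye)
  expect_equal(ga$n_cycles, rep(3, 32))
  # error identity holds exactly
  expect_equal(ga$eye, ga$carrier + ga$error)

  # two subjects with equal and opposite distortions cancel
  nz1 <- dplyr::mutate(nz, subject = 1, eye = .data$eye + 0.1 *
                         sin(2 * pi * .data$phase))
  nz2 <- dplyr::mutate(nz, subject = 2, eye = .data$eye - 0.1 *
                         sin(2 * pi * .data$phase))
  ga2 <- grand_average(dplyr::bind_rows(nz1, nz2))
  # the distortions cancel exactly
  expect_lt(max(abs(ga2$error - ga$error)), 1e-12)
  # equal subject weighting: a subject's cycle count does not bias the mean
  nz3 <- dplyr::bind_rows(nz1, dplyr::filter(nz2, .data$cycle == 1))
  ga3 <- grand_average(nz3)
  expect_lt(max(abs(ga3$error - ga$error)), 1e-12)
})

test_that("preprocessing recovers the generating simulation", {
  eng <- engine_config(step = 2, n_embed = 3, n_bins = 64,
                       compute_variance = FALSE)
  truth <- design_effects()
  cs <- cohort_spec(n_subjects = 2, trials_per_condition = 3,
                    noise_sd_deg = 0.3, saccade_rate_hz = 0,
                    blink_rate_hz = 0, master_seed = 5, engine = eng)
  trials <- purrr::map_dfr(1:2, function(s) simulate_subject(truth, cs, s))
  pp <- preprocess_cohort(trials, n_bins = 64)
  ga <- dplyr::arrange(pp$grand_average, .data$condition, .data$bin)
  pred <- dplyr::arrange(predict_responses(truth, engine = eng),
                         .data$condition, .data$bin)
  ga$condition <- factor(ga$condition, levels = levels(pred$condition))
  ga <- dplyr::arrange(ga, .data$condition, .data$bin)
  resid <- ga$error - pred$error
  # injected noise 0.3 deg over 18 cycles/condition: the averaged residual
  # must sit near the Monte-Carlo floor
  floor_sd <- 0.3 / 14.4 / sqrt(18)
  expect_lt(sqrt(mean(resid^2)), 3 * floor_sd)
})

test_that("residual pursuit velocity averages late occlusion sans saccades", {
  # constant-velocity segment at 5 deg/s with two known occlusion windows
  t <- 0:4000
  trace <- tibble::tibble(time_ms = t, x = 5 * t / 1000)
  spec <- condition_spec(period = 4, amplitude_deg = 14.4, n_cycles = 1)
  win <- tibble::tibble(t_start = c(500, 2500), t_end = c(1500, 3500))
  rv <- residual_pursuit_velocity(trace, spec, windows = win)
  expect_equal(nrow(rv), 2)
  expect_equal(rv$velocity, c(5, 5), tolerance = 1e-6)

  # a 40 deg/s saccadic excursion inside the window is excluded
  tr2 <- trace
  sel <- t >= 1100 & t < 1200
  tr2$x[t >= 1200] <- tr2$x[t >= 1200] + 3.5 # 35 deg net over 100 ms
  tr2$x[sel] <- 5 * t[sel] / 1000 + 35 * (t[sel] - 1100) / 1000
  rv2 <- residual_pursuit_velocity(tr2, spec, windows = win)
  expect_equal(rv2$velocity[1], 5, tolerance = 0.05)
  # no retained sample may exceed the threshold: re-derive the mask
  expect_true(all(abs(rv2$velocity) <= 35, na.rm = TRUE))
  # fully masked window reports a missing value
  tr3 <- trace
  tr3$x <- 40 * t / 1000
  rv3 <- residual_pursuit_velocity(tr3, spec, windows = win)
  expect_true(all(is.na(rv3$velocity)))
})

test_that("grand averages round-trip through delimited text", {
  spec <- condition_spec(period = 2, amplitude_deg = 10, n_cycles = 3)
  seg <- segment_cycles(clean_trial(spec), spec, lead_s = 1.2)
  nz <- normalize_cycle(seg, spec, n_bins = 16)
  nz$condition <- "c1"
  ga <- grand_average(nz)
  f <- tempfile(fileext = ".tsv")
  write_grand_average(ga, f, meta = list(n_bins = 16))
  expect_true(file.exists(paste0(f, ".json")))
  ga2 <- read_grand_average(f)
  expect_equal(as.data.frame(ga2), as.data.frame(ga), tolerance = 1e-9)
})
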