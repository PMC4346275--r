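test_that("smooth target starts at the trial extreme and keeps its period", {
  spec <- condition_spec(period = 4.173, n_cycles = 3, static_lead = 1.5)
  tr <- smooth_target(spec)
  onset <- tr$position[tr$time_ms >= 1500][1]
  expect_equal(onset, 1)
  half <- which.min(abs(tr$time_ms - (1500 + 4173 / 2)))
  expect_equal(tr$position[half], -1, tolerance = 1e-5)
  expect_equal(peak_target_speed(spec), 2 * pi * 14.4 / 4.173)
  # left-start trials are the mirror image
  trl <- smooth_target(condition_spec(start_side = "left", static_lead = 1.5))
  expect_equal(trl$position[trl$time_ms >= 1500][1], -1)
})

test_that("noisy target adds a reproducible phase random walk", {
  spec <- condition_spec(motion_noise = TRUE, n_cycles = 3)
  expect_error(noisy_target(spec), "seed")
  t1 <- noisy_target(spec, seed = 42)
  t2 <- noisy_target(spec, seed = 42)
  expect_identical(t1$position, t2$position)
  t3 <- noisy_target(spec, seed = 43)
  expect_false(identical(t1$position, t3$position))
  # zero variance degenerates to the smooth trajectory
  s0 <- condition_spec(motion_noise = TRUE, noise_variance = 0)
  sm <- condition_spec(motion_noise = FALSE, static_lead = s0$static_lead)
  expect_equal(noisy_target(s0, seed = 1)$position,
               smooth_target(sm)$position)
  # underlying period unchanged: the phase-aligned sinusoid fitted to the
  # noisy trace recovers the configured period to < 1%
  fit_period <- function(trace, spec) {
    mv <- trace$time_ms >= spec$static_lead * 1000
    t <- trace$time_ms[mv] - spec$static_lead * 1000
    y <- trace$position[mv]
    sse <- function(T) {
      X <- cbind(cos(2 * pi * t / T), sin(2 * pi * t / T))
      sum(stats::lm.fit(X, y)$residuals^2)
    }
    stats::optimise(sse, c(3500, 5000))$minimum
  }
  expect_lt(abs(fit_period(t1, spec) - 4173) / 4173, 0.01)
})

test_that("phase-walk increments have the configured variance", {
  # recover phi(t) from the noiseless arccos branch on monotone segments
  spec <- condition_spec(motion_noise = TRUE, n_cycles = 3, static_lead = 1)
  tr <- noisy_target(spec, seed = 7)
  f <- 1 / (spec$period * 1000)
  t <- tr$time_ms - 1000
  inc <- c()
  for (cyc in 0:2) {
    seg <- which(t > cyc * spec$period * 1000 + 300 &
                   t < cyc * spec$period * 1000 + spec$period * 400)
    ph <- acos(pmin(pmax(tr$position[seg], -1), 1)) / (2 * pi * f) - t[seg]
    inc <- c(inc, diff(ph))
  }
  expect_equal(var(inc), exp(-0.5), tolerance = 0.15)
})

test_that("occlusion windows match the printed durations and geometry", {
  fast <- smooth_target(condition_spec(period = 4.173, n_cycles = 3))
  wf <- occlusion_windows(fast)
  expect_equal(nrow(wf), 6) # two per cycle
  expect_equal(wf$duration_ms,
               rep((pi / 2 - acos(0.8)) / (2 * pi) * 4173, 6),
               tolerance = 1e-3)
  slow <- smooth_target(condition_spec(period = 5.1, n_cycles = 1))
  ws <- occlusion_windows(slow)
  expect_equal(ws$duration_ms, rep((pi / 2 - acos(0.8)) / (2 * pi) * 5100, 2),
               tolerance = 1e-3)
  # disjoint and strictly inside each half-cycle
  expect_true(all(diff(as.vector(rbind(wf$t_start, wf$t_end))) > 0))
  lead_ms <- attr(fast, "spec")$static_lead * 1000
  half <- 4173 / 2
  half_idx <- floor((wf$t_start - lead_ms) / half)
  expect_equal(half_idx, floor((wf$t_end - lead_ms) / half))
  # degenerate zero-width window
  z <- occlusion_windows(fast, occluder_geometry(-1e-9, 0, 0))
  expect_true(all(z$duration_ms < 2))
})

test_that("occluded path fraction scales with the window and path", {
  expect_equal(occluded_path_fraction(occluder_geometry(0, 0.8), 28.8),
               list(fraction = 0.4, degrees = 11.52))
  expect_equal(occluded_path_fraction(occluder_geometry(-1, 1), 30)$fraction,
               1)
  expect_equal(occluded_path_fraction(occluder_geometry(0, 0.4), 28.8),
               list(fraction = 0.2, degrees = 5.76))
})

test_that("the condition grid spans the 2 x 2 design", {
  grid <- condition_grid()
  expect_length(grid, 4)
  expect_equal(grid[["Smooth-Fast"]]$period, 4.173)
  expect_equal(grid[["Noisy-Slow"]]$period, 5.1)
  expect_equal(grid[["Noisy-Fast"]]$noise_variance, exp(-0.5))
  expect_equal(grid[["Smooth-Slow"]]$noise_variance, 0)
  expect_true(all(vapply(grid, function(g) g$amplitude_deg, 1) == 14.4))
})

test_that("target traces round-trip with their condition sidecar", {
  tr <- smooth_target(condition_spec(period = 2, n_cycles = 1))
  f <- tempfile(fileext = ".tsv")
  write_target_trace(tr, f)
  tr2 <- read_target_trace(f)
  expect_equal(tr2$position, tr$position, tolerance = 1e-12)
  expect_equal(attr(tr2, "spec")$period, 2)
  expect_equal(attr(tr2, "geom")$lower, attr(tr, "geom")$lower)
  # a re-read trace still drives the paradigm analytics
  expect_equal(nrow(occlusion_windows(tr2)), 2)
})
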