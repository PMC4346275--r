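#' Simulate Bayes-optimal pursuit of a (partially occluded) target
#'
#' Runs closed-loop active inference: the subjective model filters sensory
#' input in generalised coordinates while action drives the oculomotor plant
#' to fulfil proprioceptive predictions. The static lead of the trace is
#' dropped; integration starts at motion onset with the eye fixating the
#' target. The target position seen by the sensory channels is the trace
#' position averaged within each integration bin (which is also how subjects
#' were instructed to treat phase-noise flicker).
#'
#' @param p A [full_parameter_set()].
#' @param trace A `target_trace` from [smooth_target()] / [noisy_target()].
#' @param geom Stimulus occluder (hard window); defaults to the trace's.
#' @param engine An [engine_config()].
#' @param sg A [sensory_geometry()].
#' @param backend `"cpp"` (fast path) or `"r"` (reference implementation).
#' @return Object of class `pursuit_sim`: list with a per-bin `states` tibble
#'   (realised eye, target, action, conditional expectations and variances),
#'   matrices `pred`/`err` of order-0 sensory predictions and errors, and the
#'   configuration used.
#' @examples
#' \donttest{
#' sim <- simulate_pursuit(trace = smooth_target(condition_spec(n_cycles = 1)))
#' head(position_error(sim))
#' }
#' @export
simulate_pursuit <- function(p = full_parameter_set(),
                             trace = smooth_target(),
                             geom = attr(trace, "geom"),
                             engine = engine_config(),
                             sg = sensory_geometry(),
                             backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  spec <- attr(trace, "spec")
  binned <- bin_trace(trace, spec, engine)
  simulate_pursuit_binned(p, binned, spec, geom, engine, sg, backend)
}

# Bin-average the moving part of a trace onto the integration grid and
# compute the target velocity (units per tau) for the generalised input.
bin_trace <- function(trace, spec, engine) {
  h_ms <- engine$tau_ms * engine$step
  n_steps <- round(spec$n_cycles * spec$period * 1000 / h_ms)
  mv <- trace$time_ms >= spec$static_lead * 1000
  t_rel <- trace$time_ms[mv] - spec$static_lead * 1000
  idx <- pmin(pmax(ceiling(t_rel / h_ms), 1), n_steps)
  targ <- as.numeric(tapply(trace$position[mv], idx, mean))
  carr <- as.numeric(tapply(trace$carrier[mv], idx, mean))
  stopifnot(length(targ) == n_steps)
  targ_vel <- c(diff(targ)[1], diff(targ)) / engine$step
  if (n_steps > 2) {
    targ_vel[2:(n_steps - 1)] <-
      (targ[3:n_steps] - targ[1:(n_steps - 2)]) / (2 * engine$step)
  }
  list(targ = targ, carr = carr, targ_vel = targ_vel, n_steps = n_steps)
}

simulate_pursuit_binned <- function(p, binned, spec, geom, engine, sg,
                                    backend = "cpp") {
  sgn <- start_sign(spec)
  h_ms <- engine$tau_ms * engine$step
  cycle_tau <- spec$period * 1000 / engine$tau_ms
  n_steps <- binned$n_steps
  targ <- binned$targ
  carr <- binned$carr
  targ_vel <- binned$targ_vel

  geom_model <- occluder_geometry(geom$lower, geom$upper,
                                  engine$model_softness)
  model <- pursuit_gf_model(p, geom_model, sg, sgn, cycle_tau,
                            x_init = targ[1])

  if (backend == "cpp") {
    res <- pursuit_filter_cpp(
      theta = unlist(p$kinetic), amp = p$prior_beliefs$amplitude,
      phase = p$prior_beliefs$phase_lead,
      lnPi = c(p$precisions$log_prec_sensory, p$precisions$log_prec_states,
               p$precisions$log_prec_cause),
      sgn = sgn, x_init = targ[1], target = targ, target_vel = targ_vel,
      cycle_tau = cycle_tau, h = engine$step,
      n = engine$n_embed, d = engine$d_embed, smoothness = engine$smoothness,
      soft_model = engine$model_softness, soft_stim = engine$stim_softness,
      occ_lower = geom$lower, occ_upper = geom$upper,
      r_centres = sg$channel_centres, field_width = sg$field_width,
      action_on = engine$action, want_var = engine$compute_variance)
  } else {
    geom_stim <- occluder_geometry(geom$lower, geom$upper,
                                   engine$stim_softness)
    proc <- pursuit_process(targ, targ_vel, geom_stim, sg, engine)
    res <- gf_filter(model, n_steps, engine, process = proc)
  }

  states <- tibble::tibble(
    bin = seq_len(n_steps),
    t_ms = seq_len(n_steps) * h_ms,
    cycle = floor((seq_len(n_steps) - 0.5) * h_ms / (spec$period * 1000)) + 1,
    phase = ((seq_len(n_steps) - 0.5) * h_ms / (spec$period * 1000)) %% 1,
    target = targ, carrier = carr,
    eye = as.numeric(res$eye), eye_vel = as.numeric(res$eye_vel),
    action = as.numeric(res$action),
    mu_eye = res$mu_x[, 1], mu_eye_vel = res$mu_x[, 2],
    mu_target = res$mu_x[, 3], mu_target_vel = res$mu_x[, 4],
    mu_cause = res$mu_v[, 1],
    var_eye = res$var_x[, 1], var_target = res$var_x[, 3],
    var_cause = res$var_v[, 1],
    occluded = occluder_visibility(carr, occluder_geometry(
      geom$lower, geom$upper, 0)) < 0.5)
  structure(list(states = states, pred = res$pred, err = res$err,
                 params = p, spec = spec, geom = geom, engine = engine),
            class = "pursuit_sim")
}

# Oculomotor process for the R engine backend: linear plant flow plus
# analytic construction of the generalised sensory sample from the plant and
# the (bin-averaged, hard-occluded) stimulus. Generative-process fluctuations
# are suppressed; visual orders above the first are truncated to zero.
pursuit_process <- function(targ, targ_vel, geom_stim, sg, engine) {
  ns <- length(sg$channel_centres) + 1
  n <- engine$n_embed
  h <- engine$step
  n_steps <- length(targ)
  list(
    pstate0 = c(targ[1], 0),
    flow = function(pstate, a) c(pstate[2], a - pstate[2]),
    s_gen = function(pstate, a, t_tau) {
      i <- max(1, min(n_steps, round(t_tau / h)))
      xt <- targ[i]
      xtv <- targ_vel[i]
      o <- occluder_visibility(xt, geom_stim)
      z <- (sg$channel_centres + pstate[1] - xt) / sg$field_width
      e <- exp(-z^2)
      s <- matrix(0, ns, n)
      s[1, 1] <- pstate[1]
      s[1, 2] <- pstate[2]
      # higher proprio orders follow the plant recursion with a-dot ~ 0:
      # order o >= 2 is (-1)^o (a - velocity)
      if (n >= 3) for (oo in 2:(n - 1))
        s[1, oo + 1] <- (-1)^oo * (a - pstate[2])
      s[-1, 1] <- o * e
      s[-1, 2] <- o * e * (-2 * z / sg$field_width) * (pstate[2] - xtv)
      s
    }
  )
}

#' Position error of a simulation
#'
#' Eye position minus the noiseless target carrier, per integration bin.
#' Positive error means the eye is to the right of (ahead of a leftward-bound,
#' behind a rightward-bound) target.
#'
#' @param sim A `pursuit_sim` from [simulate_pursuit()].
#' @return Tibble with `bin`, `t_ms`, `phase`, `cycle`, `error` and
#'   `occluded`.
#' @export
position_error <- function(sim) {
  stopifnot(inherits(sim, "pursuit_sim"))
  dplyr::transmute(sim$states, bin = .data$bin, t_ms = .data$t_ms,
                   phase = .data$phase, cycle = .data$cycle,
                   error = .data$eye - .data$carrier,
                   occluded = .data$occluded)
}

#' Average single-cycle position error on a comparison grid
#'
#' Resamples eye and carrier onto `n_bins` phase bins per cycle (bin centres
#' at (k - 1/2) / n_bins) by linear interpolation and averages across the
#' simulated cycles — the model-side analogue of the grand-average data
#' feature.
#'
#' @param sim A `pursuit_sim`.
#' @param n_bins Bins per cycle; defaults to the engine's `n_bins`.
#' @param cycles Which cycles to include (default all full cycles).
#' @return Tibble with `bin`, `phase`, `eye`, `carrier`, `error`.
#' @export
average_cycle_error <- function(sim, n_bins = sim$engine$n_bins,
                                cycles = NULL) {
  st <- sim$states
  cycles <- cycles %||% unique(st$cycle)
  grid <- (seq_len(n_bins) - 0.5) / n_bins
  period_ms <- sim$spec$period * 1000
  per_cycle <- sapply(cycles, function(cy) {
    s <- st[st$cycle == cy, ]
    # recorded values sit at the end of each integration bin
    x <- s$t_ms / period_ms - (cy - 1)
    stats::approx(x, s$eye, xout = grid, rule = 2)$y
  })
  eye <- rowMeans(per_cycle)
  carrier <- start_sign(sim$spec) * cos(2 * pi * grid)
  tibble::tibble(bin = seq_len(n_bins), phase = grid, eye = eye,
                 carrier = carrier, error = eye - carrier)
}
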