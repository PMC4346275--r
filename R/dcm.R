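#' Prior density over the subjective model's parameters
#'
#' One row per parameter: the prior expectation, its class, how latent
#' deviations are applied (`additive` for the kinetic couplings theta1..6,
#' `log_scaling` for the nonnegative prior-belief parameters theta7/theta8,
#' `log_precision` for the log precisions, whose deviations add on the log
#' scale), and the prior variance of the latent deviation (one half for
#' every parameter).
#'
#' @param deviation_var Prior variance of each latent deviation.
#' @return Tibble with columns `param`, `class`, `expectation`,
#'   `scale_type`, `deviation_var`.
#' @export
parameter_prior <- function(deviation_var = 1 / 2) {
  tibble::tibble(
    param = param_names(),
    class = c(rep("kinetic", 6), rep("prior_belief", 2),
              rep("precision", 3)),
    expectation = c(1 / 4, 1 / 2, 1 / 2, 1 / 32, 1 / 32, 1 / 4,
                    1, 2 * pi / 32, 4, 4, 4),
    scale_type = c(rep("additive", 6), rep("log_scaling", 2),
                   rep("log_precision", 3)),
    deviation_var = deviation_var)
}

#' Condition-effect design: baseline and factor deviations
#'
#' Latent deviations of every parameter from its prior expectation: a
#' baseline deviation plus deviations applied with the sign of each
#' experimental factor (motion noise, speed). The viscosity parameters
#' (theta2, theta6) are fixed across conditions: their factor deviations are
#' masked to exactly zero.
#'
#' @param baseline,noise,speed Named numeric vectors over [param_names()]
#'   (missing entries are 0).
#' @param mask Optional effect mask from [effect_mask()].
#' @return Object of class `design_effects` with full named vectors.
#' @export
design_effects <- function(baseline = NULL, noise = NULL, speed = NULL,
                           mask = effect_mask()) {
  fill <- function(x) {
    out <- stats::setNames(rep(0, 11), param_names())
    if (!is.null(x)) out[names(x)] <- x
    out
  }
  out <- list(baseline = fill(baseline), noise = fill(noise),
              speed = fill(speed))
  out$noise[!mask$noise] <- 0
  out$speed[!mask$speed] <- 0
  structure(c(out, list(mask = mask)), class = "design_effects")
}

#' Which parameters may carry baseline / condition effects
#'
#' Baseline deviations are free for every parameter; condition (noise and
#' speed) effects are free for all parameters except the viscosities
#' theta2 and theta6.
#'
#' @return Tibble with logical columns `baseline`, `noise`, `speed` per
#'   parameter.
#' @export
effect_mask <- function() {
  visc <- param_names() %in% c("theta2", "theta6")
  tibble::tibble(param = param_names(), baseline = TRUE,
                 noise = !visc, speed = !visc)
}

#' Compose condition-specific parameters
#'
#' Applies baseline and signed factor deviations to the prior expectations:
#' additively for kinetic parameters, multiplicatively through `exp()` for
#' the log-scaled prior-belief parameters, and additively on the log scale
#' for the log precisions. For example, with prior expectation 0.5, baseline
#' -0.21 and a noise effect of -0.34, theta3 is 0.5 - 0.21 - (-0.34) = 0.63
#' without the noise manipulation and 0.5 - 0.21 + (-0.34) = -0.05 with it.
#'
#' @param prior A [parameter_prior()].
#' @param eff A [design_effects()].
#' @param noise_sign,speed_sign +1 with the manipulation (Noisy / Fast),
#'   -1 without (Smooth / Slow).
#' @return A [full_parameter_set()] for that condition.
#' @export
condition_parameters <- function(prior = parameter_prior(),
                                 eff = design_effects(),
                                 noise_sign = -1, speed_sign = -1) {
  stopifnot(noise_sign %in% c(-1, 1), speed_sign %in% c(-1, 1))
  dev <- eff$baseline + noise_sign * eff$noise + speed_sign * eff$speed
  val <- stats::setNames(numeric(11), param_names())
  for (i in seq_len(11)) {
    e <- prior$expectation[i]
    val[i] <- switch(prior$scale_type[i],
                     additive = e + dev[i],
                     log_scaling = e * exp(dev[i]),
                     log_precision = e + dev[i],
                     stop("unknown scale_type"))
  }
  param_set_from_vector(val)
}

#' Per-condition parameter table
#'
#' Tabulates the composed parameters of all four conditions, including the
#' natural-scale precisions `exp(lnPi)`.
#'
#' @inheritParams condition_parameters
#' @param conditions Condition labels, canonical order.
#' @return Tibble with `condition`, `param`, `value` and (for precisions)
#'   `precision`.
#' @export
condition_parameter_table <- function(prior = parameter_prior(),
                                      eff = design_effects(),
                                      conditions = c("Smooth-Slow",
                                                     "Smooth-Fast",
                                                     "Noisy-Slow",
                                                     "Noisy-Fast")) {
  purrr::map_dfr(conditions, function(cn) {
    s <- condition_signs(cn)
    v <- as_param_vector(condition_parameters(prior, eff, s["noise"],
                                              s["speed"]))
    tibble::tibble(condition = cn, param = names(v), value = as.numeric(v),
                   precision = ifelse(grepl("^lnPi", names(v)),
                                      exp(as.numeric(v)), NA_real_))
  })
}

#' Predicted grand-average position errors of the 2 x 2 design
#'
#' For each condition (canonical order Smooth-Slow, Smooth-Fast, Noisy-Slow,
#' Noisy-Fast), simulates Bayes-optimal pursuit of the noiseless carrier
#' under the condition's composed parameters and returns the cycle-averaged
#' position error on the comparison grid. The average response to noisy
#' trajectories is modelled deterministically, so the carrier is used in all
#' conditions.
#'
#' @param eff A [design_effects()].
#' @param conditions Condition list from [condition_grid()].
#' @param prior A [parameter_prior()].
#' @param engine An [engine_config()]; its `n_bins` sets the grid.
#' @param cache Optional environment reusing the binned carrier stimuli
#'   across repeated calls (used heavily inside [fit_pursuit_dcm()]).
#' @return Tibble with `condition` (ordered factor), `bin`, `phase`,
#'   `error`.
#' @export
predict_responses <- function(eff = design_effects(),
                              conditions = condition_grid(),
                              prior = parameter_prior(),
                              engine = engine_config(),
                              cache = NULL) {
  purrr::imap_dfr(conditions, function(cond, cname) {
    s <- condition_signs(cname)
    pars <- condition_parameters(prior, eff, s["noise"], s["speed"])
    cspec <- cond
    cspec$motion_noise <- FALSE
    cspec$noise_variance <- 0
    key <- paste0("c_", gsub("[^A-Za-z]", "", cname))
    pre <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]] else {
      tr <- smooth_target(cspec)
      val <- list(binned = bin_trace(tr, cspec, engine),
                  spec = cspec, geom = attr(tr, "geom"))
      if (!is.null(cache)) cache[[key]] <- val
      val
    }
    sim <- simulate_pursuit_binned(pars, pre$binned, pre$spec, pre$geom,
                                   engine, sensory_geometry())
    ace <- average_cycle_error(sim, n_bins = engine$n_bins)
    tibble::tibble(condition = cname, bin = ace$bin, phase = ace$phase,
                   error = ace$error)
  }) |>
    dplyr::mutate(condition = factor(.data$condition,
                                     levels = names(conditions)))
}

# latent parameterisation: named vector of free deviations <-> design_effects
latent_names <- function(mask = effect_mask()) {
  c(paste0("baseline.", mask$param[mask$baseline]),
    paste0("noise.", mask$param[mask$noise]),
    paste0("speed.", mask$param[mask$speed]))
}

latent_to_effects <- function(latent, mask = effect_mask()) {
  nm <- latent_names(mask)
  stopifnot(length(latent) == length(nm))
  latent <- stats::setNames(as.numeric(latent), nm)
  pick <- function(prefix) {
    sel <- startsWith(nm, paste0(prefix, "."))
    stats::setNames(latent[sel], sub(paste0(prefix, "\\."), "", nm[sel]))
  }
  design_effects(baseline = pick("baseline"), noise = pick("noise"),
                 speed = pick("speed"), mask = mask)
}

#' Invert the pursuit model on grand-averaged position errors
#'
#' Meta-Bayesian inversion: fits the active-inference forward model jointly
#' to the four conditions' grand-averaged position errors by
#' [variational_laplace()], estimating baseline deviations of every
#' parameter together with motion-noise and speed effects (excluding the
#' viscosities), plus one observation-noise log precision per condition.
#' Latent deviations have prior mean 0 and variance one half.
#'
#' @param data A `grand_average` tibble covering the four conditions (columns
#'   `condition`, `bin`, `error`).
#' @param prior A [parameter_prior()].
#' @param mask An [effect_mask()].
#' @param conditions Condition list matching the data's design.
#' @param engine An [engine_config()]; `n_bins` must match the data grid.
#' @param ... Passed to [variational_laplace()].
#' @return Object of class `pursuit_dcm` (a `vl_fit` plus metadata):
#'   posterior over the latent deviations, free energy, per-condition noise
#'   precisions, and accessors via [tidy()], [glance()],
#'   [condition_parameter_table()].
#' @export
fit_pursuit_dcm <- function(data, prior = parameter_prior(),
                            mask = effect_mask(),
                            conditions = condition_grid(),
                            engine = engine_config(n_bins = 64), ...) {
  stopifnot(all(c("condition", "bin", "error") %in% names(data)))
  data <- dplyr::arrange(
    dplyr::mutate(data, condition = factor(.data$condition,
                                           levels = names(conditions))),
    .data$condition, .data$bin)
  nb <- max(data$bin)
  stopifnot(nb == engine$n_bins, nrow(data) == 4 * nb)
  y <- data$error
  groups <- as.integer(data$condition)
  nm <- latent_names(mask)
  p <- length(nm)
  prior_mean <- stats::setNames(rep(0, p), nm)
  pvar <- prior$deviation_var[match(sub("^[a-z]+\\.", "", nm), prior$param)]
  prior_cov <- diag(pvar, p)
  cache <- new.env(parent = emptyenv())
  forward <- function(latent) {
    eff <- latent_to_effects(latent, mask)
    predict_responses(eff, conditions, prior, engine, cache = cache)$error
  }
  fit <- variational_laplace(y, forward, prior_mean, prior_cov,
                             groups = groups, ...)
  fit$mean <- stats::setNames(fit$mean, nm)
  fit$latent_names <- nm
  fit$mask <- mask
  fit$param_prior <- prior
  fit$conditions <- names(conditions)
  fit$engine <- engine
  fit$data <- data
  class(fit) <- c("pursuit_dcm", class(fit))
  fit
}

#' @export
print.pursuit_dcm <- function(x, ...) {
  cat("Pursuit DCM (variational Laplace)\n")
  cat(sprintf("  free energy: %.2f after %d iterations (%s)\n", x$F,
              x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  noise log precisions: %s\n",
              paste(sprintf("%.2f", x$lambda), collapse = ", ")))
  cat(sprintf("  latent deviations: %d\n", length(x$mean)))
  invisible(x)
}

#' @export
tidy.pursuit_dcm <- function(x, conf.level = 0.9, ...) {
  out <- tidy.vl_fit(x, conf.level = conf.level)
  out$term <- x$latent_names
  tidyr::separate_wider_delim(out, "term", delim = ".",
                              names = c("effect", "param"))
}

#' @export
glance.pursuit_dcm <- function(x, ...) {
  tibble::tibble(F = x$F, iterations = x$iterations,
                 converged = x$converged, n_latent = length(x$mean))
}

#' Posterior design effects of a fitted DCM
#'
#' @param fit A `pursuit_dcm`.
#' @return A [design_effects()] at the posterior mean.
#' @export
posterior_effects <- function(fit) {
  latent_to_effects(fit$mean, fit$mask)
}
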