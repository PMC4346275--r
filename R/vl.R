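#' Variational Laplace (Gauss-Newton / Levenberg-Marquardt) model inversion
#'
#' Fits the nonlinear regression `y = forward(theta) + e` with Gaussian prior
#' `theta ~ N(prior_mean, prior_cov)` and Gaussian observation noise whose
#' log precision is one hyperparameter per noise group, by free-energy ascent:
#' damped Gauss-Newton steps on the parameters (a step is accepted only if
#' the Laplace free energy F increases, otherwise damping escalates) with
#' interleaved Newton updates of the noise hyperparameters. F is an
#' approximation to the log model evidence; with `fixed_noise_logprec` set
#' and a linear forward model it is exact.
#'
#' @param y Numeric data vector.
#' @param forward Function mapping a parameter vector to predictions of `y`.
#' @param prior_mean,prior_cov Prior density over parameters.
#' @param groups Integer/factor of `length(y)`: one noise precision per group.
#' @param fixed_noise_logprec Optional numeric (scalar or one per group): fix
#'   the noise log precisions instead of estimating them.
#' @param hyper_mean,hyper_var Gaussian hyperprior on each noise log
#'   precision.
#' @param max_iter Maximum Gauss-Newton iterations.
#' @param tol Convergence: |dF| below `tol` for `tol_count` consecutive
#'   accepted steps.
#' @param tol_count See `tol`.
#' @param fd_step Finite-difference step for the Jacobian.
#' @param verbose Print per-iteration free energy.
#' @return Object of class `vl_fit`: posterior `mean` and `cov`, free energy
#'   `F` (with per-iteration `F_history` and per-accepted-step gains
#'   `F_gain`), noise log precisions `lambda`, convergence info, and the
#'   prior.
#' @export
variational_laplace <- function(y, forward, prior_mean, prior_cov,
                                groups = rep(1L, length(y)),
                                fixed_noise_logprec = NULL,
                                hyper_mean = 2, hyper_var = 16,
                                max_iter = 64, tol = 1e-2, tol_count = 4,
                                fd_step = 1e-3, verbose = FALSE) {
  p <- length(prior_mean)
  groups <- as.integer(factor(groups))
  ng <- max(groups)
  n_g <- tabulate(groups, ng)
  P0 <- solve(prior_cov)
  ldC0 <- determinant(as.matrix(prior_cov), logarithm = TRUE)$modulus

  fixed <- !is.null(fixed_noise_logprec)
  lambda <- if (fixed) rep(fixed_noise_logprec, length.out = ng)
            else rep(hyper_mean, ng)

  theta <- as.numeric(prior_mean)
  fx <- forward(theta)
  stopifnot(length(fx) == length(y))

  free_energy <- function(r, lambda, theta, H) {
    piy <- exp(lambda)[groups]
    Fe <- -0.5 * sum(piy * r^2) + 0.5 * sum(n_g * lambda) -
      0.5 * length(y) * log(2 * pi) -
      0.5 * as.numeric(t(theta - prior_mean) %*% P0 %*% (theta - prior_mean)) -
      0.5 * as.numeric(ldC0) -
      0.5 * as.numeric(determinant(H, logarithm = TRUE)$modulus)
    if (!fixed)
      Fe <- Fe - 0.5 * sum((lambda - hyper_mean)^2) / hyper_var
    Fe
  }

  gn_hessian <- function(J, lambda) {
    piy <- exp(lambda)[groups]
    crossprod(J * piy, J) + P0
  }

  J <- NULL
  nu <- 1e-4 # LM damping
  F_cur <- -Inf
  F_hist <- numeric(0)
  F_gain <- numeric(0) # free-energy increase of each accepted step
  still <- 0L
  converged <- FALSE
  it <- 0L

  while (it < max_iter) {
    it <- it + 1L
    # one-sided finite-difference Jacobian about the current estimate
    J <- matrix(0, length(y), p)
    for (j in seq_len(p)) {
      tp <- theta
      tp[j] <- tp[j] + fd_step
      J[, j] <- (forward(tp) - fx) / fd_step
    }
    r <- y - fx

    # hyperparameter (noise precision) updates: closed-form maximiser of the
    # likelihood part, then clamped Newton refinement for the hyperprior
    if (!fixed) {
      H <- gn_hessian(J, lambda)
      Sig <- solve(H)
      for (g in seq_len(ng)) {
        sel <- groups == g
        tr_term <- sum((J[sel, , drop = FALSE] %*% Sig) *
                         J[sel, , drop = FALSE])
        e2 <- sum(r[sel]^2) + tr_term
        lambda[g] <- log(n_g[g] / max(e2, 1e-12))
        for (rep in 1:3) {
          dF <- 0.5 * (n_g[g] - exp(lambda[g]) * e2) -
            (lambda[g] - hyper_mean) / hyper_var
          ddF <- -0.5 * exp(lambda[g]) * e2 - 1 / hyper_var
          step <- max(min(-dF / ddF, 1), -1)
          lambda[g] <- lambda[g] + step
        }
      }
    }

    H <- gn_hessian(J, lambda)
    piy <- exp(lambda)[groups]
    g_vec <- crossprod(J, piy * r) - P0 %*% (theta - prior_mean)
    F_cur <- free_energy(r, lambda, theta, H)

    accepted <- FALSE
    best_Fnew <- -Inf
    for (try in 1:8) {
      Hd <- H + nu * diag(diag(H), p)
      dth <- tryCatch(solve(Hd, g_vec), error = function(e) NULL)
      if (is.null(dth)) { nu <- nu * 8; next }
      th_new <- theta + as.numeric(dth)
      fx_new <- tryCatch(forward(th_new), error = function(e) NULL)
      if (is.null(fx_new) || any(!is.finite(fx_new))) { nu <- nu * 8; next }
      F_new <- free_energy(y - fx_new, lambda, th_new, H)
      best_Fnew <- max(best_Fnew, F_new)
      if (F_new > F_cur - 1e-12) {
        theta <- th_new
        fx <- fx_new
        dF_step <- F_new - F_cur
        F_gain <- c(F_gain, dF_step)
        F_cur <- F_new
        nu <- max(nu / 4, 1e-8)
        accepted <- TRUE
        break
      }
      nu <- nu * 8
    }
    F_hist <- c(F_hist, F_cur)
    if (verbose) message(sprintf("iter %2d  F = %.6f  nu = %.1e", it, F_cur,
                                 nu))
    if (accepted && abs(dF_step) < tol) still <- still + 1L else still <- 0L
    if (still >= tol_count) { converged <- TRUE; break }
    if (!accepted) {
      # no uphill step: converged if nothing better exists within tolerance,
      # otherwise return the best iterate flagged as unconverged
      if (is.finite(best_Fnew) && abs(best_Fnew - F_cur) < tol)
        converged <- TRUE
      break
    }
  }

  H <- gn_hessian(J, lambda)
  structure(list(mean = as.numeric(theta), cov = solve(H), F = F_cur,
                 lambda = lambda, groups = groups, iterations = it,
                 converged = converged, F_history = F_hist, F_gain = F_gain,
                 prior_mean = as.numeric(prior_mean),
                 prior_cov = as.matrix(prior_cov),
                 residuals = y - fx, fitted = fx),
            class = "vl_fit")
}

#' Gaussian marginal credible intervals of a fitted posterior
#'
#' @param fit A `vl_fit` (or any list with `mean` and `cov`).
#' @param level Credible level (default 0.9, i.e. halfwidth 1.645 sd).
#' @param names Optional parameter names.
#' @return Tibble with `param`, `mean`, `sd`, `lower`, `upper`.
#' @export
credible_intervals <- function(fit, level = 0.9, names = NULL) {
  sd <- sqrt(pmax(diag(as.matrix(fit$cov)), 0))
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    param = names %||% (names(fit$mean) %||%
                          paste0("theta", seq_along(fit$mean))),
    mean = as.numeric(fit$mean), sd = sd,
    lower = fit$mean - z * sd, upper = fit$mean + z * sd)
}

#' @export
tidy.vl_fit <- function(x, conf.level = 0.9, ...) {
  ci <- credible_intervals(x, level = conf.level)
  dplyr::rename(ci, term = "param", estimate = "mean", std.error = "sd",
                conf.low = "lower", conf.high = "upper")
}

#' @export
glance.vl_fit <- function(x, ...) {
  tibble::tibble(F = x$F, iterations = x$iterations,
                 converged = x$converged,
                 sigma = mean(exp(-x$lambda / 2)))
}

#' Broom-style tidiers
#'
#' `tidy()` returns per-parameter posterior summaries; `glance()` a one-row
#' model summary including the free energy (log-evidence bound).
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @name tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")
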