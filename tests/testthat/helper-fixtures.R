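# Shared fixtures for the test suite. Everything is generated in code; the
# heavier simulations are memoised so several tests can share one run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

# fast engine configuration used by most simulation tests
fast_engine <- function(...) {
  engine_config(step = 2, n_embed = 3, n_bins = 64, compute_variance = FALSE,
                ...)
}

# the reference simulation: Table-1 prior expectations, Fast smooth target
table1_sim <- function() {
  memo("table1_sim", {
    tr <- smooth_target(condition_spec(n_cycles = 2))
    simulate_pursuit(full_parameter_set(), tr, engine = engine_config())
  })
}

# one-dimensional linear-Gaussian model for the engine oracle tests:
# s = x + noise, x-dot = -0.5 x + v, cause prior a known sinusoid
linear_gf_model <- function(lnPs = 4, lnPx = 4, lnPv = 4,
                            omega = 2 * pi / 200, decay = 0.5) {
  structure(list(
    g = function(x, v) x[1],
    f = function(x, v) -decay * x[1] + v,
    gx = function(x, v) matrix(1, 1, 1),
    fx = function(x, v) matrix(-decay, 1, 1),
    fv = function(x, v) matrix(1, 1, 1),
    eta = function(t, order = 0) omega^order * cos(omega * t + order * pi / 2),
    nx = 1, nv = 1, ns = 1, lnPi_s = lnPs, lnPi_x = lnPx, lnPi_v = lnPv,
    x0 = 0, v0 = 1), class = "gf_model")
}

# steady-state trajectory of x-dot = -decay x + cos(omega t)
linear_truth <- function(nb, omega = 2 * pi / 200, decay = 0.5) {
  A <- 1 / sqrt(decay^2 + omega^2)
  phi <- atan2(omega, decay)
  A * cos(omega * seq_len(nb) - phi)
}

# instantaneous closed-form posterior mode given embedded data (the
# analytic optimum the filter tracks for a linear model)
linear_instant_oracle <- function(model, data, cfg) {
  mats <- pursuitdcm:::gf_matrices(model, cfg)
  n <- cfg$n_embed; d <- cfg$d_embed
  Gx <- model$gx(0, 0); Fx <- model$fx(0, 0); Fv <- model$fv(0, 0)
  Gt <- kronecker(diag(n), Gx)
  Ft <- kronecker(diag(n), Fx)
  Fvt <- matrix(0, n, d)
  for (k in seq_len(min(n, d))) Fvt[k, k] <- Fv
  DF <- mats$Dx - Ft
  H <- rbind(
    cbind(crossprod(Gt, mats$Ps %*% Gt) + crossprod(DF, mats$Px %*% DF),
          -crossprod(DF, mats$Px %*% Fvt)),
    cbind(-crossprod(Fvt, mats$Px %*% DF),
          crossprod(Fvt, mats$Px %*% Fvt) + mats$Pv))
  nb <- nrow(data)
  hist <- matrix(data[1, 1], 1, n)
  out <- numeric(nb)
  for (i in seq_len(nb)) {
    hist <- cbind(data[i, 1], hist[, -n, drop = FALSE])
    s_til <- as.numeric(hist %*% t(mats$E))
    eta_til <- vapply(0:(d - 1), function(o) model$eta(i * cfg$step, o),
                      numeric(1))
    b <- c(as.numeric(crossprod(Gt, mats$Ps %*% s_til)),
           as.numeric(mats$Pv %*% eta_til))
    out[i] <- solve(H, b)[1]
  }
  out
}

# exact log evidence of a linear-Gaussian regression y = X theta + e
linear_log_evidence <- function(y, X, prior_mean, prior_cov, noise_var) {
  n <- length(y)
  S <- X %*% prior_cov %*% t(X) + diag(noise_var, n)
  r <- y - X %*% prior_mean
  as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(S, logarithm = TRUE)$modulus +
                       t(r) %*% solve(S, r)))
}
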