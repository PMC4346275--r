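#' Engine configuration for generalised filtering
#'
#' Numerical settings of the active-inference integrator. Time inside the
#' differential equations is measured in units of the oculomotor time constant
#' `tau_ms` (default 16 ms); one integration step advances `step` of these
#' units by local linearisation (matrix-exponential update of the joint
#' system of expectations, action and plant). Generalised coordinates use
#' `n_embed` orders for hidden states and sensory data and `d_embed` orders
#' for the hidden cause, with a Gaussian autocorrelation of width `smoothness`
#' (in time-constant units) defining the precision of higher-order motion.
#'
#' @param n_embed Embedding order for states/sensory data (2..6).
#' @param d_embed Embedding order for the hidden cause (1..n_embed).
#' @param smoothness Autocorrelation width of fluctuations, tau units.
#' @param tau_ms Time-constant / time-unit of the model equations, ms.
#' @param step Integration step, tau units.
#' @param model_softness Occluder edge softness used by the subjective model
#'   (amplitude units).
#' @param stim_softness Occluder edge softness used when generating the
#'   sensory consequences of the stimulus; `NULL` (default) uses
#'   `model_softness`, so data and predictions dim in register at the
#'   occluder edge as in the generative process of the pursuit model. (The
#'   paradigm's per-sample visibility flags always use the hard window.)
#' @param action Logical: close the action-perception loop? With `FALSE` the
#'   eye is not driven and the engine performs pure filtering.
#' @param n_bins Output comparison grid: bins per cycle for normalised
#'   single-cycle summaries.
#' @param compute_variance Logical: compute per-bin Laplace conditional
#'   variances? Skipping them speeds up the inner loop of model fits, where
#'   only the trajectory is needed.
#' @return Object of class `engine_config`.
#' @export
engine_config <- function(n_embed = 4, d_embed = 2, smoothness = 1,
                          tau_ms = 16, step = 1, model_softness = 1 / 32,
                          stim_softness = NULL, action = TRUE, n_bins = 128,
                          compute_variance = TRUE) {
  stopifnot(n_embed >= 2, n_embed <= 6, d_embed >= 1, d_embed <= n_embed,
            smoothness > 0, tau_ms > 0, step > 0, model_softness >= 0,
            is.null(stim_softness) || stim_softness >= 0, n_bins >= 8)
  structure(list(n_embed = n_embed, d_embed = d_embed,
                 smoothness = smoothness, tau_ms = tau_ms, step = step,
                 model_softness = model_softness,
                 stim_softness = stim_softness %||% model_softness,
                 action = action, n_bins = n_bins,
                 compute_variance = isTRUE(compute_variance)),
            class = "engine_config")
}

# Derivative of the soft occlusion visibility O(x) w.r.t. x.
occluder_visibility_grad <- function(x, geom) {
  if (geom$softness == 0) return(rep(0, length(x)))
  s <- geom$softness
  a <- stats::plogis((x - geom$lower) / s)
  b <- stats::plogis((geom$upper - x) / s)
  -(a * (1 - a) * b / s - a * b * (1 - b) / s)
}

#' Build the generalised-filtering model of pursuit
#'
#' Packages the subjective generative model (sensory mapping, hidden-state
#' flow, attractor prior and their analytic Jacobians) in the form consumed by
#' [gf_filter()]. Hidden states are (eye pos, eye vel, target pos, target
#' vel); the single hidden cause is the attracting location.
#'
#' @param p A [full_parameter_set()].
#' @param geom Occluder geometry used by the subjective model (normally soft).
#' @param sg A [sensory_geometry()].
#' @param sgn Start sign (+1 right start, -1 left start): flips the attractor.
#' @param cycle_tau Cycle length in model time units.
#' @param x_init Initial eye/target position (trials start with a long
#'   fixation on the static target, so expectations start at truth).
#' @return A `gf_model` list with elements `g`, `f`, `gx`, `fx`, `fv`, `eta`,
#'   `nx`, `nv`, `ns`, `x0`, `v0` and log precisions.
#' @export
pursuit_gf_model <- function(p = full_parameter_set(),
                             geom = occluder_geometry(softness = 1 / 32),
                             sg = sensory_geometry(), sgn = 1,
                             cycle_tau = 4173 / 16, x_init = sgn) {
  k <- p$kinetic
  pb <- p$prior_beliefs
  r <- sg$channel_centres
  w <- sg$field_width
  omega <- 2 * pi / cycle_tau

  g <- function(x, v) {
    o <- occluder_visibility(x[3], geom)
    z <- (r + x[1] - x[3]) / w
    c(x[1], o * exp(-z^2))
  }
  gx <- function(x, v) {
    o <- occluder_visibility(x[3], geom)
    do <- occluder_visibility_grad(x[3], geom)
    z <- (r + x[1] - x[3]) / w
    e <- exp(-z^2)
    J <- matrix(0, length(r) + 1, 4)
    J[1, 1] <- 1
    J[-1, 1] <- o * e * (-2 * z / w)
    J[-1, 3] <- do * e + o * e * (2 * z / w)
    J
  }
  vis_parts <- function(x3, v) {
    ov <- occluder_visibility(v, geom)
    ot <- occluder_visibility(x3, geom)
    vis <- pmax(ov, ot)
    # subgradient of max: attribute to the larger branch (target at ties)
    list(vis = vis,
         dvis_dxt = if (ot >= ov) occluder_visibility_grad(x3, geom) else 0,
         dvis_dv = if (ov > ot) occluder_visibility_grad(v, geom) else 0)
  }
  f <- function(x, v) {
    vp <- vis_parts(x[3], v)
    kv <- k$theta1 - k$theta4 * vp$vis
    kt <- k$theta3 + k$theta5 * vp$vis
    c(x[2],
      kv * (v - x[1]) + kt * (x[3] - x[1]) - k$theta2 * x[2],
      x[4],
      (v - x[3]) / 4 - k$theta6 * x[4])
  }
  fx <- function(x, v) {
    vp <- vis_parts(x[3], v)
    kv <- k$theta1 - k$theta4 * vp$vis
    kt <- k$theta3 + k$theta5 * vp$vis
    dacc_dxt <- kt + (-k$theta4 * (v - x[1]) + k$theta5 * (x[3] - x[1])) *
      vp$dvis_dxt
    matrix(c(0, 1, 0, 0,
             -(kv + kt), -k$theta2, dacc_dxt, 0,
             0, 0, 0, 1,
             0, 0, -1 / 4, -k$theta6),
           nrow = 4, byrow = TRUE)
  }
  fv <- function(x, v) {
    vp <- vis_parts(x[3], v)
    kv <- k$theta1 - k$theta4 * vp$vis
    dacc_dv <- kv + (-k$theta4 * (v - x[1]) + k$theta5 * (x[3] - x[1])) *
      vp$dvis_dv
    matrix(c(0, dacc_dv, 0, 1 / 4), ncol = 1)
  }
  eta <- function(t_tau, order = 0) {
    sgn * pb$amplitude * omega^order *
      cos(omega * t_tau + pb$phase_lead + order * pi / 2)
  }
  structure(list(g = g, f = f, gx = gx, fx = fx, fv = fv, eta = eta,
                 nx = 4, nv = 1, ns = length(r) + 1,
                 lnPi_s = p$precisions$log_prec_sensory,
                 lnPi_x = p$precisions$log_prec_states,
                 lnPi_v = p$precisions$log_prec_cause,
                 x0 = c(x_init, 0, x_init, 0), v0 = eta(0)),
            class = "gf_model")
}

# Finite-difference Jacobians for models that do not supply analytic ones.
fd_jacobian <- function(fun, x, eps = 1e-4) {
  f0 <- fun(x)
  J <- matrix(0, length(f0), length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    J[, i] <- (fun(xp) - fun(xm)) / (2 * eps)
  }
  J
}

# Model Jacobians and linearised generalised operators at the current mode.
gf_operators <- function(u, model, mats) {
  nx <- model$nx; nv <- model$nv; ns <- model$ns
  n <- mats$n; d <- mats$d
  x0 <- u[seq_len(nx)]
  v0 <- u[nx * n + seq_len(nv)]
  Gx <- if (is.null(model$gx)) fd_jacobian(function(z) model$g(z, v0), x0) else
    model$gx(x0, v0)
  Fx <- if (is.null(model$fx)) fd_jacobian(function(z) model$f(z, v0), x0) else
    model$fx(x0, v0)
  Fv <- if (is.null(model$fv)) fd_jacobian(function(z) model$f(x0, z), v0) else
    model$fv(x0, v0)
  Gt <- kronecker(diag(n), Gx)
  Ft <- kronecker(diag(n), Fx)
  Fvt <- matrix(0, nx * n, nv * d)
  for (kk in seq_len(min(n, d))) {
    Fvt[(kk - 1) * nx + seq_len(nx), (kk - 1) * nv + seq_len(nv)] <- Fv
  }
  list(x0 = x0, v0 = v0, g0 = model$g(x0, v0), f0 = model$f(x0, v0),
       Gt = Gt, Ft = Ft, Fvt = Fvt, DF = mats$Dx - Ft)
}

# Prediction errors of the filter at the current mode, given embedded data.
gf_errors <- function(u, s_tilde, op, model, mats, t_tau) {
  nx <- model$nx; nv <- model$nv; ns <- model$ns
  n <- mats$n; d <- mats$d
  ux <- u[seq_len(nx * n)]
  uv <- u[nx * n + seq_len(nv * d)]
  g_tilde <- as.numeric(op$Gt %*% ux)
  g_tilde[seq_len(ns)] <- op$g0
  f_tilde <- as.numeric(op$Ft %*% ux + op$Fvt %*% uv)
  f_tilde[seq_len(nx)] <- op$f0
  eta_t <- as.numeric(vapply(0:(d - 1), function(o) model$eta(t_tau, o),
                             numeric(nv)))
  list(e_s = s_tilde - g_tilde,
       e_x = as.numeric(mats$Dx %*% ux) - f_tilde,
       e_v = uv - eta_t)
}

#' One local-linearisation update of perceptual expectations
#'
#' Advances the stacked generalised expectations `u = (x-tilde, v-tilde)` by
#' `dt` given embedded sensory data: the flow is `Du - dF/du` with F the
#' precision-weighted sum of squared sensory, state and cause prediction
#' errors; the Gauss-Newton Jacobian of the flow defines the local
#' linearisation (matrix-exponential update). Closed-loop simulation with
#' action is handled by [gf_filter()], which integrates the same update
#' jointly with action and the oculomotor plant.
#'
#' @param u Stacked expectations: `nx * n` state orders then `nv * d` cause
#'   orders.
#' @param s_tilde Embedded sensory data, order-major (`ns * n`).
#' @param model A `gf_model` (see [pursuit_gf_model()]).
#' @param mats Precomputed operator list from [gf_matrices()].
#' @param t_tau Current time (model units) at which the cause prior is
#'   evaluated.
#' @param dt Step length, model time units.
#' @return List with updated `u`, order-0 prediction error `e_s0` and
#'   prediction `g0`, and conditional variances `var_x`, `var_v`.
#' @export
filtering_step <- function(u, s_tilde, model, mats, t_tau, dt) {
  nx <- model$nx; nv <- model$nv
  n <- mats$n; d <- mats$d
  op <- gf_operators(u, model, mats)
  er <- gf_errors(u, s_tilde, op, model, mats, t_tau)
  ux <- u[seq_len(nx * n)]
  uv <- u[nx * n + seq_len(nv * d)]

  du_x <- as.numeric(mats$Dx %*% ux) +
    as.numeric(crossprod(op$Gt, mats$Ps %*% er$e_s)) -
    as.numeric(crossprod(op$DF, mats$Px %*% er$e_x))
  du_v <- as.numeric(mats$Dv %*% uv) +
    as.numeric(crossprod(op$Fvt, mats$Px %*% er$e_x)) -
    as.numeric(mats$Pv %*% er$e_v)

  Axx <- mats$Dx - crossprod(op$Gt, mats$Ps %*% op$Gt) -
    crossprod(op$DF, mats$Px %*% op$DF)
  Axv <- crossprod(op$DF, mats$Px %*% op$Fvt)
  Avx <- crossprod(op$Fvt, mats$Px %*% op$DF)
  Avv <- mats$Dv - crossprod(op$Fvt, mats$Px %*% op$Fvt) - mats$Pv

  flow <- c(du_x, du_v)
  A <- rbind(cbind(Axx, Axv), cbind(Avx, Avv))
  if (any(!is.finite(flow)) || any(!is.finite(A)))
    stop("non-finite gradients in filtering step")
  u_new <- u + ll_step(flow, A, dt)

  vv <- gf_variances(op, mats, model)
  list(u = u_new, e_s0 = er$e_s[seq_len(model$ns)], g0 = op$g0,
       var_x = vv$var_x, var_v = vv$var_v)
}

# Laplace conditional variances of states and cause at the current mode.
gf_variances <- function(op, mats, model) {
  nx <- model$nx; nv <- model$nv
  n <- mats$n; d <- mats$d
  H <- rbind(
    cbind(crossprod(op$Gt, mats$Ps %*% op$Gt) +
            crossprod(op$DF, mats$Px %*% op$DF),
          -crossprod(op$DF, mats$Px %*% op$Fvt)),
    cbind(-crossprod(op$Fvt, mats$Px %*% op$DF),
          crossprod(op$Fvt, mats$Px %*% op$Fvt) + mats$Pv))
  H <- (H + t(H)) / 2
  Sig <- tryCatch(solve(H), error = function(e)
    solve(H + diag(1e-8, nrow(H))))
  list(var_x = diag(Sig)[seq_len(nx)],
       var_v = diag(Sig)[nx * n + seq_len(nv)])
}

# Local-linearisation step dx = (expm(A dt) - I) A^-1 f, computed through the
# augmented matrix-exponential (avoids inverting A).
ll_step <- function(flow, A, dt) {
  m <- length(flow)
  M <- matrix(0, m + 1, m + 1)
  M[seq_len(m) + 1, 1] <- flow * dt
  M[seq_len(m) + 1, seq_len(m) + 1] <- A * dt
  (expm_mat(M))[seq_len(m) + 1, 1]
}

# Matrix exponential by scaling-and-squaring on a Pade(6,6) approximant.
expm_mat <- function(M) {
  nrm <- max(rowSums(abs(M)))
  j <- max(0, ceiling(log2(max(nrm, 1e-12))) + 1)
  Ms <- M / 2^j
  n <- nrow(M)
  cvec <- 1
  for (k in 1:6) cvec <- c(cvec, cvec[k] * (6 - k + 1) / (k * (12 - k + 1)))
  P <- diag(n) * cvec[1]
  Q <- diag(n) * cvec[1]
  Xp <- diag(n)
  for (k in 1:6) {
    Xp <- Xp %*% Ms
    P <- P + cvec[k + 1] * Xp
    Q <- Q + (-1)^k * cvec[k + 1] * Xp
  }
  E <- solve(Q, P)
  for (k in seq_len(j)) E <- E %*% E
  E
}

#' Precomputed operators of a filtering run
#'
#' Shift operators, generalised precisions and the causal Taylor embedding
#' used by [filtering_step()] and [gf_filter()].
#'
#' @param model A `gf_model`.
#' @param config An [engine_config()].
#' @return List of matrices (`Dx`, `Dv`, `Ps`, `Px`, `Pv`, `E`) and orders.
#' @export
gf_matrices <- function(model, config) {
  n <- config$n_embed; d <- config$d_embed
  list(n = n, d = d,
       Dx = shift_matrix(n, model$nx),
       Dv = shift_matrix(d, model$nv),
       Ps = generalized_precision(model$lnPi_s, n, config$smoothness,
                                  model$ns),
       Px = generalized_precision(model$lnPi_x, n, config$smoothness,
                                  model$nx),
       Pv = generalized_precision(model$lnPi_v, d, config$smoothness,
                                  model$nv),
       E = taylor_embedding(n, config$step))
}

#' Generalised filtering (R reference implementation)
#'
#' Two modes. With `data`, runs pure filtering: each row is a sensory sample;
#' samples are lifted to generalised coordinates by causal Taylor embedding
#' and the expectations follow [filtering_step()]. With `process`, runs
#' closed-loop active inference: the expectations, the action and the
#' oculomotor plant form one joint system integrated by local linearisation,
#' with the generalised sensory input constructed from the plant (random
#' fluctuations of the generative process are suppressed). The C++ fast path
#' used by [simulate_pursuit()] mirrors the process mode bin for bin.
#'
#' @param model A `gf_model` (see [pursuit_gf_model()]).
#' @param n_steps Number of integration steps.
#' @param config An [engine_config()].
#' @param data Optional `n_steps x ns` matrix of sensory samples.
#' @param process Optional process list with elements `pstate0`,
#'   `flow(pstate, a)` and `s_gen(pstate, a, t_tau)` returning the `ns x n`
#'   generalised sensory sample.
#' @return List of per-bin matrices: `mu_x`, `mu_v`, `action`, `var_x`,
#'   `var_v`, `pred` (order-0 sensory predictions), `err` (order-0 sensory
#'   prediction errors), and `eye`/`eye_vel` if a process was supplied.
#' @export
gf_filter <- function(model, n_steps, config = engine_config(), data = NULL,
                      process = NULL) {
  stopifnot(xor(is.null(data), is.null(process)))
  mats <- gf_matrices(model, config)
  n <- mats$n; d <- mats$d
  nx <- model$nx; nv <- model$nv; ns <- model$ns
  h <- config$step
  out <- list(mu_x = matrix(0, n_steps, nx), mu_v = matrix(0, n_steps, nv),
              action = numeric(n_steps), var_x = matrix(0, n_steps, nx),
              var_v = matrix(0, n_steps, nv), pred = matrix(0, n_steps, ns),
              err = matrix(0, n_steps, ns), eye = numeric(n_steps),
              eye_vel = numeric(n_steps))

  if (!is.null(data)) {
    u <- c(c(model$x0, rep(0, nx * (n - 1))),
           c(model$v0, rep(0, nv * (d - 1))))
    hist <- matrix(data[1, ], ns, n)
    for (i in seq_len(n_steps)) {
      hist <- cbind(data[i, ], hist[, -n, drop = FALSE])
      s_tilde <- as.numeric(hist %*% t(mats$E))
      st <- filtering_step(u, s_tilde, model, mats, t_tau = i * h, dt = h)
      u <- st$u
      if (max(abs(u)) > 1e3)
        stop(sprintf("integration failure: |states| > 1e3 at bin %d", i))
      out$mu_x[i, ] <- u[seq_len(nx)]
      out$mu_v[i, ] <- u[nx * n + seq_len(nv)]
      out$var_x[i, ] <- st$var_x
      out$var_v[i, ] <- st$var_v
      out$pred[i, ] <- st$g0
      out$err[i, ] <- st$e_s0
    }
    return(out)
  }

  # closed loop: joint system (expectations, action, plant)
  np <- length(process$pstate0)
  Nx <- nx * n; Nv <- nv * d
  m <- Nx + Nv + 1 + np
  ia <- Nx + Nv + 1
  ip <- Nx + Nv + 1 + seq_len(np)
  u <- c(c(model$x0, rep(0, nx * (n - 1))),
         c(model$v0, rep(0, nv * (d - 1))), 0, process$pstate0)
  act_on <- config$action
  eps <- 1e-4
  for (i in seq_len(n_steps)) {
    t_tau <- i * h
    a <- u[ia]
    pstate <- u[ip]
    op <- gf_operators(u, model, mats)
    s_mat <- process$s_gen(pstate, a, t_tau)
    s_tilde <- as.numeric(s_mat)
    er <- gf_errors(u, s_tilde, op, model, mats, t_tau)
    # sensitivities of the generalised sensory data (central differences)
    dsda <- as.numeric(process$s_gen(pstate, a + eps, t_tau) -
                         process$s_gen(pstate, a - eps, t_tau)) / (2 * eps)
    dsdp <- vapply(seq_len(np), function(j) {
      pp <- pstate; pm <- pstate
      pp[j] <- pp[j] + eps; pm[j] <- pm[j] - eps
      as.numeric(process$s_gen(pp, a, t_tau) -
                   process$s_gen(pm, a, t_tau)) / (2 * eps)
    }, numeric(ns * n))

    ux <- u[seq_len(Nx)]
    uv <- u[Nx + seq_len(Nv)]
    GtPs <- crossprod(op$Gt, mats$Ps)
    DFPx <- crossprod(op$DF, mats$Px)
    du_x <- as.numeric(mats$Dx %*% ux) + as.numeric(GtPs %*% er$e_s) -
      as.numeric(DFPx %*% er$e_x)
    du_v <- as.numeric(mats$Dv %*% uv) +
      as.numeric(crossprod(op$Fvt, mats$Px %*% er$e_x)) -
      as.numeric(mats$Pv %*% er$e_v)
    Psda <- as.numeric(mats$Ps %*% dsda)
    da <- if (act_on) -sum(Psda * er$e_s) else 0
    dp <- process$flow(pstate, if (act_on) a else 0)

    A <- matrix(0, m, m)
    A[seq_len(Nx), seq_len(Nx)] <- mats$Dx - GtPs %*% op$Gt - DFPx %*% op$DF
    A[seq_len(Nx), Nx + seq_len(Nv)] <- DFPx %*% op$Fvt
    A[Nx + seq_len(Nv), seq_len(Nx)] <- crossprod(op$Fvt, mats$Px %*% op$DF)
    A[Nx + seq_len(Nv), Nx + seq_len(Nv)] <-
      mats$Dv - crossprod(op$Fvt, mats$Px %*% op$Fvt) - mats$Pv
    A[seq_len(Nx), ia] <- as.numeric(GtPs %*% dsda)
    A[seq_len(Nx), ip] <- GtPs %*% dsdp
    if (act_on) {
      A[ia, seq_len(Nx)] <- as.numeric(crossprod(Psda, op$Gt))
      A[ia, ia] <- -sum(dsda * Psda)
      A[ia, ip] <- -as.numeric(crossprod(Psda, dsdp))
    }
    # plant Jacobian by the same central differences
    for (j in seq_len(np)) {
      pp <- pstate; pm <- pstate
      pp[j] <- pp[j] + eps; pm[j] <- pm[j] - eps
      A[ip, ip[j] ] <- (process$flow(pp, a) - process$flow(pm, a)) / (2 * eps)
    }
    A[ip, ia] <- (process$flow(pstate, a + eps) -
                    process$flow(pstate, a - eps)) / (2 * eps)

    flow <- c(du_x, du_v, da, dp)
    if (any(!is.finite(flow)) || any(!is.finite(A)))
      stop(sprintf("non-finite gradients at bin %d", i))
    u <- u + ll_step(flow, A, h)
    if (max(abs(u)) > 1e3)
      stop(sprintf("integration failure: |states| > 1e3 at bin %d", i))

    vv <- gf_variances(op, mats, model)
    out$mu_x[i, ] <- u[seq_len(nx)]
    out$mu_v[i, ] <- u[Nx + seq_len(nv)]
    out$action[i] <- u[ia]
    out$var_x[i, ] <- vv$var_x
    out$var_v[i, ] <- vv$var_v
    out$pred[i, ] <- op$g0
    out$err[i, ] <- er$e_s[seq_len(ns)]
    out$eye[i] <- u[ip[1]]
    out$eye_vel[i] <- u[ip[2]]
  }
  out
}

#' One gradient step of action
#'
#' Action performs a descent on free energy through the proprioceptive
#' prediction error: `a-dot = -(ds-tilde/da)' Pi-s e-s`. Exposed for testing
#' the sign and fixed-point structure of the action gradient; [gf_filter()]
#' integrates action jointly with the expectations and plant.
#'
#' @param a Current action.
#' @param e_s Generalised sensory prediction error (order-major).
#' @param dsda Gradient of the generalised sensory data w.r.t. action.
#' @param Ps Generalised sensory precision.
#' @param dt Step, model time units.
#' @return Updated action after an explicit Euler step.
#' @export
action_step <- function(a, e_s, dsda, Ps, dt) {
  a - dt * sum(dsda * (Ps %*% e_s))
}
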