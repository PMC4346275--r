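#' Bayesian model reduction of a Gaussian posterior
#'
#' Given the prior and posterior of a full model and an alternative (reduced)
#' prior over the same parameters, computes the posterior and the change in
#' log evidence that would have been obtained by inverting the reduced model,
#' in closed form:
#' reduced posterior precision = full posterior precision + reduced prior
#' precision - full prior precision (means updated correspondingly), and
#' `dF` is the log of the Gaussian integral ratio. Under conjugacy (linear
#' models) the reduction is exact. Free parameters are effectively removed by
#' very precise shrinkage priors.
#'
#' @param prior_mean,prior_cov Full-model prior.
#' @param post_mean,post_cov Full-model posterior.
#' @param red_mean,red_cov Reduced prior.
#' @return List with `mean`, `cov`, `dF` (reduced minus full log evidence)
#'   and `feasible` (`FALSE` when the implied precision is not positive
#'   definite).
#' @export
reduce_posterior <- function(prior_mean, prior_cov, post_mean, post_cov,
                             red_mean, red_cov) {
  P0 <- solve(prior_cov)
  P <- solve(post_cov)
  Pr0 <- solve(red_cov)
  Pr <- P + Pr0 - P0
  ev <- eigen(Pr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    return(list(mean = NULL, cov = NULL, dF = -Inf, feasible = FALSE))
  }
  b <- P %*% post_mean + Pr0 %*% red_mean - P0 %*% prior_mean
  Cr <- solve(Pr)
  mr <- as.numeric(Cr %*% b)
  ld <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)
  qf <- function(m, Pm) as.numeric(t(m) %*% Pm %*% m)
  dF <- 0.5 * (ld(Pr0) - ld(P0) + ld(P) - ld(Pr)) -
    0.5 * (qf(post_mean, P) + qf(red_mean, Pr0) - qf(prior_mean, P0) -
             qf(mr, Pr))
  list(mean = mr, cov = Cr, dF = dF, feasible = TRUE)
}

#' Default candidate model family for post-hoc optimisation
#'
#' All on/off combinations of each experimental factor's effect on each of
#' five parameter groups: the three log precisions, the kinetic coupling
#' group (theta1, theta3, theta4, theta5) and the prior-belief group
#' (theta7, theta8) - 2^10 = 1024 reduced models. Baseline deviations are
#' retained in every candidate.
#'
#' @param fit A fitted `pursuit_dcm`.
#' @return Tibble with a logical column per (factor x group) toggle and a
#'   list-column `keep` of logical vectors over the fit's latent parameters.
#' @export
default_candidate_masks <- function(fit) {
  nm <- fit$latent_names
  group_of <- function(param) {
    switch(param,
           lnPi_s = "pi_s", lnPi_x = "pi_x", lnPi_v = "pi_v",
           theta7 = "prior", theta8 = "prior",
           "kinetic")
  }
  toggles <- expand.grid(rep(list(c(FALSE, TRUE)), 10))
  names(toggles) <- paste0(rep(c("noise", "speed"), each = 5), "_",
                           c("pi_s", "pi_x", "pi_v", "kinetic", "prior"))
  keep <- lapply(seq_len(nrow(toggles)), function(i) {
    row <- toggles[i, ]
    vapply(nm, function(l) {
      parts <- strsplit(l, ".", fixed = TRUE)[[1]]
      if (parts[1] == "baseline") return(TRUE)
      isTRUE(row[[paste0(parts[1], "_", group_of(parts[2]))]])
    }, logical(1))
  })
  out <- tibble::as_tibble(toggles)
  out$model_id <- seq_len(nrow(out))
  out$keep <- keep
  out
}

#' Search over reduced models
#'
#' Scores every candidate reduced model by Bayesian model reduction of the
#' full fit: parameters outside a candidate's mask get a very precise
#' shrinkage prior (variance `shrink_var`) centred on zero. Posterior model
#' probabilities follow by softmax of the evidence changes.
#'
#' @param fit A fitted `pursuit_dcm` (or `vl_fit` with prior information).
#' @param candidates Candidate table from [default_candidate_masks()], or a
#'   list of logical keep-vectors.
#' @param shrink_var Shrinkage prior variance for removed parameters.
#' @return Tibble `model_id`, `dF`, `prob`, `keep` (list-column), plus the
#'   toggle columns when present; sorted by probability. Reduced posterior
#'   means/covariances are attached as list-columns `post_mean`, `post_cov`.
#' @export
model_search <- function(fit, candidates = default_candidate_masks(fit),
                         shrink_var = 1e-8) {
  if (is.list(candidates) && !is.data.frame(candidates))
    candidates <- tibble::tibble(model_id = seq_along(candidates),
                                 keep = candidates)
  p <- length(fit$mean)
  base_var <- diag(fit$prior_cov)
  res <- purrr::map(candidates$keep, function(keep) {
    rv <- ifelse(keep, base_var, shrink_var)
    reduce_posterior(fit$prior_mean, fit$prior_cov, fit$mean, fit$cov,
                     red_mean = rep(0, p), red_cov = diag(rv, p))
  })
  dF <- vapply(res, `[[`, numeric(1), "dF")
  pr <- exp(dF - max(dF))
  pr <- pr / sum(pr)
  out <- candidates
  out$dF <- dF
  out$prob <- pr
  out$post_mean <- purrr::map(res, "mean")
  out$post_cov <- purrr::map(res, "cov")
  dplyr::arrange(out, dplyr::desc(.data$prob))
}

#' Bayesian model averaging over a model search
#'
#' Mixture of the reduced posteriors weighted by their posterior model
#' probabilities; the mixture covariance includes the dispersion of the
#' member means about the average.
#'
#' @param search Output of [model_search()].
#' @param min_prob Members below this probability are dropped (weights are
#'   renormalised) to keep the average numerically tidy.
#' @return List with `mean`, `cov` and the member table used.
#' @export
bayesian_model_average <- function(search, min_prob = 1e-6) {
  keep <- search$prob >= min_prob & is.finite(search$dF)
  s <- search[keep, ]
  w <- s$prob / sum(s$prob)
  p <- length(s$post_mean[[1]])
  m <- rep(0, p)
  for (i in seq_along(w)) m <- m + w[i] * s$post_mean[[i]]
  C <- matrix(0, p, p)
  for (i in seq_along(w)) {
    d <- s$post_mean[[i]] - m
    C <- C + w[i] * (s$post_cov[[i]] + tcrossprod(d))
  }
  list(mean = m, cov = C, members = s[, setdiff(names(s),
                                                c("post_mean", "post_cov"))])
}
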