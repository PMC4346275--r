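#' Shift operator on generalised coordinates
#'
#' A variable in generalised coordinates of motion is stored with one column
#' per temporal derivative (order 0, 1, 2, ...). The shift operator D maps
#' each order to the next: order d of the output is order d + 1 of the input,
#' and the highest order is zero-filled. Applying D `order` times annihilates
#' the vector.
#'
#' @param g Numeric vector (orders of a scalar variable) or matrix with one
#'   row per variable and one column per order.
#' @return Object of the same shape with orders shifted down.
#' @examples
#' shift_operator(c(1, 2, 3)) # 2 3 0
#' @export
shift_operator <- function(g) {
  if (is.matrix(g)) {
    n <- ncol(g)
    cbind(g[, -1, drop = FALSE], matrix(0, nrow(g), 1))
  } else {
    c(g[-1], 0)
  }
}

#' Shift matrix over stacked generalised orders
#'
#' Matrix form of [shift_operator()] for an order-major stacking
#' (all variables at order 0, then all at order 1, ...).
#'
#' @param order Number of generalised orders.
#' @param n_var Number of variables per order.
#' @return A `(order * n_var)` square matrix.
#' @export
shift_matrix <- function(order, n_var = 1) {
  s <- matrix(0, order, order)
  if (order > 1) s[cbind(seq_len(order - 1), seq_len(order - 1) + 1)] <- 1
  kronecker(s, diag(n_var))
}

#' Autocorrelation matrix of generalised motion
#'
#' Covariance (up to the fluctuation variance) among the generalised orders of
#' a stationary process with Gaussian autocorrelation
#' rho(h) = exp(-h^2 / (2 s^2)), where `s` is the autocorrelation width
#' (smoothness) in integration bins. Entry (i, j) is
#' (-1)^i * rho^(i+j)(0); odd-order entries vanish and even derivatives are
#' rho^(2m)(0) = (-1)^m (2m - 1)!! / s^(2m). The matrix is symmetric positive
#' definite for any order.
#'
#' @param order Number of generalised orders (>= 1).
#' @param smoothness Autocorrelation width `s` in bins (> 0).
#' @return `order x order` covariance matrix.
#' @export
gen_autocorr <- function(order, smoothness) {
  stopifnot(order >= 1, smoothness > 0)
  V <- matrix(0, order, order)
  for (i in seq_len(order)) {
    for (j in seq_len(order)) {
      k <- (i - 1) + (j - 1)
      if (k %% 2 == 0) {
        m <- k / 2
        dd <- if (m == 0) 1 else prod(seq(1, 2 * m - 1, by = 2)) # (2m-1)!!
        V[i, j] <- (-1)^(i - 1) * (-1)^m * dd / smoothness^(2 * m)
      }
    }
  }
  V
}

#' Precision over generalised orders
#'
#' Kronecker-form precision of a set of channels in generalised coordinates:
#' the base precision exp(`log_precision`) times the inverse autocorrelation
#' matrix of [gen_autocorr()], expanded over channels (order-major stacking).
#' For `order = 1` this is just `exp(log_precision) * I`.
#'
#' @param log_precision Natural-log precision of the fluctuations (scalar, or
#'   one value per channel).
#' @param order Number of generalised orders.
#' @param smoothness Autocorrelation width in bins.
#' @param n_channels Number of channels.
#' @return Symmetric positive-definite `(order * n_channels)` square matrix.
#' @export
generalized_precision <- function(log_precision, order, smoothness = 0.5,
                                  n_channels = 1) {
  stopifnot(order >= 1)
  base <- if (length(log_precision) == 1) {
    diag(exp(log_precision), n_channels)
  } else {
    stopifnot(length(log_precision) == n_channels)
    diag(exp(log_precision), n_channels)
  }
  V <- gen_autocorr(order, smoothness)
  P <- kronecker(solve(V), base)
  (P + t(P)) / 2
}

#' Causal Taylor embedding matrix
#'
#' Maps the most recent `order` samples of a series (current sample first,
#' spacing `dt`) to its generalised coordinates at the current time, by exact
#' inversion of the Taylor expansion s(t - k dt) = sum_j (-k dt)^j / j! s^(j).
#'
#' @param order Embedding order (number of samples / derivatives).
#' @param dt Sample spacing in time units of the derivatives.
#' @return `order x order` matrix E with s_tilde = E %*% history.
#' @export
taylor_embedding <- function(order, dt = 1) {
  Tm <- outer(0:(order - 1), 0:(order - 1),
              function(k, j) (-k * dt)^j / factorial(j))
  solve(Tm)
}
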