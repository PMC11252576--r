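# Fractal-fractional Caputo solver: explicit two-step-Lagrange fractional
# Adams-Bashforth product integration on a uniform grid.  The state update is
# the cumulative form
#
#   Y_{m+1} = Y_0 + q l^p / Gamma(p+2) *
#             sum_{n=0}^{m} [ g_n h(t_n, Y_n) wA(m,n,p)
#                             - g_{n-1} h(t_{n-1}, Y_{n-1}) wB(m,n,p) ]
#
# with g_n = t_n^{q-1} the fractal weight, wA/wB the closed-form bracket
# coefficients (see ab_weight_pair), and the full memory sum recomputed from
# Y_0 at every step (O(n^2) work, deliberately: it is the literal cumulative
# scheme and it makes the pair-sum conservation exact per step).

.check_order <- function(p, q) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p > 1)
    stop("fractional order p must satisfy 0 < p <= 1")
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q > 1)
    stop("fractal dimension q must satisfy 0 < q <= 1")
  invisible(NULL)
}

#' Closed-form Adams-Bashforth bracket weights
#'
#' The two bracketed coefficients of the explicit fractional two-step scheme,
#' for step index \code{m}, summation index \code{n <= m} and fractional
#' order \code{p}:
#' \deqn{wA = (m+p+2-n)(1+m-n)^p - (m+2p+2-n)(m-n)^p}
#' \deqn{wB = (m+1-n)^{p+1} - (m+1+p-n)(m-n)^p}
#' with \eqn{0^p = 0}.  They depend only on the lag \code{k = m - n}.  At
#' \code{p = 1} they collapse to the classical Adams-Bashforth pair (3, 1)
#' for every lag; at \code{n = m} they are \code{(p + 2, 1)}.
#'
#' @param m step index (integer >= 0).
#' @param n summation index, \code{0 <= n <= m}; may be a vector.
#' @param p fractional order in (0, 1].
#' @return List with numeric components \code{wA} and \code{wB}.
#' @examples
#' ab_weight_pair(5, 5, 0.7)   # (p + 2, 1)
#' ab_weight_pair(9, 0:9, 1)   # all (3, 1)
#' @export
ab_weight_pair <- function(m, n, p) {
  .check_order(p, 1)
  if (any(n > m) || any(n < 0) || m < 0)
    stop("indices must satisfy 0 <= n <= m")
  k <- m - n
  # 0^p = 0 for p > 0 holds natively in R
  list(wA = (k + p + 2) * (k + 1)^p - (k + 2 * p + 2) * k^p,
       wB = (k + 1)^(p + 1) - (k + 1 + p) * k^p)
}

#' Fractal weight of a grid node
#'
#' The factor \eqn{t_n^{q-1}} that the fractal dimension attaches to the
#' integrand at node \code{n}.  For \code{q < 1} the factor is singular at
#' \code{t_0 = 0}; it is regularized by the first-panel mean of
#' \eqn{s^{q-1}}, namely \eqn{l^{q-1}/q}, used for both \code{n = 0} and the
#' pre-grid history node \code{n = -1}.  At \code{q = 1} every weight is
#' exactly 1, so the regularization is inert.
#'
#' @param n node index, \code{n >= -1}; may be a vector.
#' @param l grid step in years (> 0).
#' @param q fractal dimension in (0, 1].
#' @return Numeric weights, same length as \code{n}.
#' @examples
#' fractal_factor(5, 0.1, 1)     # 1
#' fractal_factor(4, 0.5, 0.5)   # 2^-0.5
#' @export
fractal_factor <- function(n, l, q) {
  .check_order(1, q)
  if (!is.numeric(l) || l <= 0) stop("step l must be positive")
  if (any(n < -1)) stop("node index must be >= -1")
  ifelse(n >= 1, (n * l)^(q - 1), l^(q - 1) / q)
}

.make_grid <- function(step, n_steps = NULL, horizon = NULL) {
  if (is.null(n_steps)) {
    if (is.null(horizon)) stop("give either n_steps or horizon")
    n_steps <- as.integer(round(horizon / step))
  }
  if (step <= 0 || n_steps < 0) stop("need step > 0 and n_steps >= 0")
  list(step = step, n_steps = as.integer(n_steps),
       times = (0:n_steps) * step)
}

.new_trajectory <- function(times, states, p, q, step, method) {
  if (is.null(colnames(states)))
    colnames(states) <- if (ncol(states) == 7) .compartments else
      paste0("y", seq_len(ncol(states)))
  structure(list(time = times, states = states, p = p, q = q,
                 step = step, method = method),
            class = "ff_trajectory")
}

#' Solve a system under the fractal-fractional Caputo derivative
#'
#' Integrates \eqn{{}^{FF}D^{p,q} y = h(t, y)} on a uniform grid by the
#' explicit two-step-Lagrange fractional Adams-Bashforth product-integration
#' scheme.  The scheme is fully deterministic (fixed summation order, double
#' precision) and reduces algebraically to the cumulative classical AB2
#' method at \code{p = q = 1}.
#'
#' The n = 0 term of the memory sum references the pre-grid pair
#' \eqn{(t_{-1}, Y_{-1})}, taken by constant extrapolation as
#' \eqn{(t_0, Y_0)}; the singular fractal weight at t = 0 is regularized by
#' the first-panel mean (see \code{\link{fractal_factor}}).
#'
#' @param rhs function \code{(t, y) -> dy}; for the AD model use
#'   \code{function(t, y) ad_rhs(y, params)}.
#' @param y0 numeric initial state (any length; named or not).
#' @param step grid step l in years.
#' @param p fractional order in (0, 1].
#' @param q fractal dimension in (0, 1].
#' @param n_steps number of steps; alternatively give \code{horizon}.
#' @param horizon final time T in years (used when \code{n_steps} is NULL).
#' @param warn_negative warn the first time any component goes negative
#'   (the model is linear and unclamped).
#' @return An \code{ff_trajectory}: list with \code{time} (length n+1),
#'   \code{states} ((n+1) x d matrix), and the run settings.
#' @examples
#' tr <- solve_ff(function(t, y) ad_rhs(y), ad_initial_state(),
#'                step = 0.05, p = 0.9, q = 0.9, horizon = 2)
#' conserved_sums(tr$states[nrow(tr$states), ])
#' @export
solve_ff <- function(rhs, y0, step, p, q, n_steps = NULL, horizon = NULL,
                     warn_negative = TRUE) {
  .check_order(p, q)
  grid <- .make_grid(step, n_steps, horizon)
  N <- grid$n_steps
  l <- grid$step
  d <- length(y0)
  if (!is.numeric(y0) || any(!is.finite(y0))) stop("y0 must be finite numeric")
  Y <- matrix(NA_real_, N + 1, d)
  nm <- names(y0)
  if (!is.null(nm)) colnames(Y) <- nm
  Y[1, ] <- y0
  if (N == 0)
    return(.new_trajectory(grid$times, Y, p, q, l, "ff_ab2"))
  g <- fractal_factor(0:N, l, q)
  k <- 0:(N - 1)
  wA <- (k + p + 2) * (k + 1)^p - (k + 2 * p + 2) * k^p
  wB <- (k + 1)^(p + 1) - (k + 1 + p) * k^p
  pref <- q * l^p / gamma(p + 2)
  FF <- matrix(NA_real_, N + 1, d)        # FF[n+1, ] = g_n * h(t_n, Y_n)
  FF[1, ] <- g[1] * rhs(0, y0)
  warned <- !warn_negative
  for (m in 0:(N - 1)) {
    # A-part: sum_n F_n wA_{m-n};  B-part: history term F_{-1} := F_0
    a <- crossprod(FF[1:(m + 1), , drop = FALSE], wA[(m:0) + 1])[, 1]
    b <- FF[1, ] * wB[m + 1]
    if (m >= 1)
      b <- b + crossprod(FF[1:m, , drop = FALSE], wB[((m - 1):0) + 1])[, 1]
    ynew <- y0 + pref * (a - b)
    if (any(!is.finite(ynew)))
      stop("solution became non-finite at step ", m + 1,
           " (t = ", format((m + 1) * l), ")")
    if (!warned && any(ynew < 0)) {
      warning("a population went negative at step ", m + 1,
              " (t = ", format((m + 1) * l),
              "); the model is linear and unclamped")
      warned <- TRUE
    }
    Y[m + 2, ] <- ynew
    FF[m + 2, ] <- g[m + 2] * rhs(grid$times[m + 2], ynew)
  }
  .new_trajectory(grid$times, Y, p, q, l, "ff_ab2")
}

#' Classical two-step Adams-Bashforth (cumulative form)
#'
#' The integer-order reduction oracle: standard AB2 with an Euler starter,
#' written in the same cumulative from-Y0 form and with the same constant
#' history extrapolation as \code{\link{solve_ff}}, so that at
#' \code{p = q = 1} the two agree to rounding error.
#'
#' @inheritParams solve_ff
#' @return An \code{ff_trajectory} with \code{p = q = 1}.
#' @export
classical_ab2 <- function(rhs, y0, step, n_steps = NULL, horizon = NULL) {
  grid <- .make_grid(step, n_steps, horizon)
  N <- grid$n_steps
  l <- grid$step
  d <- length(y0)
  Y <- matrix(NA_real_, N + 1, d)
  if (!is.null(names(y0))) colnames(Y) <- names(y0)
  Y[1, ] <- y0
  if (N == 0)
    return(.new_trajectory(grid$times, Y, 1, 1, l, "classical_ab2"))
  H <- matrix(NA_real_, N + 1, d)
  H[1, ] <- rhs(0, y0)
  for (m in 0:(N - 1)) {
    a <- 3 * crossprod(H[1:(m + 1), , drop = FALSE], rep(1, m + 1))[, 1]
    b <- H[1, ]
    if (m >= 1)
      b <- b + crossprod(H[1:m, , drop = FALSE], rep(1, m))[, 1]
    Y[m + 2, ] <- y0 + (l / 2) * (a - b)
    H[m + 2, ] <- rhs(grid$times[m + 2], Y[m + 2, ])
  }
  .new_trajectory(grid$times, Y, 1, 1, l, "classical_ab2")
}

#' @export
print.ff_trajectory <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf(
    "Fractal-fractional trajectory (%s): p = %g, q = %g, step = %g, %d nodes, t in [0, %g]\n",
    x$method, x$p, x$q, x$step, n, x$time[n]))
  cat("final state:\n")
  print(x$states[n, ], ...)
  invisible(x)
}

#' @export
summary.ff_trajectory <- function(object, ...) {
  rng <- apply(object$states, 2, range)
  rownames(rng) <- c("min", "max")
  out <- list(p = object$p, q = object$q, step = object$step,
              horizon = object$time[length(object$time)],
              range = rng,
              final = object$states[nrow(object$states), ])
  class(out) <- "summary.ff_trajectory"
  out
}

#' @export
print.summary.ff_trajectory <- function(x, ...) {
  cat(sprintf("p = %g, q = %g, step = %g years, horizon = %g years\n",
              x$p, x$q, x$step, x$horizon))
  cat("component ranges over the run:\n")
  print(x$range, ...)
  invisible(x)
}

#' @export
as.data.frame.ff_trajectory <- function(x, ...) {
  data.frame(time = x$time, x$states, check.names = FALSE)
}

#' Plot a trajectory
#'
#' One panel per component, time in years on the x axis.
#'
#' @param x an \code{ff_trajectory}.
#' @param which components to plot (names or indices); default all.
#' @param ... passed to \code{matplot}.
#' @export
plot.ff_trajectory <- function(x, which = colnames(x$states), ...) {
  sel <- x$states[, which, drop = FALSE]
  op <- graphics::par(mfrow = grDevices::n2mfrow(ncol(sel)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (j in seq_len(ncol(sel))) {
    graphics::plot(x$time, sel[, j], type = "l",
                   xlab = "time (years)", ylab = colnames(sel)[j],
                   main = colnames(sel)[j], ...)
  }
  invisible(x)
}
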