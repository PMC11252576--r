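# Independent reference solutions used to validate the product-integration
# scheme: matrix exponential (integer-order limit), scalar Mittag-Leffler
# (q = 1 limit), Beta-integral closed forms for power-law forcing (general
# p, q), and a fine-grid self-reference.  These exist to test solve_ff; they
# are not a general fractional-calculus API.

#' Matrix-exponential reference trajectory
#'
#' Exact solution \eqn{y(t) = e^{Mt} y_0} of the integer-order linear system,
#' the oracle for the \code{p = q = 1} limit of the scheme.
#'
#' @param M square rate matrix (1/year).
#' @param y0 initial state.
#' @param times numeric vector of evaluation times (years).
#' @return An \code{ff_trajectory} (method \code{"expm"}).
#' @export
expm_solution <- function(M, y0, times) {
  M <- as.matrix(M)
  d <- length(y0)
  res <- vapply(times, function(t)
    as.numeric(Matrix::expm(Matrix::Matrix(M * t)) %*% y0),
    numeric(d))
  Y <- if (d == 1L) matrix(res, ncol = 1L) else t(res)
  if (!is.null(names(y0))) colnames(Y) <- names(y0)
  .new_trajectory(times, Y,
                  p = 1, q = 1,
                  step = if (length(times) > 1) times[2] - times[1] else NA_real_,
                  method = "expm")
}

#' One-parameter Mittag-Leffler function
#'
#' \eqn{E_p(z) = \sum_{k \ge 0} z^k / \Gamma(pk + 1)}, the relaxation
#' function of the classical Caputo derivative: the scalar problem
#' \eqn{{}^C D^p y = \lambda y}, \eqn{y(0) = y_0} has solution
#' \eqn{y_0 E_p(\lambda t^p)}.  Evaluated by direct series summation,
#' truncated when a term falls below \code{tol}; for \code{|z| > 30}, where
#' the alternating series loses accuracy in double precision, the standard
#' exponential/algebraic asymptotic expansion is used instead.
#'
#' @param z real argument (vectorized).
#' @param p order in (0, 1].
#' @param tol series truncation tolerance.
#' @return Numeric vector, \eqn{E_p(z)}.
#' @examples
#' mittag_leffler(1, 1)        # e
#' mittag_leffler(0, 0.3)      # 1
#' @export
mittag_leffler <- function(z, p, tol = 1e-14) {
  .check_order(p, 1)
  vapply(z, function(zi) {
    if (abs(zi) <= 30) {
      s <- 0; term <- 1; k <- 0
      repeat {
        s <- s + term
        k <- k + 1
        term <- zi^k / gamma(p * k + 1)
        if (!is.finite(term))
          stop("Mittag-Leffler series term overflowed at k = ", k)
        if (abs(term) < tol) break
        if (k > 10000)
          stop("Mittag-Leffler series failed to converge within 10000 terms")
      }
      s
    } else {
      # asymptotic expansion for large |z|: algebraic tail, plus the
      # exponential term exp(z^{1/p})/p on the positive axis
      K <- 20L
      ks <- seq_len(K)
      # gamma() is NaN (with a warning) at the non-positive-integer poles,
      # where the reciprocal-gamma factor is 0
      terms <- -zi^(-ks) / suppressWarnings(gamma(1 - p * ks))
      terms[!is.finite(terms)] <- 0
      # optimal truncation: stop at the smallest nonzero term (at integer p
      # every algebraic term sits on a Gamma pole and the tail is empty)
      mag <- abs(terms)
      mag[mag == 0] <- NA
      s <- if (all(is.na(mag))) 0 else sum(terms[seq_len(which.min(mag))])
      if (zi > 0) s <- s + exp(zi^(1 / p)) / p
      s
    }
  }, numeric(1))
}

#' Exact solution under power-law forcing
#'
#' For forcing \eqn{h(t) = c t^a} the fractal-fractional Volterra equation
#' \deqn{y(t) = y_0 + \frac{q}{\Gamma(p)} \int_0^t s^{q-1} (t-s)^{p-1} c s^a ds}
#' has the closed form
#' \deqn{y(t) = y_0 + c \frac{q}{\Gamma(p)} B(q + a, p)\, t^{p+q+a-1}}
#' via the Beta integral.  Used as the general-(p, q) oracle.
#'
#' @param c forcing amplitude.
#' @param a forcing exponent (>= 0 so the integral converges).
#' @param y0 initial value.
#' @param p fractional order in (0, 1].
#' @param q fractal dimension in (0, 1].
#' @param t evaluation times (vectorized, >= 0).
#' @return Numeric vector of exact values.
#' @examples
#' power_forcing_exact(1, 0, 0, 0.5, 0.5, 1)   # 0.5 * sqrt(pi)
#' @export
power_forcing_exact <- function(c, a, y0, p, q, t) {
  .check_order(p, q)
  if (a < 0) stop("forcing exponent a must be >= 0")
  if (any(t < 0)) stop("t must be >= 0")
  y0 + c * (q / gamma(p)) * beta(q + a, p) * t^(p + q + a - 1)
}

#' Fine-grid self-reference
#'
#' Runs \code{\link{solve_ff}} on a refined grid and subsamples the result at
#' the nodes of a coarser grid, for self-convergence studies at general
#' (p, q) where no closed form exists.  \code{l_ref} must divide \code{step}.
#'
#' @inheritParams solve_ff
#' @param l_ref reference step (a divisor of \code{step}).
#' @return An \code{ff_trajectory} on the coarse nodes.
#' @export
fine_grid_reference <- function(rhs, y0, step, p, q, horizon, l_ref) {
  r <- step / l_ref
  if (abs(r - round(r)) > 1e-9)
    stop("l_ref must divide step")
  r <- as.integer(round(r))
  fine <- solve_ff(rhs, y0, l_ref, p, q, horizon = horizon,
                   warn_negative = FALSE)
  idx <- seq(1, length(fine$time), by = r)
  .new_trajectory(fine$time[idx], fine$states[idx, , drop = FALSE],
                  p, q, step, "ff_ab2_reference")
}
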