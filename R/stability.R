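# Ulam-Hyers stability machinery: the Lipschitz constant of the linear
# right-hand side, the Banach contraction constant Xi, the
# perturbation-to-solution factor C_{p,q}, and the stability certificate.
# The function space norm is the max over time of the summed component
# magnitudes, so the consistent Lipschitz constant of a linear map is the
# maximum absolute column sum (induced 1-norm).

#' Lipschitz constant of the linear right-hand side
#'
#' The induced matrix 1-norm (maximum absolute column sum), consistent with
#' the summed-components state norm.  For the default rates both the Abeta
#' and S columns attain the maximum, 1.04/year.
#'
#' @param M rate matrix (e.g. \code{\link{ad_matrix}()}).
#' @return Non-negative scalar, 1/year.
#' @examples
#' lipschitz_constant(ad_matrix())   # 1.04
#' @export
lipschitz_constant <- function(M) {
  M <- as.matrix(M)
  if (any(!is.finite(M))) stop("matrix must be finite")
  max(colSums(abs(M)))
}

#' Contraction constant of the solution operator
#'
#' \deqn{\Xi = q X_\Theta T^{p+q-1} B(p, q) / \Gamma(p)}
#' where \eqn{B} is the Beta function.  \eqn{\Xi < 1} certifies uniqueness of
#' the solution (Banach contraction) and Ulam-Hyers stability on the horizon
#' \code{T}.  At \code{p = q = 1} it reduces to \eqn{X_\Theta T}.
#'
#' @param p fractional order in (0, 1].
#' @param q fractal dimension in (0, 1].
#' @param T horizon in years (> 0).
#' @param X_theta Lipschitz constant of the right-hand side (>= 0).
#' @return Non-negative scalar.
#' @export
xi_constant <- function(p, q, T, X_theta) {
  .check_order(p, q)
  if (T <= 0) stop("horizon T must be positive")
  if (X_theta < 0) stop("X_theta must be >= 0")
  q * X_theta * T^(p + q - 1) * beta(p, q) / gamma(p)
}

#' Perturbation-to-solution factor
#'
#' \deqn{C_{p,q} = q T^{p+q-1} B(p, q) / \Gamma(p)}
#' the factor bounding how far an \eqn{\epsilon}-perturbed solution can drift
#' from the unperturbed Volterra solution.  Identical to
#' \code{xi_constant(p, q, T, 1)}.
#'
#' @inheritParams xi_constant
#' @return Non-negative scalar.
#' @export
c_pq <- function(p, q, T) {
  xi_constant(p, q, T, 1)
}

#' Ulam-Hyers stability report
#'
#' Assembles the Lipschitz constant, \eqn{\Xi}, \eqn{C_{p,q}} and — when
#' \eqn{\Xi < 1} so the certificate holds — the stability bound factor
#' \eqn{C_{p,q} / (1 - \Xi)}: every \eqn{\epsilon}-approximate solution then
#' lies within \eqn{(C_{p,q}/(1-\Xi))\epsilon} of the exact one.
#' Non-certification is a reported state, not an error; with the default
#' rates and the 20-year horizon \eqn{\Xi = 20.8 \ge 1} and no certificate
#' is available.
#'
#' @param M rate matrix; default the AD model defaults.
#' @inheritParams xi_constant
#' @return An object of class \code{uh_report}: list with \code{X_theta},
#'   \code{T}, \code{p}, \code{q}, \code{Xi}, \code{C_pq}, \code{certified},
#'   and \code{bound_factor} (NA when not certified).
#' @examples
#' uh_report(T = 0.5)   # certified, bound factor ~ 1.042
#' uh_report(T = 20)    # Xi = 20.8, not certified
#' @export
uh_report <- function(M = ad_matrix(), p = 1, q = 1, T = 20) {
  X <- lipschitz_constant(M)
  Xi <- xi_constant(p, q, T, X)
  C <- c_pq(p, q, T)
  certified <- Xi < 1
  structure(list(X_theta = X, T = T, p = p, q = q, Xi = Xi, C_pq = C,
                 certified = certified,
                 bound_factor = if (certified) C / (1 - Xi) else NA_real_),
            class = "uh_report")
}

#' @export
print.uh_report <- function(x, ...) {
  cat("Ulam-Hyers stability report\n")
  cat(sprintf("  p = %g, q = %g, horizon T = %g years\n", x$p, x$q, x$T))
  cat(sprintf("  Lipschitz constant X_theta : %.6g 1/year\n", x$X_theta))
  cat(sprintf("  contraction constant Xi    : %.6g\n", x$Xi))
  cat(sprintf("  perturbation factor C_pq   : %.6g\n", x$C_pq))
  if (x$certified) {
    cat(sprintf("  certificate                : Xi < 1 (uniqueness + UH stability)\n"))
    cat(sprintf("  stability bound factor     : %.6g\n", x$bound_factor))
  } else {
    cat("  certificate                : NOT certified (Xi >= 1);\n")
    cat("                               the contraction argument is inconclusive\n")
    cat("                               on this horizon; no bound factor.\n")
  }
  invisible(x)
}

# machine-readable key=value block for the CLI
format_uh_report <- function(x) {
  c(sprintf("X_theta=%.17g", x$X_theta),
    sprintf("T=%.17g", x$T),
    sprintf("p=%.17g", x$p),
    sprintf("q=%.17g", x$q),
    sprintf("Xi=%.17g", x$Xi),
    sprintf("C_pq=%.17g", x$C_pq),
    sprintf("certified=%s", tolower(as.character(x$certified))),
    if (x$certified) sprintf("bound_factor=%.17g", x$bound_factor))
}
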