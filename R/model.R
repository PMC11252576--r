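# Canonical compartment order used everywhere in the package:
# R  proliferative reactive astrocytes
# Q  quiescent (resting) astrocytes
# Abeta aggregation-prone amyloid-beta fibrils
# Ip activated microglia, pro-inflammatory state
# Ia activated microglia, anti-inflammatory state
# S  surviving neurons
# D  dead neurons
.compartments <- c("R", "Q", "Abeta", "Ip", "Ia", "S", "D")

.lambda_names <- c(paste0("lambda", 1:16), "lambdaR")

#' Default crosstalk rates of the Alzheimer's disease model
#'
#' The seventeen signed pathway rates of the seven-population
#' astrocyte/microglia/amyloid/neuron model, all in 1/year.  The defaults are
#' the published values for this system: \code{lambda1 = 1e-5} (Q activates S)
#' through \code{lambda16 = 1e-2} (Ia suppresses Abeta) and the amyloid
#' clearance rate \code{lambdaR = 1}.
#'
#' @param ... named overrides, e.g. \code{lambda15 = 0.5}.  Unknown names are
#'   an error; values must be finite and non-negative.
#' @return A named numeric vector of class \code{ad_parameters} with entries
#'   \code{lambda1 .. lambda16, lambdaR}.
#' @examples
#' p <- ad_parameters()
#' p[["lambda15"]]   # 1, the S -> Abeta production rate
#' ad_parameters(lambdaR = 2)[["lambdaR"]]
#' @export
ad_parameters <- function(...) {
  p <- c(lambda1 = 1e-5, lambda2 = 1e-3, lambda3 = 1e-2, lambda4 = 1e-4,
         lambda5 = 1e-2, lambda6 = 1e-2, lambda7 = 1e-4, lambda8 = 1e-2,
         lambda9 = 1e-2, lambda10 = 1e-2, lambda11 = 1e-2, lambda12 = 1e-4,
         lambda13 = 1e-2, lambda14 = 1e-4, lambda15 = 1, lambda16 = 1e-2,
         lambdaR = 1)
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("parameter overrides must be named")
    bad <- setdiff(names(ov), .lambda_names)
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    vals <- unlist(ov)
    if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals < 0))
      stop("all rates must be finite and non-negative")
    p[names(ov)] <- vals
  }
  structure(p, class = "ad_parameters")
}

#' Default initial populations
#'
#' The published time-zero populations used for the 20-year simulations:
#' R = 1e3, Q = 1e5, Abeta = 1e3, Ip = 1e3, Ia = 1e5, S = 1e4, D = 1e2.
#'
#' @return Named numeric vector in the canonical compartment order.
#' @export
ad_initial_state <- function() {
  c(R = 1e3, Q = 1e5, Abeta = 1e3, Ip = 1e3, Ia = 1e5, S = 1e4, D = 1e2)
}

.check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 7L)
    stop("state must be a numeric vector of length 7 (R, Q, Abeta, Ip, Ia, S, D)")
  if (any(!is.finite(state)))
    stop("state contains non-finite entries")
  invisible(state)
}

#' Right-hand side of the seven-population system
#'
#' Evaluates the instantaneous crosstalk rates (h1, ..., h7), in counts/year,
#' at a given state.  The astrocyte pair (R, Q), the microglia pair (Ip, Ia)
#' and the neuron pair (S, D) obey exact antisymmetry: h2 = -h1, h5 = -h4,
#' h7 = -h6.  The paired components are computed by explicit negation so the
#' antisymmetry holds bit-exactly in floating point, which is what makes the
#' three pair sums conserved to rounding error by any linear one-step update.
#'
#' @param state numeric length-7 state (R, Q, Abeta, Ip, Ia, S, D).
#' @param params an \code{\link{ad_parameters}} vector.
#' @return Named numeric length-7 rate vector.
#' @examples
#' h <- ad_rhs(ad_initial_state(), ad_parameters())
#' h[["R"]] + h[["Q"]]   # exactly 0
#' @export
ad_rhs <- function(state, params = ad_parameters()) {
  .check_state(state)
  p <- unclass(params)
  R <- state[[1]]; Q <- state[[2]]; Ab <- state[[3]]; Ip <- state[[4]]
  Ia <- state[[5]]; S <- state[[6]]; D <- state[[7]]
  h1 <- p[["lambda5"]] * Ip - p[["lambda4"]] * Ia
  h3 <- -p[["lambdaR"]] * Ab - p[["lambda16"]] * Ia + p[["lambda15"]] * S
  h4 <- -(p[["lambda7"]] + p[["lambda12"]]) * Q +
        (p[["lambda8"]] + p[["lambda13"]]) * Ab +
        p[["lambda9"]] * Ip - p[["lambda14"]] * Ia -
        (p[["lambda6"]] + p[["lambda11"]]) * S + p[["lambda10"]] * D
  h6 <- -p[["lambda2"]] * R + p[["lambda1"]] * Q - p[["lambda3"]] * Ip
  out <- c(h1, -h1, h3, h4, -h4, h6, -h6)
  names(out) <- .compartments
  out
}

#' Rate matrix of the linear system
#'
#' The model is linear: \code{ad_rhs(y, params)} equals \code{M \%*\% y} for
#' the 7x7 matrix returned here (rows and columns in the canonical order).
#' The paired rows (R, Q), (Ip, Ia) and (S, D) sum to zero exactly.
#'
#' @param params an \code{\link{ad_parameters}} vector.
#' @return A 7x7 numeric matrix with dimnames.
#' @export
ad_matrix <- function(params = ad_parameters()) {
  p <- unclass(params)
  M <- matrix(0, 7, 7, dimnames = list(.compartments, .compartments))
  # h1 = lambda5*Ip - lambda4*Ia
  M["R", "Ip"] <- p[["lambda5"]]
  M["R", "Ia"] <- -p[["lambda4"]]
  M["Q", ] <- -M["R", ]
  # h3 = -lambdaR*Abeta - lambda16*Ia + lambda15*S
  M["Abeta", "Abeta"] <- -p[["lambdaR"]]
  M["Abeta", "Ia"] <- -p[["lambda16"]]
  M["Abeta", "S"] <- p[["lambda15"]]
  # h4 = -(l7+l12)Q + (l8+l13)Abeta + l9*Ip - l14*Ia - (l6+l11)S + l10*D
  M["Ip", "Q"] <- -(p[["lambda7"]] + p[["lambda12"]])
  M["Ip", "Abeta"] <- p[["lambda8"]] + p[["lambda13"]]
  M["Ip", "Ip"] <- p[["lambda9"]]
  M["Ip", "Ia"] <- -p[["lambda14"]]
  M["Ip", "S"] <- -(p[["lambda6"]] + p[["lambda11"]])
  M["Ip", "D"] <- p[["lambda10"]]
  M["Ia", ] <- -M["Ip", ]
  # h6 = -lambda2*R + lambda1*Q - lambda3*Ip
  M["S", "R"] <- -p[["lambda2"]]
  M["S", "Q"] <- p[["lambda1"]]
  M["S", "Ip"] <- -p[["lambda3"]]
  M["D", ] <- -M["S", ]
  M
}

#' Conserved pair totals
#'
#' The antisymmetric structure conserves three totals: astrocytes (R + Q),
#' microglia (Ip + Ia) and neurons (S + D).  For any trajectory of the model
#' these stay at their time-zero values up to floating-point rounding.
#'
#' @param state numeric length-7 state, or a matrix with 7 such columns.
#' @return Named numeric vector (astro_total, microglia_total, neuron_total),
#'   or a 3-column matrix when \code{state} is a matrix.
#' @examples
#' conserved_sums(ad_initial_state())   # 101000 101000 10100
#' @export
conserved_sums <- function(state) {
  if (is.matrix(state)) {
    out <- cbind(astro_total = state[, 1] + state[, 2],
                 microglia_total = state[, 4] + state[, 5],
                 neuron_total = state[, 6] + state[, 7])
    return(out)
  }
  c(astro_total = state[[1]] + state[[2]],
    microglia_total = state[[4]] + state[[5]],
    neuron_total = state[[6]] + state[[7]])
}

#' @export
print.ad_parameters <- function(x, ...) {
  cat("Alzheimer's disease crosstalk rates (1/year)\n")
  print(unclass(x), ...)
  invisible(x)
}
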