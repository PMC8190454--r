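#' Analytic Jacobian of the core model
#'
#' The exact 6x6 Jacobian of [plasmid_rhs()] with respect to the six cell
#' densities, evaluated at `state`. Rows and columns follow the fixed
#' [CELL_TYPES] ordering. Hand-derived from the model equations; the test
#' suite validates it against central finite differences.
#'
#' @param state state vector of cell densities.
#' @param params a [plasmid_params] object.
#' @return A 6x6 numeric matrix with `CELL_TYPES` dimnames.
#' @examples
#' eigen(plasmid_jacobian(state_vector(), plasmid_params()))$values
#' @export
plasmid_jacobian <- function(state, params) {
  x <- unname(as_state(state))
  p <- params
  lam <- p$lambda; gam <- p$gamma; beta <- p$beta; s <- p$s; A <- p$A
  lamP <- (1 - p$cP) * lam
  lamR <- (1 - p$cR) * lam
  lamRP <- (1 - p$cR) * (1 - p$cP) * lam
  lamRRP <- (1 - p$cR)^2 * (1 - p$cP) * lam
  TT <- sum(x)
  P <- x[2] + x[3] + x[5] + x[6]
  J <- matrix(0, 6, 6, dimnames = list(CELL_TYPES, CELL_TYPES))

  J[1, 1] <- lam - beta * P - gam * TT - A - gam * x[1]
  J[1, 2] <- -(beta + gam) * x[1] + s * lamP
  J[1, 3] <- -(beta + gam) * x[1] + s * lamRP
  J[1, 4] <- -gam * x[1]
  J[1, 5] <- -(beta + gam) * x[1]
  J[1, 6] <- -(beta + gam) * x[1]

  J[2, 1] <- beta * (x[2] + x[5]) - gam * x[2]
  J[2, 2] <- (1 - s) * lamP - gam * TT - A - gam * x[2] + beta * x[1]
  J[2, 3] <- -gam * x[2]
  J[2, 4] <- -gam * x[2]
  J[2, 5] <- -gam * x[2] + beta * x[1]
  J[2, 6] <- -gam * x[2]

  J[3, 1] <- beta * (x[3] + x[6]) - gam * x[3]
  J[3, 2] <- -gam * x[3]
  J[3, 3] <- (1 - s) * lamRP - gam * TT - gam * x[3] + beta * x[1]
  J[3, 4] <- -gam * x[3]
  J[3, 5] <- -gam * x[3]
  J[3, 6] <- -gam * x[3] + beta * x[1]

  J[4, 1] <- -gam * x[4]
  J[4, 2] <- -(beta + gam) * x[4]
  J[4, 3] <- -(beta + gam) * x[4]
  J[4, 4] <- lamR - beta * P - gam * TT - gam * x[4]
  J[4, 5] <- -(beta + gam) * x[4] + s * lamRP
  J[4, 6] <- -(beta + gam) * x[4] + s * lamRRP

  J[5, 1] <- -gam * x[5]
  J[5, 2] <- -gam * x[5] + beta * x[4]
  J[5, 3] <- -gam * x[5]
  J[5, 4] <- -gam * x[5] + beta * (x[2] + x[5])
  J[5, 5] <- (1 - s) * lamRP - gam * TT - gam * x[5] + beta * x[4]
  J[5, 6] <- -gam * x[5]

  J[6, 1] <- -gam * x[6]
  J[6, 2] <- -gam * x[6]
  J[6, 3] <- -gam * x[6] + beta * x[4]
  J[6, 4] <- -gam * x[6] + beta * (x[3] + x[6])
  J[6, 5] <- -gam * x[6]
  J[6, 6] <- (1 - s) * lamRRP - gam * TT - gam * x[6] + beta * x[4]

  J
}
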