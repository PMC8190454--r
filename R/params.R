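#' Fixed cell-type ordering
#'
#' The six cell types of the model, in the ordering used by every function in
#' the package (state vectors, right-hand sides, Jacobians, eigenvalue
#' reports). The first letter denotes the chromosome (S = sensitive,
#' R = resistant), the second the plasmid (0 = no plasmid, S = sensitive
#' plasmid, R = resistant plasmid).
#'
#' @format A character vector of length 6:
#'   `c("S0", "SS", "SR", "R0", "RS", "RR")`.
#' @export
CELL_TYPES <- c("S0", "SS", "SR", "R0", "RS", "RR")

#' Model parameters
#'
#' Construct and validate the parameter set of the six-cell-type competition
#' model. Defaults are the reference parameterisation used throughout the
#' analyses.
#'
#' @param lambda replication rate (1/time).
#' @param gamma density-dependent death coefficient (volume cells^-1 time^-1).
#'   Death rate of every cell is `gamma * T`, `T` the total density.
#' @param A antibiotic-associated death rate (1/time), experienced only by
#'   cells with no resistance gene (types S0 and SS).
#' @param cR cost of carrying the resistance gene (dimensionless, in \[0, 1)):
#'   one copy multiplies the replication rate by `1 - cR`, two copies (type
#'   RR) by `(1 - cR)^2`.
#' @param cP cost of plasmid carriage (dimensionless, in \[0, 1)).
#' @param beta plasmid transmission (conjugation) rate
#'   (volume cells^-1 time^-1). Cells carry at most one plasmid, so only
#'   plasmid-free cells can be infected.
#' @param s segregation-loss probability (dimensionless, in \[0, 1\]): the
#'   probability that a daughter of a plasmid-bearing cell fails to inherit
#'   the plasmid.
#'
#' @return An object of class `plasmid_params`.
#' @examples
#' p <- plasmid_params()
#' p$beta
#' @export
plasmid_params <- function(lambda = 1, gamma = 1, A = 1, cR = 0.05,
                           cP = 0.075, beta = 0.2, s = 0.005) {
  check_num <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  for (nm in c("lambda", "gamma", "A", "cR", "cP", "beta", "s"))
    check_num(get(nm), nm)
  if (lambda <= 0) stop("'lambda' must be > 0", call. = FALSE)
  if (gamma <= 0) stop("'gamma' must be > 0", call. = FALSE)
  if (A < 0) stop("'A' must be >= 0", call. = FALSE)
  if (beta < 0) stop("'beta' must be >= 0", call. = FALSE)
  if (cR < 0 || cR >= 1) stop("'cR' must be in [0, 1)", call. = FALSE)
  if (cP < 0 || cP >= 1) stop("'cP' must be in [0, 1)", call. = FALSE)
  if (s < 0 || s > 1) stop("'s' must be in [0, 1]", call. = FALSE)
  structure(list(lambda = lambda, gamma = gamma, A = A, cR = cR, cP = cP,
                 beta = beta, s = s),
            class = "plasmid_params")
}

#' @export
print.plasmid_params <- function(x, ...) {
  cat("Six-type plasmid/chromosome competition model parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-7s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Build a state vector of cell densities
#'
#' @param S0,SS,SR,R0,RS,RR densities (cells/volume) of the six cell types;
#'   see [CELL_TYPES] for the naming convention.
#' @return A named numeric vector of length 6 in the fixed ordering.
#' @examples
#' state_vector(R0 = 0.95)
#' @export
state_vector <- function(S0 = 0, SS = 0, SR = 0, R0 = 0, RS = 0, RR = 0) {
  x <- c(S0 = S0, SS = SS, SR = SR, R0 = R0, RS = RS, RR = RR)
  as_state(x)
}

#' Coerce and validate a state vector
#'
#' Accepts a numeric vector of length 6 (named in any order using
#' [CELL_TYPES] names, or unnamed and assumed to be in the fixed ordering)
#' and returns it named and ordered.
#'
#' @param x numeric vector of length 6.
#' @return Named numeric vector in the [CELL_TYPES] ordering.
#' @export
as_state <- function(x) {
  if (!is.numeric(x) || length(x) != 6L)
    stop("a state vector must be numeric of length 6", call. = FALSE)
  if (!is.null(names(x))) {
    if (!setequal(names(x), CELL_TYPES))
      stop("state names must be exactly ", paste(CELL_TYPES, collapse = ", "),
           call. = FALSE)
    x <- x[CELL_TYPES]
  } else {
    names(x) <- CELL_TYPES
  }
  if (any(!is.finite(x))) stop("state densities must be finite", call. = FALSE)
  x
}

#' Derived replication rates and aggregate densities
#'
#' The cost-discounted replication rates and the aggregate densities used by
#' the model equations: `lamR = (1 - cR) * lambda` (chromosomal resistance),
#' `lamP = (1 - cP) * lambda` (plasmid carriage),
#' `lamRP = (1 - cR) * (1 - cP) * lambda` (one resistance copy plus plasmid),
#' `lamRRP = (1 - cR)^2 * (1 - cP) * lambda` (dual resistance: two copies,
#' dual cost, no added benefit); `T` the total density, `TPR` the total
#' density of cells carrying a resistant plasmid (SR + RR) and `TPS` of cells
#' carrying a sensitive plasmid (SS + RS).
#'
#' @param params a [plasmid_params] object.
#' @param state a state vector (see [as_state]).
#' @return A list with elements `lamR`, `lamP`, `lamRP`, `lamRRP`, `T`,
#'   `TPR`, `TPS`.
#' @examples
#' derived_rates(plasmid_params(), state_vector(S0 = 1, SR = 0.5))
#' @export
derived_rates <- function(params, state) {
  x <- as_state(state)
  lam <- params$lambda
  list(lamR = (1 - params$cR) * lam,
       lamP = (1 - params$cP) * lam,
       lamRP = (1 - params$cR) * (1 - params$cP) * lam,
       lamRRP = (1 - params$cR)^2 * (1 - params$cP) * lam,
       T = sum(x),
       TPR = x[["SR"]] + x[["RR"]],
       TPS = x[["SS"]] + x[["RS"]])
}
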