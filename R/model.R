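# Right-hand side of the six-type competition model and its structural
# generalisations. The core model and every variant share one internal
# implementation (.rhs_general) so that a variant with all knobs at their
# defaults reproduces the core derivative bitwise.

.default_variant <- function() {
  list(transposition_rate = 0,
       fluctuation = NULL,
       dual_cost_second_copy = NULL,   # NULL -> cR, giving (1 - cR)^2
       single_copy_protection = 1,
       segregation_mode = "at_replication",
       antibiotic_mode = "death",
       cost_mode = "growth")
}

# x: bare numeric state (fixed ordering), p: plasmid_params, v: variant list,
# t: time (used only by the fluctuating-antibiotic variant). No input checks:
# this is the hot path called by the ODE solvers.
.rhs_general <- function(x, p, v, t = 0) {
  lam <- p$lambda; gam <- p$gamma; beta <- p$beta; s <- p$s
  A <- p$A
  fl <- v$fluctuation
  if (!is.null(fl)) {
    A <- if ((t %% fl$period) < fl$duty * fl$period) fl$A_on else fl$A_off
  }
  d2 <- if (is.null(v$dual_cost_second_copy)) p$cR else v$dual_cost_second_copy
  # cost-discounted replication rates per type (S0, SS, SR, R0, RS, RR)
  g <- c(lam,
         (1 - p$cP) * lam,
         (1 - p$cR) * (1 - p$cP) * lam,
         (1 - p$cR) * lam,
         (1 - p$cR) * (1 - p$cP) * lam,
         (1 - p$cR) * (1 - d2) * (1 - p$cP) * lam)
  cdeath <- numeric(6)
  if (v$cost_mode == "death") {        # costs as added death, growth at lam
    cdeath <- lam - g
    g <- rep(lam, 6)
  }
  # antibiotic exposure per type; one resistance copy prevents a fraction
  # `single_copy_protection` of the antibiotic effect, two copies square it
  prot <- v$single_copy_protection
  aexp <- c(A, A, (1 - prot) * A, (1 - prot) * A, (1 - prot) * A,
            (1 - prot)^2 * A)
  adeath <- numeric(6)
  if (v$antibiotic_mode == "death") {
    adeath <- aexp
  } else {                             # growth_slowing
    g <- g * pmax(0, 1 - aexp / lam)
  }
  TT <- x[1] + x[2] + x[3] + x[4] + x[5] + x[6]
  P <- x[2] + x[3] + x[5] + x[6]       # plasmid-bearing total
  FS <- beta * (x[2] + x[5])           # infection force, sensitive plasmid
  FR <- beta * (x[3] + x[6])           # infection force, resistant plasmid
  if (v$segregation_mode == "at_replication") {
    # a fraction s of replications of plasmid bearers yields a plasmid-free
    # daughter of the same chromosomal type
    dx1 <- x[1] * (g[1] - beta * P - gam * TT - adeath[1] - cdeath[1]) +
      s * (g[2] * x[2] + g[3] * x[3])
    dx2 <- x[2] * ((1 - s) * g[2] - gam * TT - adeath[2] - cdeath[2]) + FS * x[1]
    dx3 <- x[3] * ((1 - s) * g[3] - gam * TT - adeath[3] - cdeath[3]) + FR * x[1]
    dx4 <- x[4] * (g[4] - beta * P - gam * TT - adeath[4] - cdeath[4]) +
      s * (g[5] * x[5] + g[6] * x[6])
    dx5 <- x[5] * ((1 - s) * g[5] - gam * TT - adeath[5] - cdeath[5]) + FS * x[4]
    dx6 <- x[6] * ((1 - s) * g[6] - gam * TT - adeath[6] - cdeath[6]) + FR * x[4]
  } else {                             # independent_rate: standalone loss
    # plasmid loss as a constant per-capita rate s * lambda decoupled from
    # the type's (cost-modified) replication rate; the cell survives and
    # joins the plasmid-free class. Agrees with the default bookkeeping to
    # first order: the per-type difference is s * (lam - g_type), i.e.
    # O(s * cost).
    sl <- s * lam
    dx1 <- x[1] * (g[1] - beta * P - gam * TT - adeath[1] - cdeath[1]) +
      sl * (x[2] + x[3])
    dx2 <- x[2] * (g[2] - gam * TT - adeath[2] - cdeath[2] - sl) + FS * x[1]
    dx3 <- x[3] * (g[3] - gam * TT - adeath[3] - cdeath[3] - sl) + FR * x[1]
    dx4 <- x[4] * (g[4] - beta * P - gam * TT - adeath[4] - cdeath[4]) +
      sl * (x[5] + x[6])
    dx5 <- x[5] * (g[5] - gam * TT - adeath[5] - cdeath[5] - sl) + FS * x[4]
    dx6 <- x[6] * (g[6] - gam * TT - adeath[6] - cdeath[6] - sl) + FR * x[4]
  }
  tau <- v$transposition_rate
  if (tau > 0) {
    # within-cell relocation of the resistance gene between replicons:
    # SR (gene on plasmid) <-> RS (gene on chromosome), equal rates
    flow <- tau * (x[5] - x[3])
    dx3 <- dx3 + flow
    dx5 <- dx5 - flow
  }
  c(dx1, dx2, dx3, dx4, dx5, dx6)
}

#' Time derivatives of the six-type competition model
#'
#' The right-hand side of the core ODE system: replication discounted by the
#' fitness costs of resistance and plasmid carriage (and by segregation loss
#' `1 - s` for plasmid bearers), density-dependent death `gamma * T`,
#' antibiotic-associated death `A` acting on the two fully susceptible types
#' (S0, SS), density-dependent plasmid transmission `beta` with
#' single-plasmid exclusion (only plasmid-free cells can be infected), and
#' the segregation influx `s * g * N` of plasmid-free daughters.
#'
#' @param state state vector of cell densities (see [as_state]); all
#'   densities must be non-negative.
#' @param params a [plasmid_params] object.
#' @param t time. Accepted (and ignored by the autonomous core model) so that
#'   time-dependent variants share the same signature.
#' @return Named numeric vector of the six time derivatives.
#' @examples
#' plasmid_rhs(state_vector(R0 = 0.5), plasmid_params())
#' @seealso [plasmid_rhs_variant()], [plasmid_rhs_migration()],
#'   [plasmid_jacobian()]
#' @export
plasmid_rhs <- function(state, params, t = 0) {
  x <- as_state(state)
  if (any(x < 0)) stop("cell densities must be non-negative", call. = FALSE)
  out <- .rhs_general(unname(x), params, .default_variant(), t)
  names(out) <- CELL_TYPES
  out
}
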