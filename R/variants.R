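#' Immigration (local adaptation) parameters
#'
#' Constant influx of sensitive cells into the modeled environment,
#' representing a local niche in which the resistance gene is beneficial
#' while immigrants come from outside, where it is not selected. Immigrants
#' are chromosomally sensitive; a fraction `f_imm` of them carry the
#' sensitive plasmid.
#'
#' @param mu influx rate (cells volume^-1 time^-1).
#' @param f_imm frequency of the sensitive plasmid among immigrants, in
#'   \[0, 1\].
#' @return A list of class `migration_params`.
#' @export
migration_params <- function(mu, f_imm) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0,
            is.numeric(f_imm), length(f_imm) == 1L, f_imm >= 0, f_imm <= 1)
  structure(list(mu = mu, f_imm = f_imm), class = "migration_params")
}

#' Structural variant configuration
#'
#' Knobs for the sensitivity analyses of the model structure. With every
#' knob at its default the variant reproduces the core model exactly.
#'
#' @param transposition_rate per-cell rate of resistance-gene relocation
#'   between replicons (SR <-> RS, equal rates both ways).
#' @param fluctuation NULL for constant antibiotic pressure, or a list
#'   `list(period, duty, A_on, A_off)` replacing the constant `A` with a
#'   square wave: `A_on` for the first `duty` fraction of each period,
#'   `A_off` for the rest.
#' @param dual_cost_second_copy cost factor of the second resistance copy;
#'   `NULL` means `cR`, i.e. the default dual cost `(1 - cR)^2`. Setting it
#'   to 0 removes the extra cost of dual resistance.
#' @param single_copy_protection fraction of the antibiotic effect prevented
#'   by one resistance copy (default 1: full protection). Below 1, single
#'   resistance leaves residual exposure `(1 - protection) * A` and dual
#'   resistance `(1 - protection)^2 * A`, so a second copy has residual
#'   benefit.
#' @param segregation_mode `"at_replication"` (default: a fraction `s` of
#'   replications of plasmid bearers yields a plasmid-free daughter, so loss
#'   scales with the type's cost-modified replication rate) or
#'   `"independent_rate"` (plasmid loss as a standalone per-capita rate
#'   `s * lambda`, decoupled from replication; differs from the default at
#'   order `s * cost`).
#' @param antibiotic_mode `"death"` (default: added death rate) or
#'   `"growth_slowing"` (the susceptible replication rate is multiplied by
#'   `1 - A / lambda`, clamped at 0 — calibrated so the susceptible-alone
#'   equilibrium density matches the death formulation whenever
#'   `A < lambda`).
#' @param cost_mode `"growth"` (default: costs discount the replication
#'   rate) or `"death"` (the same per-capita fitness deficit is charged as
#'   an added death rate while every type replicates at `lambda`).
#' @return A list of class `variant_config`.
#' @export
variant_config <- function(transposition_rate = 0,
                           fluctuation = NULL,
                           dual_cost_second_copy = NULL,
                           single_copy_protection = 1,
                           segregation_mode = c("at_replication",
                                                "independent_rate"),
                           antibiotic_mode = c("death", "growth_slowing"),
                           cost_mode = c("growth", "death")) {
  stopifnot(transposition_rate >= 0,
            single_copy_protection >= 0, single_copy_protection <= 1)
  if (!is.null(dual_cost_second_copy))
    stopifnot(dual_cost_second_copy >= 0, dual_cost_second_copy < 1)
  if (!is.null(fluctuation)) {
    stopifnot(is.list(fluctuation),
              all(c("period", "duty", "A_on", "A_off") %in% names(fluctuation)))
    stopifnot(fluctuation$period > 0, fluctuation$duty >= 0,
              fluctuation$duty <= 1, fluctuation$A_on >= 0,
              fluctuation$A_off >= 0)
  }
  structure(list(transposition_rate = transposition_rate,
                 fluctuation = fluctuation,
                 dual_cost_second_copy = dual_cost_second_copy,
                 single_copy_protection = single_copy_protection,
                 segregation_mode = match.arg(segregation_mode),
                 antibiotic_mode = match.arg(antibiotic_mode),
                 cost_mode = match.arg(cost_mode)),
            class = "variant_config")
}

#' Core model plus immigration of sensitive cells
#'
#' [plasmid_rhs()] with an added constant influx `mu * (1 - f_imm)` into S0
#' and `mu * f_imm` into SS. There is no emigration term.
#'
#' @inheritParams plasmid_rhs
#' @param migration a [migration_params()] object.
#' @return Named numeric vector of the six time derivatives.
#' @export
plasmid_rhs_migration <- function(state, params, migration, t = 0) {
  out <- plasmid_rhs(state, params, t)
  out[["S0"]] <- out[["S0"]] + migration$mu * (1 - migration$f_imm)
  out[["SS"]] <- out[["SS"]] + migration$mu * migration$f_imm
  out
}

#' Time derivatives under a structural variant
#'
#' @inheritParams plasmid_rhs
#' @param variant a [variant_config()] object.
#' @return Named numeric vector of the six time derivatives. With all knobs
#'   at their defaults this is bitwise identical to [plasmid_rhs()].
#' @export
plasmid_rhs_variant <- function(state, params, variant, t = 0) {
  x <- as_state(state)
  if (any(x < 0)) stop("cell densities must be non-negative", call. = FALSE)
  out <- .rhs_general(unname(x), params, variant, t)
  names(out) <- CELL_TYPES
  out
}

#' Finite-difference Jacobian of a variant model
#'
#' Central-difference Jacobian (via [pracma::jacobian()]) of the autonomous
#' variant right-hand side at a state. Used for stability analysis of
#' variants, whose Jacobians are not hand-coded.
#'
#' @param state state vector.
#' @param params a [plasmid_params] object.
#' @param variant a [variant_config()] object (must be autonomous, i.e. no
#'   fluctuation).
#' @return A 6x6 numeric matrix.
#' @export
variant_jacobian <- function(state, params, variant) {
  if (!is.null(variant$fluctuation))
    stop("Jacobian-based stability analysis does not apply to the ",
         "non-autonomous fluctuating-antibiotic variant", call. = FALSE)
  f <- function(y) .rhs_general(y, params, variant, 0)
  J <- pracma::jacobian(f, unname(as_state(state)))
  dimnames(J) <- list(CELL_TYPES, CELL_TYPES)
  J
}

# Damped-Newton refinement of an equilibrium of the variant model, restricted
# to the support (nonzero pattern) of the core equilibrium used as the start.
.refine_variant_equilibrium <- function(state, params, variant,
                                        tol = 1e-12, max_iter = 40) {
  x <- as_state(state)
  nz <- which(x > 0)
  for (it in seq_len(max_iter)) {
    f <- .rhs_general(unname(x), params, variant, 0)
    if (max(abs(f[nz])) < tol) return(x)
    J <- variant_jacobian(x, params, variant)
    step <- tryCatch(solve(J[nz, nz, drop = FALSE], f[nz]),
                     error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {                            # damping: keep the support positive
      cand <- x
      cand[nz] <- x[nz] - lam * step
      if (all(cand[nz] > 0)) break
      lam <- lam / 2
      if (lam < 1e-6) return(NULL)
    }
    x <- cand
  }
  f <- .rhs_general(unname(x), params, variant, 0)
  if (max(abs(f[nz])) < tol) x else NULL
}

#' Stability of a candidate equilibrium under a structural variant
#'
#' Starts from the core model's reduced equilibrium, refines it into the
#' corresponding equilibrium of the variant model (damped Newton on the
#' equilibrium's support — a no-op for variants such as the dual-resistance
#' knobs, which modify only RR terms and leave RR-free equilibria fixed),
#' and evaluates the variant Jacobian there.
#'
#' @inheritParams stability
#' @param variant a [variant_config()] object.
#' @param residual_tol maximum tolerated variant-rhs residual at the refined
#'   equilibrium.
#' @return A `stability_result` (see [stability()]).
#' @export
variant_stability <- function(params, label, variant, tol = 1e-9,
                              residual_tol = 1e-10) {
  eq <- reduced_equilibrium(params, label)
  if (!eq$exists) {
    return(structure(list(label = label, applicable = FALSE, equilibrium = eq,
                          eigenvalues = NULL, max_re = NA_real_,
                          stable = NA, marginal = NA, tol = tol),
                     class = "stability_result"))
  }
  st <- eq$state
  if (max(abs(plasmid_rhs_variant(st, params, variant))) > residual_tol) {
    st <- .refine_variant_equilibrium(st, params, variant, tol = residual_tol)
    if (is.null(st))
      stop("could not refine the '", label, "' equilibrium under this ",
           "variant (Newton did not converge)", call. = FALSE)
    eq$state <- st
    eq$residual <- max(abs(plasmid_rhs_variant(st, params, variant)))
    # a small residual outside the support (e.g. the transposition leak out
    # of an equilibrium that excludes one form) is tolerated: the true
    # equilibrium is then an O(rate) perturbation of the reported one
    slack <- max(1e-8, 2 * variant$transposition_rate * sum(st))
    if (eq$residual > slack)
      stop("'", label, "' is not an equilibrium of this variant ",
           "(residual ", format(eq$residual), ")", call. = FALSE)
  }
  J <- variant_jacobian(st, params, variant)
  ev <- eigen(J, only.values = TRUE)$values
  mr <- max(Re(ev))
  structure(list(label = label, applicable = TRUE, equilibrium = eq,
                 eigenvalues = ev, max_re = mr,
                 stable = mr < -tol, marginal = abs(mr) <= tol, tol = tol),
            class = "stability_result")
}

#' Outcome map for the immigration experiment
#'
#' The initial population is fully resistant with total density 1, split
#' between plasmid-borne (SR) and chromosomal resistance by the y-axis
#' frequency `y = SR / (SR + RS)`; chromosomally resistant cells carry the
#' sensitive plasmid. Sensitive cells flow in at rate `mu` with sensitive-
#' plasmid frequency `f_imm` (x-axis). Each grid cell is integrated to
#' equilibrium and classified.
#'
#' @param params a [plasmid_params] object.
#' @param mu influx rate.
#' @param n grid resolution for both axes.
#' @param settings a [sim_settings] object.
#' @return data.frame with columns `f_imm`, `y`, `outcome` and attribute
#'   `mu`.
#' @export
migration_outcome_map <- function(params = plasmid_params(), mu = 0.1,
                                  n = 41, settings = sim_settings()) {
  fr <- seq(0, 1, length.out = n)
  grid <- expand.grid(f_imm = fr, y = fr, KEEP.OUT.ATTRS = FALSE)
  outcome <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    mig <- migration_params(mu, grid$f_imm[i])
    state0 <- state_vector(SR = grid$y[i], RS = 1 - grid$y[i])
    outcome[i] <- tryCatch(
      classify_outcome(integrate_model(state0, params, settings,
                                       migration = mig),
                       settings$round_tol),
      error = function(e) "error")
  }
  out <- data.frame(f_imm = grid$f_imm, y = grid$y, outcome = outcome,
                    stringsAsFactors = FALSE)
  attr(out, "mu") <- mu
  out
}

# Piecewise integration of the square-wave antibiotic model: each on/off
# segment is integrated as an autonomous constant-A system, avoiding solver
# trouble at the discontinuities.
.integrate_squarewave <- function(state0, params, period, duty, A_on, A_off,
                                  n_periods, settings) {
  y <- as_state(state0)
  base <- unclass(params)
  for (k in seq_len(n_periods)) {
    for (seg in list(c(A_on, duty * period), c(A_off, (1 - duty) * period))) {
      if (seg[2] <= 0) next
      base$A <- seg[1]
      p <- do.call(plasmid_params, base)
      f <- .make_ode_func(p)
      out <- deSolve::lsoda(y = y, times = c(0, seg[2]), func = f,
                            parms = NULL, rtol = settings$rtol,
                            atol = settings$atol)
      y <- out[nrow(out), 1 + seq_len(6)]
      y[y < 0] <- 0
      names(y) <- CELL_TYPES
    }
  }
  y[y < settings$round_tol] <- 0
  y
}

#' Persistence of each resistance form under fluctuating antibiotic pressure
#'
#' For each period of a square-wave antibiotic input, starts the system at
#' the constant-pressure equilibrium of each resistance form (computed at
#' `A_on`) plus a small inoculum of the competing form, integrates over
#' `n_periods` periods, and records the outcome. Because the system is
#' non-autonomous, persistence is assessed by simulation rather than by
#' eigenvalues.
#'
#' @param params a [plasmid_params] object (its `A` is ignored in favour of
#'   `A_on`/`A_off`).
#' @param periods numeric vector of square-wave periods (time units).
#' @param duty fraction of each period with antibiotic on.
#' @param A_on,A_off antibiotic death rates in the on/off phases.
#' @param n_periods number of periods to simulate.
#' @param inoculum density of the competing form added at start.
#' @param settings a [sim_settings] object.
#' @return data.frame with columns `period`, `resident`, `outcome`,
#'   `resident_persists`.
#' @export
fluctuation_experiment <- function(params = plasmid_params(),
                                   periods, duty = 0.5,
                                   A_on = params$A, A_off = 0,
                                   n_periods = 50, inoculum = 1e-6,
                                   settings = sim_settings()) {
  base <- unclass(params)
  base$A <- A_on
  p_on <- do.call(plasmid_params, base)
  chrom_label <- if (reduced_equilibrium(p_on,
                                         "chromosomal_with_plasmid")$exists)
    "chromosomal_with_plasmid" else "chromosomal_no_plasmid"
  residents <- list(
    chromosomal = list(label = chrom_label, invader = "SR"),
    plasmid_borne = list(label = "plasmid_borne", invader = "R0"))
  rows <- list()
  for (per in periods) {
    for (nm in names(residents)) {
      r <- residents[[nm]]
      eq <- reduced_equilibrium(p_on, r$label)
      if (!eq$exists) {
        rows[[length(rows) + 1L]] <- data.frame(
          period = per, resident = nm, outcome = "not_applicable",
          resident_persists = NA)
        next
      }
      y0 <- eq$state
      y0[[r$invader]] <- y0[[r$invader]] + inoculum
      fin <- .integrate_squarewave(y0, params, per, duty, A_on, A_off,
                                   n_periods, settings)
      res_dens <- switch(nm,
                         chromosomal = fin[["R0"]] + fin[["RS"]] + fin[["RR"]],
                         plasmid_borne = fin[["SR"]] + fin[["RR"]])
      rows[[length(rows) + 1L]] <- data.frame(
        period = per, resident = nm,
        outcome = classify_outcome(fin, settings$round_tol),
        resident_persists = res_dens > 1e-6)
    }
  }
  do.call(rbind, rows)
}
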