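#' Candidate equilibrium labels
#'
#' The five boundary equilibria considered in the stability analysis.
#' Coexistence of sensitive and resistant variants of the same replicon, and
#' equilibria containing dually resistant cells (RR), are excluded by
#' competitive-exclusion and dominance arguments (dual resistance pays a dual
#' cost for no added benefit); the numerical attractor scan
#' ([attractor_scan()]) guards against overlooked attractors.
#'
#' @format Character vector of length 5.
#' @export
EQUILIBRIUM_LABELS <- c("sensitive_no_plasmid", "sensitive_with_plasmid",
                        "chromosomal_no_plasmid", "chromosomal_with_plasmid",
                        "plasmid_borne")

# Steady state of the reduced two-type subsystem consisting of a plasmid-free
# host X0 (replication lam0, antibiotic death A0) and a plasmid-bearing type
# XP (replication lamp, antibiotic death Ap) of the same chromosomal
# background. Setting dXP/dt = 0 for XP > 0 gives
#   gamma * T = (1 - s) * lamp - Ap + beta * X0,
# i.e. XP = a + b * X0 with a = ((1 - s) * lamp - Ap) / gamma and
# b = (beta - gamma) / gamma. Substituting into dX0/dt = 0 yields a quadratic
# in X0 with leading coefficient -beta^2 / gamma:
#   -(beta^2 / gamma) X0^2
#   + (lam0 - A0 - (beta + gamma) a + s lamp b) X0 + s lamp a = 0.
# Returns c(X0, XP) for the admissible root (both strictly positive), or NULL.
.two_type_equilibrium <- function(p, lam0, A0, lamp, Ap) {
  gam <- p$gamma; beta <- p$beta; s <- p$s
  a <- ((1 - s) * lamp - Ap) / gam
  b <- (beta - gam) / gam
  c2 <- -beta^2 / gam
  c1 <- (lam0 - A0) - (beta + gam) * a + s * lamp * b
  c0 <- s * lamp * a
  pos <- 1e-12
  if (abs(c2) < 1e-300) {                     # beta = 0: linear equation
    if (abs(c1) < 1e-300) return(NULL)
    roots <- -c0 / c1
  } else {
    disc <- c1^2 - 4 * c2 * c0
    if (disc < 0) return(NULL)
    sq <- sqrt(disc)
    roots <- c((-c1 + sq) / (2 * c2), (-c1 - sq) / (2 * c2))
  }
  for (X0 in sort(roots, decreasing = TRUE)) {
    XP <- a + b * X0
    if (is.finite(X0) && X0 > pos && XP > pos) return(c(X0, XP))
  }
  NULL
}

#' Equilibrium of a reduced subsystem
#'
#' Computes the candidate equilibrium named by `label` by setting every other
#' cell type to zero and solving the reduced system in closed form. The
#' single-type equilibria are `S0 = (lambda - A) / gamma` (sensitive, no
#' plasmid; exists only when `A < lambda`) and
#' `R0 = (1 - cR) * lambda / gamma` (chromosomal resistance, no plasmid).
#' The two-type equilibria (host plus plasmid) reduce to a quadratic in the
#' plasmid-free density (see source). The residual of the full model's
#' right-hand side at the returned state is checked against `residual_tol`.
#'
#' @param params a [plasmid_params] object.
#' @param label one of [EQUILIBRIUM_LABELS].
#' @param residual_tol maximum tolerated `max(abs(plasmid_rhs))` at a state
#'   reported as existing.
#' @return An object of class `equilibrium_point`: a list with `label`,
#'   `state` (the full six-type state vector), `exists` (TRUE iff a steady
#'   state with the required strictly positive components was found) and
#'   `residual`.
#' @examples
#' reduced_equilibrium(plasmid_params(), "chromosomal_no_plasmid")$state
#' @export
reduced_equilibrium <- function(params, label,
                                residual_tol = 1e-10) {
  label <- match.arg(label, EQUILIBRIUM_LABELS)
  p <- params
  lam <- p$lambda
  lamR <- (1 - p$cR) * lam
  lamP <- (1 - p$cP) * lam
  lamRP <- (1 - p$cR) * (1 - p$cP) * lam
  state <- state_vector()
  exists <- FALSE
  if (label == "sensitive_no_plasmid") {
    n <- (lam - p$A) / p$gamma
    if (n > 0) { state[["S0"]] <- n; exists <- TRUE }
  } else if (label == "chromosomal_no_plasmid") {
    n <- lamR / p$gamma
    if (n > 0) { state[["R0"]] <- n; exists <- TRUE }
  } else if (label == "chromosomal_with_plasmid") {
    eq <- .two_type_equilibrium(p, lam0 = lamR, A0 = 0, lamp = lamRP, Ap = 0)
    if (!is.null(eq)) { state[["R0"]] <- eq[1]; state[["RS"]] <- eq[2]; exists <- TRUE }
  } else if (label == "plasmid_borne") {
    eq <- .two_type_equilibrium(p, lam0 = lam, A0 = p$A, lamp = lamRP, Ap = 0)
    if (!is.null(eq)) { state[["S0"]] <- eq[1]; state[["SR"]] <- eq[2]; exists <- TRUE }
  } else if (label == "sensitive_with_plasmid") {
    eq <- .two_type_equilibrium(p, lam0 = lam, A0 = p$A, lamp = lamP, Ap = p$A)
    if (!is.null(eq)) { state[["S0"]] <- eq[1]; state[["SS"]] <- eq[2]; exists <- TRUE }
  }
  residual <- if (exists) max(abs(plasmid_rhs(state, p))) else NA_real_
  if (exists && residual > residual_tol)
    stop("equilibrium solver did not converge for '", label,
         "' (residual ", format(residual), ")", call. = FALSE)
  structure(list(label = label, state = state, exists = exists,
                 residual = residual),
            class = "equilibrium_point")
}

#' Linear stability of a candidate equilibrium in the full model
#'
#' Evaluates the full six-dimensional Jacobian at the reduced equilibrium
#' named by `label` and reports its eigenvalues. The equilibrium is called
#' stable when all six real parts are below `-tol`; a spectrum whose largest
#' real part lies within `tol` of zero is flagged marginal and counted as
#' neither stable nor unstable.
#'
#' @param params a [plasmid_params] object.
#' @param label one of [EQUILIBRIUM_LABELS].
#' @param tol numerical guard on "negative real part" (1/time).
#' @param jacobian_fn function `(state, params) -> 6x6 matrix`; defaults to
#'   the analytic [plasmid_jacobian()]. Variants supply their own (see
#'   [variant_stability()]).
#' @return An object of class `stability_result`: list with `label`,
#'   `applicable` (FALSE when the equilibrium does not exist), `equilibrium`,
#'   `eigenvalues` (complex, length 6), `max_re`, `stable`, `marginal`,
#'   `tol`.
#' @examples
#' stability(plasmid_params(), "chromosomal_with_plasmid")$stable
#' @export
stability <- function(params, label, tol = 1e-9, jacobian_fn = NULL) {
  eq <- reduced_equilibrium(params, label)
  if (!eq$exists) {
    return(structure(list(label = label, applicable = FALSE, equilibrium = eq,
                          eigenvalues = NULL, max_re = NA_real_,
                          stable = NA, marginal = NA, tol = tol),
                     class = "stability_result"))
  }
  J <- if (is.null(jacobian_fn)) plasmid_jacobian(eq$state, params)
       else jacobian_fn(eq$state, params)
  ev <- eigen(J, only.values = TRUE)$values
  mr <- max(Re(ev))
  structure(list(label = label, applicable = TRUE, equilibrium = eq,
                 eigenvalues = ev, max_re = mr,
                 stable = mr < -tol, marginal = abs(mr) <= tol, tol = tol),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Stability of '", x$label, "': ", sep = "")
  if (!x$applicable) {
    cat("not applicable (equilibrium does not exist)\n")
  } else {
    verdict <- if (x$marginal) "marginal" else if (x$stable) "stable" else "unstable"
    cat(verdict, sprintf(" (max Re eigenvalue = %.3e)\n", x$max_re))
  }
  invisible(x)
}

#' Invasion growth rate of a rare type at a resident equilibrium
#'
#' At a boundary equilibrium the Jacobian block of the absent cell types is
#' decoupled from the resident directions, so its eigenvalues are the linear
#' growth rates of rare invaders. This function restricts that block further
#' to the set of absent types dynamically reachable from a given inoculated
#' type (following the nonzero entries of the block as a directed graph) and
#' returns its dominant growth rate: positive means the inoculum invades.
#'
#' @param params a [plasmid_params] object.
#' @param resident label of the resident equilibrium (must exist).
#' @param invader cell type (one of [CELL_TYPES]) absent from the resident.
#' @return The maximal real part of the reachable invasion block (1/time),
#'   with attributes `types` (the reachable absent types) and `eigenvalues`.
#' @examples
#' invasion_eigenvalue(plasmid_params(), "plasmid_borne", "R0")
#' @export
invasion_eigenvalue <- function(params, resident, invader) {
  eq <- reduced_equilibrium(params, resident)
  if (!eq$exists)
    stop("resident equilibrium '", resident, "' does not exist", call. = FALSE)
  invader <- match.arg(invader, CELL_TYPES)
  zero_idx <- which(eq$state <= 0)
  if (!(invader %in% CELL_TYPES[zero_idx]))
    stop("invader '", invader, "' is part of the resident equilibrium",
         call. = FALSE)
  J <- plasmid_jacobian(eq$state, params)
  Jz <- J[zero_idx, zero_idx, drop = FALSE]
  start <- match(invader, CELL_TYPES[zero_idx])
  reach <- start
  repeat {
    fed <- which(rowSums(abs(Jz[, reach, drop = FALSE]) > 1e-14) > 0)
    nxt <- union(reach, fed)
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  sub <- Jz[reach, reach, drop = FALSE]
  ev <- eigen(sub, only.values = TRUE)$values
  structure(max(Re(ev)),
            types = CELL_TYPES[zero_idx][reach], eigenvalues = ev)
}

#' Classify the evolutionary regime at a parameter point
#'
#' Combines the stability verdicts of the three resistance-carrying candidate
#' equilibria: `bistable` when both a chromosomal equilibrium (with or
#' without the sensitive plasmid) and the plasmid-borne equilibrium are
#' stable; `chromosomal_only` / `plasmid_only` when only one side is;
#' `no_resistance` when neither. For chromosomal regimes,
#' `plasmid_presence` records whether the stable chromosomal equilibrium
#' carries the sensitive plasmid.
#'
#' @param params a [plasmid_params] object.
#' @param tol eigenvalue tolerance passed to [stability()].
#' @param variant optional [variant_config()]; when given, stability is
#'   assessed with the variant's (finite-difference) Jacobian via
#'   [variant_stability()].
#' @return List with `regime`, `plasmid_presence` (`"present"`, `"absent"` or
#'   `NA`), `stability` (the three `stability_result`s) and `needs_review`
#'   (TRUE when no candidate equilibrium is stable and neither the sensitive
#'   equilibria nor extinction are stable either).
#' @examples
#' classify_regime(plasmid_params())$regime
#' @export
classify_regime <- function(params, tol = 1e-9, variant = NULL) {
  st <- function(lbl) {
    if (is.null(variant)) stability(params, lbl, tol)
    else variant_stability(params, lbl, variant, tol)
  }
  cwp <- st("chromosomal_with_plasmid")
  cnp <- st("chromosomal_no_plasmid")
  pb <- st("plasmid_borne")
  chrom <- isTRUE(cwp$stable) || isTRUE(cnp$stable)
  plas <- isTRUE(pb$stable)
  regime <- if (chrom && plas) "bistable"
            else if (chrom) "chromosomal_only"
            else if (plas) "plasmid_only"
            else "no_resistance"
  presence <- if (isTRUE(cwp$stable)) "present"
              else if (isTRUE(cnp$stable)) "absent"
              else NA_character_
  needs_review <- FALSE
  if (regime == "no_resistance") {
    snp <- st("sensitive_no_plasmid")
    swp <- st("sensitive_with_plasmid")
    ext <- eigen(plasmid_jacobian(state_vector(), params),
                 only.values = TRUE)$values
    ext_stable <- max(Re(ext)) < -tol
    needs_review <- !isTRUE(snp$stable) && !isTRUE(swp$stable) && !ext_stable
  }
  list(regime = regime, plasmid_presence = presence,
       stability = list(chromosomal_with_plasmid = cwp,
                        chromosomal_no_plasmid = cnp,
                        plasmid_borne = pb),
       needs_review = needs_review)
}

#' Define a sweep axis
#'
#' @param name a [plasmid_params] field name.
#' @param from,to range of values.
#' @param n number of grid points.
#' @return List with `name` and `values` for [phase_sweep()].
#' @export
sweep_axis <- function(name, from, to, n = 61) {
  name <- match.arg(name, c("lambda", "gamma", "A", "cR", "cP", "beta", "s"))
  list(name = name, values = seq(from, to, length.out = n))
}

#' Two-parameter regime sweep (phase diagram)
#'
#' Runs [classify_regime()] on the Cartesian grid of two parameter axes and
#' returns a tidy table, one row per grid point. Failures at individual
#' points are recorded as regime `"error"` rather than aborting the sweep.
#'
#' @param base a [plasmid_params] object supplying all off-axis values.
#' @param axis1,axis2 axes built with [sweep_axis()] (or lists with `name`
#'   and `values`); must name two distinct parameters.
#' @param tol eigenvalue tolerance.
#' @param variant optional [variant_config()] applied at every point.
#' @return A data.frame with columns `<axis1 name>`, `<axis2 name>`,
#'   `regime`, `plasmid_presence`, `needs_review`, and the max real
#'   eigenvalue of each candidate (`max_re_chromosomal_with_plasmid`,
#'   `max_re_chromosomal_no_plasmid`, `max_re_plasmid_borne`).
#' @examples
#' phase_sweep(plasmid_params(),
#'             sweep_axis("A", 0.5, 1.5, 3), sweep_axis("cR", 0, 0.2, 3))
#' @export
phase_sweep <- function(base, axis1, axis2, tol = 1e-9, variant = NULL) {
  stopifnot(axis1$name != axis2$name)
  grid <- expand.grid(v1 = axis1$values, v2 = axis2$values,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  regime <- character(n); presence <- character(n); review <- logical(n)
  mre <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    res <- tryCatch({
      args <- unclass(base)
      args[[axis1$name]] <- grid$v1[i]
      args[[axis2$name]] <- grid$v2[i]
      p <- do.call(plasmid_params, args)
      classify_regime(p, tol, variant)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      regime[i] <- "error"; presence[i] <- NA_character_; review[i] <- TRUE
    } else {
      regime[i] <- res$regime
      presence[i] <- res$plasmid_presence
      review[i] <- res$needs_review
      mre[i, ] <- c(res$stability$chromosomal_with_plasmid$max_re,
                    res$stability$chromosomal_no_plasmid$max_re,
                    res$stability$plasmid_borne$max_re)
    }
  }
  out <- data.frame(grid$v1, grid$v2, regime, presence, review,
                    mre[, 1], mre[, 2], mre[, 3],
                    stringsAsFactors = FALSE)
  names(out) <- c(axis1$name, axis2$name, "regime", "plasmid_presence",
                  "needs_review", "max_re_chromosomal_with_plasmid",
                  "max_re_chromosomal_no_plasmid", "max_re_plasmid_borne")
  out
}

#' Can a sensitive plasmid persist as a pure parasite?
#'
#' TRUE when a rare sensitive plasmid invades the plasmid-free sensitive
#' population at its carrying capacity, i.e. the SS-invasion growth rate at
#' the sensitive/no-plasmid equilibrium is positive. Used to contrast
#' parasitic persistence with the evolutionary stability of plasmid-borne
#' resistance: the two need not coincide.
#'
#' @param params a [plasmid_params] object.
#' @param tol eigenvalue tolerance.
#' @return TRUE/FALSE, or NA (with attribute `reason`) when sensitive cells
#'   are not viable at all (`A >= lambda`), in which case the question does
#'   not apply.
#' @examples
#' parasite_persistence(plasmid_params(A = 0, s = 0, cP = 0))
#' @export
parasite_persistence <- function(params, tol = 1e-9) {
  eq <- reduced_equilibrium(params, "sensitive_no_plasmid")
  if (!eq$exists) {
    return(structure(NA, reason = "sensitive cells not viable (A >= lambda)"))
  }
  ev <- invasion_eigenvalue(params, "sensitive_no_plasmid", "SS")
  as.vector(ev) > tol
}

#' Search for the persistence paradox
#'
#' Scans a beta x A grid for parameter points where the sensitive plasmid
#' cannot persist parasitically ([parasite_persistence()] FALSE) yet
#' plasmid-borne resistance is evolutionarily stable: low-transmissibility
#' plasmids maintained purely by the benefit they carry.
#'
#' @param base a [plasmid_params] object for off-grid parameters.
#' @param beta_values,A_values grid values; `A_values` should stay below
#'   `lambda` so the parasitic-persistence question applies.
#' @return data.frame with columns `beta`, `A`, `parasite_persists`,
#'   `plasmid_borne_stable`, `paradox`.
#' @export
persistence_paradox_search <- function(base,
                                       beta_values = seq(0.05, 0.25, by = 0.025),
                                       A_values = seq(0.5, 0.95, by = 0.05)) {
  grid <- expand.grid(beta = beta_values, A = A_values,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    args <- unclass(base)
    args$beta <- grid$beta[i]
    args$A <- grid$A[i]
    p <- do.call(plasmid_params, args)
    pp <- parasite_persistence(p)
    pb <- stability(p, "plasmid_borne")
    data.frame(beta = grid$beta[i], A = grid$A[i],
               parasite_persists = as.logical(pp),
               plasmid_borne_stable = isTRUE(pb$stable))
  })
  out <- do.call(rbind, res)
  out$paradox <- !is.na(out$parasite_persists) & !out$parasite_persists &
    out$plasmid_borne_stable
  out
}
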