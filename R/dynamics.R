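#' Numerical integration settings
#'
#' @param horizon integration horizon in model time units. The default mimics
#'   very long runs; in practice the early-stop criterion ends most
#'   integrations after a few thousand time units.
#' @param round_tol densities below this value in the final state are set to
#'   zero, so that "present at equilibrium" means exceeding this threshold.
#'   Applied only to the reported final state, never mid-integration.
#' @param rtol,atol relative/absolute solver tolerances (lsoda family).
#' @param stop_tol early-stop criterion: integration ends once the sup-norm
#'   of the derivative falls below this value. Chosen below
#'   `round_tol * (slowest relevant decay rate)` — the slowest eigenvalues
#'   near the equilibria of interest are of order 1e-3 in the default time
#'   units — so that decaying types have dropped well under `round_tol` by
#'   the time the stop triggers.
#' @return A list of class `sim_settings`.
#' @export
sim_settings <- function(horizon = 1e7, round_tol = 1e-10,
                         rtol = 1e-8, atol = 1e-12, stop_tol = 1e-14) {
  stopifnot(horizon > 0, round_tol > 0, rtol > 0, atol > 0, stop_tol >= 0)
  structure(list(horizon = horizon, round_tol = round_tol, rtol = rtol,
                 atol = atol, stop_tol = stop_tol),
            class = "sim_settings")
}

# deSolve-compatible derivative closure for the core model, a structural
# variant, and/or constant immigration of sensitive cells.
.make_ode_func <- function(params, migration = NULL, variant = NULL) {
  v <- if (is.null(variant)) .default_variant() else variant
  if (is.null(migration)) {
    function(t, y, parms) list(.rhs_general(y, params, v, t))
  } else {
    in_S0 <- migration$mu * (1 - migration$f_imm)
    in_SS <- migration$mu * migration$f_imm
    function(t, y, parms) {
      dy <- .rhs_general(y, params, v, t)
      dy[1] <- dy[1] + in_S0
      dy[2] <- dy[2] + in_SS
      list(dy)
    }
  }
}

#' Integrate the model forward in time
#'
#' Adaptive stiff integration (lsoda family from \pkg{deSolve}) of the core
#' model, a structural variant, or the immigration model, from a given
#' initial state. By default integration runs until either the horizon is
#' reached or the derivative sup-norm falls below `settings$stop_tol`
#' (root-finding early stop), and the final state is reported with tiny
#' negative excursions clipped and densities below `settings$round_tol`
#' rounded to zero. Early stopping is disabled for non-autonomous systems
#' (fluctuating antibiotic pressure).
#'
#' @param state0 initial state vector.
#' @param params a [plasmid_params] object.
#' @param settings a [sim_settings] object.
#' @param migration optional [migration_params()].
#' @param variant optional [variant_config()].
#' @param times optional numeric vector of output times; when supplied the
#'   full trajectory is returned as a matrix (deSolve output, no early stop,
#'   no rounding) instead of the final state.
#' @return Named final state vector with attributes `time` (stop time) and
#'   `converged` (TRUE when the early-stop criterion triggered), or a
#'   trajectory matrix when `times` is given.
#' @examples
#' eq <- reduced_equilibrium(plasmid_params(), "chromosomal_no_plasmid")
#' integrate_model(eq$state, plasmid_params())
#' @export
integrate_model <- function(state0, params, settings = sim_settings(),
                            migration = NULL, variant = NULL, times = NULL) {
  y0 <- as_state(state0)
  if (any(y0 < 0)) stop("initial densities must be non-negative", call. = FALSE)
  f <- .make_ode_func(params, migration, variant)
  if (!is.null(times)) {
    out <- deSolve::ode(y = y0, times = times, func = f, parms = NULL,
                        rtol = settings$rtol, atol = settings$atol,
                        method = "lsoda")
    return(out)
  }
  autonomous <- is.null(variant$fluctuation)
  if (autonomous && settings$stop_tol > 0) {
    g <- function(t, y, parms) max(abs(f(t, y, parms)[[1]])) - settings$stop_tol
    out <- deSolve::lsodar(y = y0, times = c(0, settings$horizon), func = f,
                           parms = NULL, rtol = settings$rtol,
                           atol = settings$atol, rootfunc = g)
  } else {
    out <- deSolve::lsoda(y = y0, times = c(0, settings$horizon), func = f,
                          parms = NULL, rtol = settings$rtol,
                          atol = settings$atol)
  }
  if (nrow(out) < 2 && out[nrow(out), 1] < settings$horizon &&
      is.null(attr(out, "troot")))
    stop("solver failed before reaching the horizon (t = ",
         out[nrow(out), 1], ")", call. = FALSE)
  fin <- out[nrow(out), 1 + seq_len(6)]
  if (any(fin < -1e-6))
    warning("large negative densities clipped at final state", call. = FALSE)
  fin[fin < 0] <- 0
  fin[fin < settings$round_tol] <- 0
  names(fin) <- CELL_TYPES
  attr(fin, "time") <- unname(out[nrow(out), 1])
  attr(fin, "converged") <- !is.null(attr(out, "troot")) &&
    length(attr(out, "troot")) > 0
  fin
}

#' Classify the equilibrium outcome of a simulation
#'
#' Based on the zero pattern of the (rounded) final state: `plasmid_borne`
#' when resistant plasmids persist without any chromosomal resistance,
#' `chromosomal` when the reverse holds, `sensitive` when cells persist but
#' no resistance does, `extinct` when everything is gone, and `mixed` when
#' both forms of resistance coexist (not expected under the default model
#' assumptions).
#'
#' @param final a final state vector (e.g. from [integrate_model()]).
#' @param round_tol presence threshold; densities at or below it count as
#'   absent.
#' @return One of `"plasmid_borne"`, `"chromosomal"`, `"sensitive"`,
#'   `"extinct"`, `"mixed"`.
#' @export
classify_outcome <- function(final, round_tol = 1e-10) {
  x <- as_state(final)
  x[x < round_tol] <- 0
  tpr <- x[["SR"]] + x[["RR"]]
  chrom <- x[["R0"]] + x[["RS"]] + x[["RR"]]
  if (tpr > 0 && chrom == 0) "plasmid_borne"
  else if (chrom > 0 && tpr == 0) "chromosomal"
  else if (tpr == 0 && chrom == 0) { if (sum(x) > 0) "sensitive" else "extinct" }
  else "mixed"
}

#' Basin-of-attraction map over initial conditions
#'
#' Reconstructs the initial-condition experiment behind the bistability
#' analysis: the population starts as a sensitive subpopulation of total
#' density `sensitive_total` split between S0 and SS by the x-axis frequency
#' `x = SS / (S0 + SS)`, plus a resistant subpopulation of total density
#' `resistant_total` split by the y-axis frequency of plasmid-borne
#' resistance. In panel A the chromosomally resistant cells carry the
#' sensitive plasmid (`y = SR / (SR + RS)`); in panel B they are plasmid-free
#' (`y = SR / (SR + R0)`). Each grid cell is integrated to equilibrium and
#' classified.
#'
#' @param panel `"A"` or `"B"`.
#' @param n grid resolution per axis (frequencies `seq(0, 1, length.out = n)`).
#' @param params a [plasmid_params] object.
#' @param settings a [sim_settings] object.
#' @param sensitive_total,resistant_total initial total densities of the two
#'   subpopulations.
#' @return A data.frame (class `basin_map`) with columns `x`, `y`, `outcome`;
#'   integration failures are recorded as outcome `"error"`.
#' @examples
#' \donttest{
#' basin_map("B", n = 5)
#' }
#' @export
basin_map <- function(panel = c("A", "B"), n = 41,
                      params = plasmid_params(), settings = sim_settings(),
                      sensitive_total = 1, resistant_total = 1) {
  panel <- match.arg(panel)
  fr <- seq(0, 1, length.out = n)
  grid <- expand.grid(x = fr, y = fr, KEEP.OUT.ATTRS = FALSE)
  outcome <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    x <- grid$x[i]; y <- grid$y[i]
    state0 <- state_vector(
      S0 = (1 - x) * sensitive_total,
      SS = x * sensitive_total,
      SR = y * resistant_total,
      RS = if (panel == "A") (1 - y) * resistant_total else 0,
      R0 = if (panel == "B") (1 - y) * resistant_total else 0)
    outcome[i] <- tryCatch(
      classify_outcome(integrate_model(state0, params, settings),
                       settings$round_tol),
      error = function(e) "error")
  }
  out <- data.frame(x = grid$x, y = grid$y, outcome = outcome,
                    stringsAsFactors = FALSE)
  attr(out, "panel") <- panel
  attr(out, "params") <- params
  class(out) <- c("basin_map", class(out))
  out
}

#' Invasion experiment at a resident equilibrium
#'
#' Adds a small inoculum of one cell type to a resident equilibrium and
#' integrates to equilibrium. Invasion succeeds when the system leaves the
#' resident's outcome class; it fails when the invader's lineage (the
#' resistance/plasmid form it carries) collapses back below a tenth of the
#' inoculum while the resident outcome is unchanged. Anything else is
#' reported as inconclusive (NA).
#'
#' @param params a [plasmid_params] object.
#' @param resident label of the resident equilibrium (must exist).
#' @param invader cell type absent from the resident.
#' @param inoculum invader density added (default 1e-6, far below resident
#'   densities of order `lambda / gamma`).
#' @param settings a [sim_settings] object.
#' @return TRUE (invaded), FALSE (repelled) or NA (inconclusive), with
#'   attributes `final`, `resident_outcome`, `final_outcome`,
#'   `invader_lineage` (final density of the invader's form).
#' @examples
#' \donttest{
#' invasion_test(plasmid_params(), "plasmid_borne", "R0")
#' }
#' @export
invasion_test <- function(params, resident, invader, inoculum = 1e-6,
                          settings = sim_settings()) {
  eq <- reduced_equilibrium(params, resident)
  if (!eq$exists)
    stop("resident equilibrium '", resident, "' does not exist", call. = FALSE)
  invader <- match.arg(invader, CELL_TYPES)
  if (eq$state[[invader]] > 0)
    stop("invader '", invader, "' is part of the resident equilibrium",
         call. = FALSE)
  state0 <- eq$state
  state0[[invader]] <- state0[[invader]] + inoculum
  fin <- integrate_model(state0, params, settings)
  lineage <- switch(invader,
                    SR = , RR = fin[["SR"]] + fin[["RR"]],
                    R0 = , RS = fin[["R0"]] + fin[["RS"]] + fin[["RR"]],
                    SS = fin[["SS"]] + fin[["RS"]],
                    S0 = fin[["S0"]])
  res_out <- classify_outcome(eq$state, settings$round_tol)
  fin_out <- classify_outcome(fin, settings$round_tol)
  verdict <- if (fin_out != res_out) TRUE
             else if (lineage <= inoculum / 10) FALSE
             else NA
  structure(verdict, final = fin, resident_outcome = res_out,
            final_outcome = fin_out, invader_lineage = lineage)
}

#' Scan for unanticipated attractors
#'
#' Integrates the model from randomized initial conditions and reports, for
#' each run, the outcome class and whether the final state matches one of
#' the candidate boundary equilibria (within `match_tol` in sup-norm). A
#' guard for the verbal competitive-exclusion argument that narrows the
#' candidate equilibrium list: any unmatched attractor (in particular one
#' retaining dually resistant RR cells) is flagged.
#'
#' @param params a [plasmid_params] object.
#' @param n number of random initial conditions (densities ~ U(0, 1)).
#' @param settings a [sim_settings] object.
#' @param match_tol matching tolerance on the final state.
#' @param seed optional RNG seed.
#' @return data.frame with one row per run: the six final densities,
#'   `outcome`, `matched` (label of the matched candidate or `"none"`).
#' @export
attractor_scan <- function(params, n = 10, settings = sim_settings(),
                           match_tol = 1e-6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cands <- lapply(EQUILIBRIUM_LABELS, function(l)
    reduced_equilibrium(params, l))
  cands <- Filter(function(e) e$exists, cands)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    state0 <- state_vector()
    state0[] <- stats::runif(6)
    fin <- integrate_model(state0, params, settings)
    matched <- "none"
    if (sum(fin) == 0) matched <- "extinction"
    for (e in cands) {
      if (max(abs(fin - e$state)) < match_tol) { matched <- e$label; break }
    }
    rows[[i]] <- data.frame(t(as.matrix(fin)),
                            outcome = classify_outcome(fin, settings$round_tol),
                            matched = matched, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
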