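#' Ready-made analysis scenarios
#'
#' The experimental designs of the main analyses, encoded as reproducible
#' scenario specifications: the two regime sweeps (antibiotic pressure x
#' resistance cost, and transmission rate x plasmid cost), the two
#' basin-of-attraction panels, the immigration experiment at the high and
#' low influx rates, and the multispecies acquisition sweep. Each spec
#' carries its parameters, design knobs and seed, and can be executed with
#' [run_scenario()].
#'
#' @return Named list of `scenario_spec` objects with names `fig2_left`,
#'   `fig2_right`, `fig3_panelA`, `fig3_panelB`, `fig4_migration`,
#'   `fig5_multispecies`.
#' @export
builtin_scenarios <- function() {
  base <- plasmid_params()
  specs <- list(
    fig2_left = list(
      name = "fig2_left", type = "phase_sweep", params = base,
      axis1 = list(name = "A", from = 0, to = 2),
      axis2 = list(name = "cR", from = 0, to = 0.5),
      grid = 61, seed = 1L),
    fig2_right = list(
      name = "fig2_right", type = "phase_sweep", params = base,
      axis1 = list(name = "beta", from = 0, to = 0.25),
      axis2 = list(name = "cP", from = 0, to = 0.5),
      grid = 61, seed = 1L),
    fig3_panelA = list(
      name = "fig3_panelA", type = "basin", params = base, panel = "A",
      sensitive_total = 1, resistant_total = 1, grid = 41, seed = 1L),
    fig3_panelB = list(
      name = "fig3_panelB", type = "basin", params = base, panel = "B",
      sensitive_total = 1, resistant_total = 1, grid = 41, seed = 1L),
    fig4_migration = list(
      name = "fig4_migration", type = "migration", params = base,
      mu = c(1e-1, 1e-2), grid = 41, seed = 1L),
    fig5_multispecies = list(
      name = "fig5_multispecies", type = "multispecies",
      n_values = c(2L, 5L, 10L, 20L),
      ratio_values = 10^seq(-1, 2, length.out = 7),
      m = 1e-6, c = 1e-5, t_freq = 1e-1,
      n_realizations = 1000L, seed = 1L))
  lapply(specs, function(s) structure(s, class = "scenario_spec"))
}

#' Execute a scenario and serialize its results
#'
#' Dispatches a scenario specification to the appropriate analysis function
#' and, optionally, writes a tidy CSV of results plus a JSON metadata file
#' (parameters, design, seed, package version, wall-clock time) alongside
#' it. Stochastic scenarios are reproducible from their recorded seed.
#'
#' @param spec a `scenario_spec` from [builtin_scenarios()], or the name of
#'   one.
#' @param out_dir output directory; `NULL` skips writing.
#' @param grid optional override of the grid resolution (or of
#'   `n_realizations` for the multispecies scenario via `n_realizations`).
#' @param n_realizations optional override for stochastic scenarios.
#' @param settings a [sim_settings] object for simulation scenarios.
#' @return List with `table` (the tidy results data.frame), `meta`, and
#'   `files` (paths written, or `NULL`).
#' @export
run_scenario <- function(spec, out_dir = NULL, grid = NULL,
                         n_realizations = NULL, settings = sim_settings()) {
  if (is.character(spec)) {
    all <- builtin_scenarios()
    if (!spec %in% names(all))
      stop("unknown scenario '", spec, "'; available: ",
           paste(names(all), collapse = ", "), call. = FALSE)
    spec <- all[[spec]]
  }
  t0 <- Sys.time()
  if (spec$type == "phase_sweep") {
    n <- if (is.null(grid)) spec$grid else grid
    tab <- phase_sweep(spec$params,
                       sweep_axis(spec$axis1$name, spec$axis1$from,
                                  spec$axis1$to, n),
                       sweep_axis(spec$axis2$name, spec$axis2$from,
                                  spec$axis2$to, n))
  } else if (spec$type == "basin") {
    n <- if (is.null(grid)) spec$grid else grid
    tab <- basin_map(spec$panel, n = n, params = spec$params,
                     settings = settings,
                     sensitive_total = spec$sensitive_total,
                     resistant_total = spec$resistant_total)
    tab <- as.data.frame(tab)
  } else if (spec$type == "migration") {
    n <- if (is.null(grid)) spec$grid else grid
    tabs <- lapply(spec$mu, function(mu) {
      d <- migration_outcome_map(spec$params, mu = mu, n = n,
                                 settings = settings)
      d$mu <- mu
      d
    })
    tab <- do.call(rbind, tabs)
  } else if (spec$type == "multispecies") {
    reps <- if (is.null(n_realizations)) spec$n_realizations else n_realizations
    tab <- figure5_sweep(spec$n_values, spec$ratio_values, m = spec$m,
                         c = spec$c, t_freq = spec$t_freq,
                         n_realizations = reps, seed = spec$seed)
  } else {
    stop("unknown scenario type '", spec$type, "'", call. = FALSE)
  }
  meta <- list(
    name = spec$name, type = spec$type, seed = spec$seed,
    spec = spec[setdiff(names(spec), c("params", "name", "type", "seed"))],
    params = if (!is.null(spec$params)) unclass(spec$params),
    settings = unclass(settings),
    package_version = as.character(utils::packageVersion("plasmidfate")),
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    schema_version = 1L)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(out_dir, paste0(spec$name, ".csv"))
    js <- file.path(out_dir, paste0(spec$name, "_meta.json"))
    utils::write.csv(tab, csv, row.names = FALSE)
    jsonlite::write_json(meta, js, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    files <- c(csv = csv, json = js)
  }
  list(table = tab, meta = meta, files = files)
}
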