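#' Parameters of the multispecies gene-acquisition model
#'
#' A stochastic model of how a resistance gene spreads across `n` species.
#' Each species is in one of three states: S (no resistance), RC
#' (chromosomal resistance) or RP (plasmid-borne resistance). RC and RP are
#' absorbing: once a species has fixed one form, positive frequency-
#' dependent selection prevents the other from establishing. The gene
#' emerges de novo only on the chromosome (rate `m`); it spreads between
#' species by transfer of chromosomal resistance (rate `c` per donor) or of
#' resistance plasmids (rate `p` per donor). Gene flow between plasmid and
#' chromosome keeps the excluded form present at low frequency `t_freq`
#' within each resistant species, so RC donors also transmit plasmid-borne
#' resistance at rate `t_freq * p` and RP donors chromosomal resistance at
#' rate `t_freq * c`.
#'
#' @param n number of species (>= 1).
#' @param m de novo chromosomal mutation rate (per species per time).
#' @param c interspecies chromosomal-gene transfer rate (per donor-recipient
#'   pair per time).
#' @param p interspecies plasmid transfer rate (per donor-recipient pair per
#'   time).
#' @param t_freq frequency of the low-frequency form maintained by
#'   plasmid-chromosome gene flow, in \[0, 1\].
#' @return A list of class `multispecies_params`.
#' @export
multispecies_params <- function(n, m = 1e-6, c = 1e-5, p = 1e-4,
                                t_freq = 0.1) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n),
            m >= 0, c >= 0, p >= 0, t_freq >= 0, t_freq <= 1)
  structure(list(n = as.integer(n), m = m, c = c, p = p, t_freq = t_freq),
            class = "multispecies_params")
}

#' Per-species transition hazards
#'
#' For every species still in state S, the hazard of acquiring chromosomal
#' resistance is `m + c * N_RC + c * t_freq * N_RP` and of acquiring
#' plasmid-borne resistance `p * N_RP + p * t_freq * N_RC`; absorbed species
#' have zero hazards.
#'
#' @param state character vector of per-species states
#'   (`"S"`, `"RC"`, `"RP"`).
#' @param params a [multispecies_params()] object.
#' @return data.frame with columns `species`, `state`, `hazard_RC`,
#'   `hazard_RP`.
#' @examples
#' transition_hazards(c("S", "RC"), multispecies_params(n = 2))
#' @export
transition_hazards <- function(state, params) {
  stopifnot(all(state %in% c("S", "RC", "RP")))
  n_rc <- sum(state == "RC")
  n_rp <- sum(state == "RP")
  h_rc <- params$m + params$c * n_rc + params$c * params$t_freq * n_rp
  h_rp <- params$p * n_rp + params$p * params$t_freq * n_rc
  is_s <- state == "S"
  data.frame(species = seq_along(state), state = state,
             hazard_RC = ifelse(is_s, h_rc, 0),
             hazard_RP = ifelse(is_s, h_rp, 0),
             stringsAsFactors = FALSE)
}

#' Simulate one realization of the multispecies model
#'
#' Starting from all species in S, draws acquisition events until every
#' species is absorbed in RC or RP. The default mode is a continuous-time
#' Markov chain whose per-species hazards are the expressions of
#' [transition_hazards()]; the next event is resolved by competing
#' exponentials, so the destination of each transition is RC with
#' probability `hazard_RC / (hazard_RC + hazard_RP)`. A discrete-time
#' Bernoulli scheme (explicit timestep `dt`, categorical draw per species
#' per step) is provided for cross-checking; it converges to the CTMC as
#' `dt * hazard -> 0`.
#'
#' @param params a [multispecies_params()] object with `m > 0` (otherwise
#'   absorption is unreachable from the all-S start and an error is
#'   raised).
#' @param mode `"ctmc"` (default) or `"discrete"`.
#' @param dt timestep for the discrete mode.
#' @return List with `state` (final per-species states), `n_RC`, `n_RP`,
#'   `proportion` (`n_RP / n`).
#' @export
run_realization <- function(params, mode = c("ctmc", "discrete"), dt = 1) {
  mode <- match.arg(mode)
  n <- params$n
  if (params$m <= 0)
    stop("unreachable absorption: 'm' must be > 0 so that resistance can ",
         "first arise de novo", call. = FALSE)
  state <- rep("S", n)
  n_rc <- 0L; n_rp <- 0L
  if (mode == "ctmc") {
    while (n_rc + n_rp < n) {
      h_rc <- params$m + params$c * n_rc + params$c * params$t_freq * n_rp
      h_rp <- params$p * n_rp + params$p * params$t_freq * n_rc
      idx <- which(state == "S")
      i <- idx[sample.int(length(idx), 1L)]
      if (stats::runif(1) < h_rc / (h_rc + h_rp)) {
        state[i] <- "RC"; n_rc <- n_rc + 1L
      } else {
        state[i] <- "RP"; n_rp <- n_rp + 1L
      }
    }
  } else {
    while (n_rc + n_rp < n) {
      h_rc <- params$m + params$c * n_rc + params$c * params$t_freq * n_rp
      h_rp <- params$p * n_rp + params$p * params$t_freq * n_rc
      p_rc <- h_rc * dt; p_rp <- h_rp * dt
      if (p_rc + p_rp > 1)
        stop("'dt' too large: per-step transition probability exceeds 1",
             call. = FALSE)
      for (i in which(state == "S")) {
        u <- stats::runif(1)
        if (u < p_rc) { state[i] <- "RC"; n_rc <- n_rc + 1L }
        else if (u < p_rc + p_rp) { state[i] <- "RP"; n_rp <- n_rp + 1L }
      }
    }
  }
  list(state = state, n_RC = n_rc, n_RP = n_rp, proportion = n_rp / n)
}

#' Ensemble of multispecies realizations
#'
#' Runs independent realizations under a seeded RNG and summarises the
#' final proportion of species with plasmid-borne resistance: mean and a
#' normal-approximation 95% confidence interval
#' (`mean +/- 1.96 * sd / sqrt(n_realizations)`).
#'
#' @param params a [multispecies_params()] object.
#' @param n_realizations number of independent realizations.
#' @param seed optional RNG seed.
#' @param mode,dt passed to [run_realization()].
#' @return A list of class `ms_ensemble`: `proportions` (per-realization),
#'   `mean`, `se`, `ci` (length-2), `n_realizations`, `seed`, `params`.
#' @examples
#' ms_ensemble(multispecies_params(n = 2), n_realizations = 50, seed = 1)$mean
#' @export
ms_ensemble <- function(params, n_realizations = 1000, seed = NULL,
                        mode = "ctmc", dt = 1) {
  if (!is.null(seed)) set.seed(seed)
  props <- vapply(seq_len(n_realizations),
                  function(i) run_realization(params, mode, dt)$proportion,
                  numeric(1))
  m <- mean(props)
  se <- stats::sd(props) / sqrt(n_realizations)
  structure(list(proportions = props, mean = m, se = se,
                 ci = c(m - 1.96 * se, m + 1.96 * se),
                 n_realizations = n_realizations, seed = seed,
                 params = params),
            class = "ms_ensemble")
}

#' @export
print.ms_ensemble <- function(x, ...) {
  cat(sprintf(
    "Multispecies ensemble (n = %d species, %d realizations):\n",
    x$params$n, x$n_realizations))
  cat(sprintf("  mean plasmid-borne proportion %.4f (95%% CI %.4f-%.4f)\n",
              x$mean, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Sweep over species number and plasmid/chromosome transfer ratio
#'
#' Runs an ensemble for every combination of species number and `p / c`
#' ratio (the plasmid transfer rate is set to `ratio * c`), reproducing the
#' design of the multispecies figure.
#'
#' @param n_values integer vector of species numbers.
#' @param ratio_values numeric vector of `p / c` ratios.
#' @param m,c,t_freq shared rates (defaults: the reference values
#'   `m = 1e-6`, `c = 1e-5`, `t_freq = 0.1`).
#' @param n_realizations realizations per cell.
#' @param seed RNG seed; each cell uses an offset sub-seed so the sweep is
#'   reproducible cell-by-cell.
#' @return data.frame with columns `n`, `ratio`, `mean`, `se`, `ci_lo`,
#'   `ci_hi`, `max_proportion`.
#' @export
figure5_sweep <- function(n_values, ratio_values, m = 1e-6, c = 1e-5,
                          t_freq = 0.1, n_realizations = 1000, seed = 1) {
  grid <- expand.grid(n = n_values, ratio = ratio_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pars <- multispecies_params(n = grid$n[i], m = m, c = c,
                                p = grid$ratio[i] * c, t_freq = t_freq)
    ens <- ms_ensemble(pars, n_realizations, seed = seed + i)
    data.frame(n = grid$n[i], ratio = grid$ratio[i], mean = ens$mean,
               se = ens$se, ci_lo = ens$ci[1], ci_hi = ens$ci[2],
               max_proportion = max(ens$proportions))
  })
  do.call(rbind, rows)
}
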