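# Shared fixtures: the reference parameter set and random generators used by
# the property-style tests.

ref_params <- function(...) plasmid_params(...)

rand_state <- function(max = 1) {
  x <- stats::runif(6, 0, max)
  names(x) <- CELL_TYPES
  x
}

# random parameter draws spanning the regimes of the two-parameter sweeps
rand_params <- function() {
  plasmid_params(lambda = stats::runif(1, 0.6, 1.5),
                 gamma = stats::runif(1, 0.6, 1.5),
                 A = stats::runif(1, 0.05, 1.8),
                 cR = stats::runif(1, 0.005, 0.35),
                 cP = stats::runif(1, 0, 0.3),
                 beta = stats::runif(1, 0.02, 0.25),
                 s = stats::runif(1, 0, 0.03))
}

# closed-form logistic growth, the analytic oracle for single-type dynamics
logistic_solution <- function(n0, r, K, t) {
  K * n0 * exp(r * t) / (K + n0 * (exp(r * t) - 1))
}
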