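test_that("single-type equilibria match their closed forms", {
  p <- ref_params()
  eq <- reduced_equilibrium(p, "chromosomal_no_plasmid")
  expect_true(eq$exists)
  expect_equal(eq$state[["R0"]], 0.95, tolerance = 1e-12)
  expect_equal(sum(eq$state[names(eq$state) != "R0"]), 0)

  eq2 <- reduced_equilibrium(plasmid_params(A = 0.5), "sensitive_no_plasmid")
  expect_true(eq2$exists)
  expect_equal(eq2$state[["S0"]], 0.5, tolerance = 1e-12)

  # susceptible cells are not viable when A >= lambda
  expect_false(reduced_equilibrium(plasmid_params(A = 1),
                                   "sensitive_no_plasmid")$exists)
  expect_false(reduced_equilibrium(plasmid_params(A = 1.5),
                                   "sensitive_no_plasmid")$exists)
})

test_that("the plasmid-borne equilibrium solves the full model and attracts nearby states", {
  p <- ref_params()
  eq <- reduced_equilibrium(p, "plasmid_borne")
  expect_true(eq$exists)
  expect_true(eq$state[["S0"]] > 0 && eq$state[["SR"]] > 0)
  expect_lt(max(abs(plasmid_rhs(eq$state, p))), 1e-10)

  # long forward integration from a nearby state lands on the same point
  y0 <- eq$state * c(1.01, 1, 1.02, 1, 1, 1)
  fin <- integrate_model(y0, p)
  expect_lt(max(abs(fin - eq$state)), 1e-6)
})

test_that("stable equilibria recover from small random perturbations", {
  p <- ref_params()
  set.seed(7)
  for (label in c("chromosomal_with_plasmid", "plasmid_borne")) {
    eq <- reduced_equilibrium(p, label)
    for (k in 1:3) {
      y0 <- pmax(0, eq$state * (1 + 1e-3 * stats::runif(6, -1, 1)))
      fin <- integrate_model(y0, p)
      expect_lt(max(abs(fin - eq$state)), 1e-6)
    }
  }
})

test_that("the analytic Jacobian agrees with central finite differences", {
  set.seed(11)
  for (i in 1:100) {
    p <- rand_params()
    x <- rand_state()
    Ja <- plasmid_jacobian(x, p)
    Jn <- pracma::jacobian(function(y) .rhs_general(y, p, .default_variant()),
                           unname(x))
    expect_lt(max(abs(Ja - Jn)) / max(abs(Ja)), 1e-6)
  }
})

test_that("the Jacobian at extinction reads off the linear growth rates", {
  p <- ref_params()
  J <- plasmid_jacobian(state_vector(), p)
  dr <- derived_rates(p, state_vector())
  # each type's own linear growth rate on the diagonal
  expect_equal(unname(diag(J)),
               c(p$lambda - p$A, (1 - p$s) * dr$lamP - p$A,
                 (1 - p$s) * dr$lamRP, dr$lamR, (1 - p$s) * dr$lamRP,
                 (1 - p$s) * dr$lamRRP))
  # the R0 direction grows at lamR out of extinction
  expect_true(any(abs(eigen(J, only.values = TRUE)$values - dr$lamR) < 1e-12))
})

test_that("chromosome relabeling is a symmetry when resistance is cost- and effect-free", {
  p <- plasmid_params(cR = 0, A = 0)
  perm <- c(4, 5, 6, 1, 2, 3)   # S0<->R0, SS<->RS, SR<->RR
  P <- diag(6)[perm, ]
  set.seed(12)
  for (i in 1:10) {
    x <- rand_state()
    J1 <- plasmid_jacobian(unname(x)[perm], p)
    J2 <- P %*% plasmid_jacobian(x, p) %*% t(P)
    expect_equal(unname(J1), unname(J2), tolerance = 1e-12)
  }
})

test_that("stability verdicts at the reference parameters show bistability", {
  p <- ref_params()
  cwp <- stability(p, "chromosomal_with_plasmid")
  expect_true(cwp$stable)
  expect_true(all(Re(cwp$eigenvalues) < 0))
  pb <- stability(p, "plasmid_borne")
  expect_true(pb$stable)
  r <- classify_regime(p)
  expect_identical(r$regime, "bistable")
  expect_identical(r$plasmid_presence, "present")
})

test_that("resistance is not stable without antibiotic pressure", {
  p <- plasmid_params(A = 0)
  s <- stability(p, "chromosomal_no_plasmid")
  expect_false(s$stable)
  # the S0 invasion eigenvalue is lambda - lamR = cR * lambda > 0
  ev <- invasion_eigenvalue(p, "chromosomal_no_plasmid", "S0")
  expect_equal(as.vector(ev), p$cR * p$lambda, tolerance = 1e-10)
  r <- classify_regime(p)
  expect_identical(r$regime, "no_resistance")
  expect_false(r$needs_review)   # the sensitive equilibria take over
})

test_that("a non-transmissible lossy plasmid cannot hold the resistance gene", {
  p <- plasmid_params(beta = 0, s = 0.005)
  r <- classify_regime(p)
  expect_false(r$regime %in% c("plasmid_only", "bistable"))
})

test_that("regime classification behaves on sweeps and degenerate grids", {
  p <- ref_params()
  # a 1x1 sweep is just classify_regime
  sw <- phase_sweep(p, list(name = "A", values = 1),
                    list(name = "cR", values = 0.05))
  expect_equal(nrow(sw), 1L)
  expect_identical(sw$regime, classify_regime(p)$regime)

  # transmission x plasmid-cost sweep: plasmid-involving regimes need beta
  # above a threshold that increases with cP
  sw2 <- phase_sweep(p, sweep_axis("beta", 0.02, 0.25, 8),
                     sweep_axis("cP", 0, 0.15, 4))
  expect_true(all(sw2$regime %in%
    c("bistable", "chromosomal_only", "plasmid_only", "no_resistance")))
  thresholds <- vapply(split(sw2, sw2$cP), function(d) {
    pl <- d$beta[d$regime %in% c("bistable", "plasmid_only")]
    if (length(pl)) min(pl) else Inf
  }, numeric(1))
  expect_true(all(diff(thresholds) >= 0))
  expect_true(any(is.finite(thresholds)))
})

test_that("no attractor with dual-resistance cells arises under default assumptions", {
  p <- ref_params()
  scan <- attractor_scan(p, n = 8, seed = 42)
  expect_true(all(scan$matched != "none"))
  expect_true(all(scan$RR == 0))
  expect_true(all(scan$outcome %in% c("chromosomal", "plasmid_borne")))
})

test_that("parasitic plasmid persistence matches hand linearization", {
  # no transmission: segregation loss alone cannot sustain the plasmid
  expect_false(parasite_persistence(plasmid_params(beta = 0, A = 0.5)))
  # cost-free, lossless, transmissible plasmid invades: eigenvalue beta * N*
  p <- plasmid_params(s = 0, cP = 0, beta = 0.1, A = 0)
  expect_true(parasite_persistence(p))
  ev <- invasion_eigenvalue(p, "sensitive_no_plasmid", "SS")
  expect_equal(as.vector(ev), 0.1 * 1, tolerance = 1e-10)
  # question not applicable when sensitive cells are not viable
  expect_true(is.na(parasite_persistence(plasmid_params(A = 1.2))))
})

test_that("plasmid-borne resistance can be stable where the parasitic plasmid cannot persist", {
  res <- persistence_paradox_search(ref_params(),
                                    beta_values = seq(0.1, 0.2, by = 0.05),
                                    A_values = c(0.5, 0.7, 0.9))
  expect_true(any(res$paradox))
})
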