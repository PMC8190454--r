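test_that("variants with all knobs at defaults reproduce the core derivative exactly", {
  set.seed(31)
  for (i in 1:20) {
    p <- rand_params()
    x <- rand_state()
    expect_identical(plasmid_rhs_variant(x, p, variant_config()),
                     plasmid_rhs(x, p))
    expect_identical(plasmid_rhs_migration(x, p, migration_params(0, 0.3)),
                     plasmid_rhs(x, p))
  }
})

test_that("immigration adds the stated influx terms", {
  p <- ref_params()
  x <- rand_state()
  mig <- migration_params(mu = 0.1, f_imm = 0.25)
  d <- plasmid_rhs_migration(x, p, mig) - plasmid_rhs(x, p)
  expect_equal(unname(d), c(0.075, 0.025, 0, 0, 0, 0))
})

test_that("removing the second-copy cost abolishes bistability and lets dual resistance persist", {
  p <- ref_params()
  v <- variant_config(dual_cost_second_copy = 0)
  # the chromosomal equilibrium becomes neutrally invadable by RR and the
  # plasmid-borne equilibrium outright unstable: no bistability
  cwp <- variant_stability(p, "chromosomal_with_plasmid", v)
  expect_false(isTRUE(cwp$stable))
  pb <- variant_stability(p, "plasmid_borne", v)
  expect_false(isTRUE(pb$stable))
  expect_gt(pb$max_re, 0)
  expect_false(classify_regime(p, variant = v)$regime == "bistable")

  # dual-resistance cells persist in simulation once both forms are present
  y0 <- state_vector(S0 = 0.3, SR = 0.5, R0 = 0.5, RS = 0.1)
  fin <- integrate_model(y0, p, variant = v)
  expect_gt(fin[["RR"]], 0.01)
})

test_that("residual dual benefit plus no dual cost makes dual resistance dominate", {
  p <- ref_params()
  v <- variant_config(dual_cost_second_copy = 0, single_copy_protection = 0.9)
  y0 <- state_vector(S0 = 0.3, SR = 0.5, R0 = 0.5, RS = 0.1)
  fin <- integrate_model(y0, p, variant = v)
  expect_identical(classify_outcome(fin), "mixed")
  expect_gt(fin[["RR"]], max(fin[c("SR", "RS", "R0")]))
})

test_that("tiny transposition rates leave the regime unchanged but sustain the excluded form", {
  p <- ref_params()
  v <- variant_config(transposition_rate = 1e-9)
  expect_identical(classify_regime(p, variant = v)$regime,
                   classify_regime(p)$regime)
  # gene flow maintains chromosomal resistance at low frequency in a
  # plasmid-borne resident (mutation-selection-balance analogue)
  v2 <- variant_config(transposition_rate = 1e-6)
  eq <- reduced_equilibrium(p, "plasmid_borne")
  fin <- integrate_model(eq$state, p, variant = v2,
                         settings = sim_settings(round_tol = 1e-12))
  chrom <- fin[["R0"]] + fin[["RS"]] + fin[["RR"]]
  expect_gt(chrom, 0)
  expect_lt(chrom, 1e-2)
})

test_that("independent segregation loss approximates the replication-coupled form at small s", {
  p <- ref_params()
  v <- variant_config(segregation_mode = "independent_rate")
  set.seed(32)
  for (i in 1:10) {
    x <- rand_state()
    d0 <- plasmid_rhs(x, p)
    d1 <- plasmid_rhs_variant(x, p, v)
    # difference is O(s * cost): bounded by s * lambda * max cost * density
    expect_lt(max(abs(d1 - d0)), p$s * p$lambda * 0.2 * max(x) * 4)
  }
  expect_identical(classify_regime(p, variant = v)$regime, "bistable")
})

test_that("growth-slowing antibiotic action is calibrated to the death formulation", {
  p <- plasmid_params(A = 0.5)
  v <- variant_config(antibiotic_mode = "growth_slowing")
  # susceptible-alone equilibrium density matches (lambda - A) / gamma
  fin <- integrate_model(state_vector(S0 = 0.1), p, variant = v)
  expect_equal(fin[["S0"]], 0.5, tolerance = 1e-6)
  # bistability is preserved under this formulation at the reference point
  expect_identical(classify_regime(ref_params(A = 0.5))$regime,
                   classify_regime(plasmid_params(A = 0.5),
                                   variant = v)$regime)
})

test_that("costs charged as death instead of slowed growth preserve the regime", {
  p <- ref_params()
  v <- variant_config(cost_mode = "death")
  expect_identical(classify_regime(p, variant = v)$regime, "bistable")
})

test_that("the migration experiment reproduces the local-adaptation contrast", {
  p <- ref_params()
  mm <- migration_outcome_map(p, mu = 0.1, n = 5)
  # immigrants without the plasmid favour plasmid-borne resistance
  f0 <- mm[mm$f_imm == 0 & mm$y > 0, ]
  expect_true(all(f0$outcome[f0$y > 0.3] == "plasmid_borne"))
  # immigrants carrying the sensitive plasmid favour chromosomal resistance
  f1 <- mm[mm$f_imm == 1 & mm$y <= 0.5, ]
  expect_true(all(f1$outcome == "chromosomal"))
})

test_that("square-wave antibiotic input reduces to the constant model in its limits", {
  p <- ref_params()
  # duty = 1 is constant exposure: compare against a plain lsoda run over the
  # same horizon
  eq <- reduced_equilibrium(p, "plasmid_borne")
  y0 <- eq$state
  y0[["R0"]] <- y0[["R0"]] + 1e-6
  fin_sq <- plasmidfate:::.integrate_squarewave(
    y0, p, period = 10, duty = 1, A_on = 1, A_off = 0, n_periods = 10,
    settings = sim_settings())
  tr <- integrate_model(y0, p, times = c(0, 100))
  fin_const <- as_state(tr[nrow(tr), 1 + 1:6])
  fin_const[fin_const < 1e-10] <- 0
  expect_equal(unname(fin_sq), unname(fin_const), tolerance = 1e-6)

  # duty = 0 means no antibiotic. At low transmissibility (where the plasmid
  # cannot persist parasitically) resistance decays and the population goes
  # sensitive; at the default beta the resistant plasmid survives as a
  # parasite even without selection for its cargo.
  p_lo <- plasmid_params(beta = 0.05)
  fe <- fluctuation_experiment(p_lo, periods = 50, duty = 0, A_on = 1,
                               A_off = 0, n_periods = 60)
  expect_true(all(fe$outcome == "sensitive"))
  expect_true(all(!fe$resident_persists))
})

test_that("both resistance forms persist as residents under moderate fluctuation", {
  p <- ref_params()
  fe <- fluctuation_experiment(p, periods = c(2, 20), duty = 0.5, A_on = 1,
                               A_off = 0, n_periods = 60)
  expect_true(all(fe$resident_persists))
})
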