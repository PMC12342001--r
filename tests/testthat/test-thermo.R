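# Elemental bookkeeping and thermodynamic formulas.

test_that("molecular formulas parse into element counts", {
  expect_equal(parseFormula("H2O2"), c(H = 2L, O = 2L))
  expect_equal(parseFormula("C10H18N3O6S"),
               c(C = 10L, H = 18L, N = 3L, O = 6L, S = 1L))
  expect_equal(parseFormula("C20H34N6O12S2"),
               c(C = 20L, H = 34L, N = 6L, O = 12L, S = 2L))
  # counts sum to the atom total
  expect_identical(sum(parseFormula("C6H12O6")), 24L)
  # repeated symbols accumulate
  expect_equal(parseFormula("CH3COOH"), c(C = 2L, H = 4L, O = 2L))
  expect_error(parseFormula("C10Xx2"), "unknown element")
  expect_error(parseFormula(""), "empty")
  expect_error(parseFormula("2HO"), "malformed")
})

test_that("the superoxide dismutation and catalase reactions balance", {
  net <- liverNet()
  sp <- speciesTable(net)
  sod <- getReaction(net, "R_SOD") # 2 O2- + 2 H+ -> H2O2 + O2
  rep1 <- checkBalance(sod, sp)
  expect_true(rep1$balanced)
  expect_true(all(abs(rep1$elements) == 0))
  expect_identical(rep1$charge, 0)
  cat <- getReaction(net, "R_CAT") # 2 H2O2 -> 2 H2O + O2
  expect_true(checkBalance(cat, sp)$balanced)
  # deliberate imbalance: drop the water coefficient to 1
  bad <- cat
  bad@stoich["h2o_c"] <- 1
  rep2 <- checkBalance(bad, sp)
  expect_false(rep2$balanced)
  expect_true(abs(rep2$elements["H"]) > 0)
})

test_that("checkBalance reports missing species", {
  net <- liverNet()
  r <- getReaction(net, "R_CAT")
  expect_error(checkBalance(r, speciesTable(net)[1:3, ]), "not in table")
})

test_that("reaction Gibbs energy / enthalpy is linear and antisymmetric", {
  net <- liverNet()
  sp <- speciesTable(net)
  r <- getReaction(net, "R_GPX")
  dG <- reactionDelta(r, sp, "G")
  dH <- reactionDelta(r, sp, "H")
  # the glutathione peroxidase reaction enthalpy is the -196 kJ/mol anchor
  expect_equal(dH, -196, tolerance = 1e-9)
  # linearity: doubling every coefficient doubles the result
  r2 <- r
  r2@stoich <- 2 * r@stoich
  expect_equal(reactionDelta(r2, sp, "G"), 2 * dG)
  # antisymmetry under reversal
  rev <- r
  rev@stoich <- -r@stoich
  expect_equal(reactionDelta(rev, sp, "G"), -dG)
  # empty stoichiometry is the empty sum
  r0 <- r
  r0@stoich <- numeric(0)
  expect_identical(reactionDelta(r0, sp, "G"), 0)
})

test_that("the Gibbs-Helmholtz correction behaves at and away from T0", {
  R <- thermoConstants()$R_gas / 1000
  T0 <- thermoConstants()$T0
  # at T = T0 the correction vanishes exactly
  expect_identical(gibbsHelmholtz(-20, -196, T0), -20 / (R * T0))
  # zero enthalpy makes the dimensionless value temperature independent
  expect_equal(gibbsHelmholtz(-20, 0, 277), gibbsHelmholtz(-20, 0, 320))
  # direct evaluation of the closed form as oracle
  expected <- -20 / (R * 298) + (-196 / R) * (1 / 310 - 1 / 298)
  expect_equal(gibbsHelmholtz(-20, -196, 310), expected)
  # an exothermic reaction becomes less favourable on warming
  expect_gt(gibbsHelmholtz(-20, -196, 320), gibbsHelmholtz(-20, -196, 300))
  expect_error(gibbsHelmholtz(-20, -196, -1), "positive")
})

test_that("the ideal mixture Gibbs energy matches hand evaluation", {
  # pure component: its formation value, ln 1 = 0
  expect_equal(mixtureGibbs(5, -3.2), -3.2)
  # two species, equal amounts, both zero formation: ln(1/2)
  expect_equal(mixtureGibbs(c(1, 1), c(0, 0)), log(0.5))
  # three species, amounts (2,1,1): direct summation oracle
  g <- c(-1.5, 0.25, 2)
  x <- c(2, 1, 1) / 4
  expect_equal(mixtureGibbs(c(2, 1, 1), g), sum(x * g) + sum(x * log(x)))
  # a zero amount contributes nothing (x log x -> 0)
  expect_equal(mixtureGibbs(c(1, 0), c(-1, 99)), -1)
  expect_error(mixtureGibbs(c(0, 0), c(0, 0)), "all-zero")
  expect_error(mixtureGibbs(c(-1, 2), c(0, 0)), "non-negative")
})
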