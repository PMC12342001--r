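# Monte Carlo layer: the scalar return, viability rule, temperature-policy
# search and glutathione-supplement minimisation.

fakeResult <- function(glu, atp, mev, ec, lac = 1, ph = 7.5) {
  bm <- data.frame(glucose_consumed = glu, net_atp = atp, net_bile = mev,
                   energy_charge = ec, lactate_mM = lac, ph = ph)
  new("SimulationResult", biomarkers = bm,
      extents = matrix(0, 1, 1, dimnames = list(NULL, "x")),
      finalState = new("SystemState", amounts = c(a = 1)),
      convergence = list(),
      phase = protocolPhase("MP", 1, 16, uwSolution(), nSteps = 1L))
}

test_that("the scalar return is the exact weighted sum of its four metrics", {
  r <- fakeResult(glu = 1.5, atp = 2.398, mev = 0.1, ec = 0.6)
  expect_identical(returnValue(r, c(0, 0, 0, 0))$R, 0)
  # the net-ATP metric alone
  expect_identical(returnValue(r, c(0, 1, 0, 0))$R, 2.398)
  expect_identical(returnValue(r, c(1, 1, 1, 1))$R, 1.5 + 2.398 + 0.1 + 0.6)
  expect_equal(returnValue(r, c(2, 0, 1, 3))$R, 3 + 0.1 + 1.8)
})

test_that("viability is lactate <= 2.3 mM with strictly alkaline pH above 7.3", {
  expect_true(checkViability(fakeResult(1, 1, 1, 1, lac = 2.3, ph = 7.31)))
  expect_false(checkViability(fakeResult(1, 1, 1, 1, lac = 2.4, ph = 7.5)))
  expect_false(checkViability(fakeResult(1, 1, 1, 1, lac = 1.0, ph = 7.3)))
})

test_that("a zero-iteration optimisation returns the initial policy", {
  sim <- mpSimulator()
  init <- new("TemperaturePolicy", temps = rep(16, 8), stepHours = 1)
  w <- defaultWeights(sim(init))
  out <- optimizeTemperature(sim, init, w, mcConfig(n_iter = 0L))
  expect_identical(out$policy@temps, rep(16, 8))
  expect_identical(out$accepted, 0L)
  expect_identical(nrow(out$trace), 0L)
})

test_that("identical seeds give bit-identical acceptance traces", {
  sim <- mpSimulator()
  init <- new("TemperaturePolicy", temps = rep(16, 8), stepHours = 1)
  w <- defaultWeights(sim(init))
  a <- optimizeTemperature(sim, init, w, mcConfig(n_iter = 8L, seed = 11L))
  b <- optimizeTemperature(sim, init, w, mcConfig(n_iter = 8L, seed = 11L))
  expect_identical(a$trace, b$trace)
  expect_identical(a$policy@temps, b$policy@temps)
})

test_that("every accepted policy is monotone, viable and physiological", {
  sim <- mpSimulator()
  init <- new("TemperaturePolicy", temps = rep(16, 8), stepHours = 1)
  w <- defaultWeights(sim(init))
  out <- optimizeTemperature(sim, init, w, mcConfig(n_iter = 40L, seed = 3L))
  tr <- out$trace
  acc <- tr[tr$accepted, ]
  expect_gt(nrow(acc), 0)
  expect_true(all(acc$viable))
  expect_true(all(acc$physiology))
  # R of the incumbent is strictly increasing along the acceptance chain
  expect_true(all(diff(acc$R) > 0 | diff(acc$R) == 0) &&
                !is.unsorted(acc$R))
  expect_true(all(acc$R > acc$R_incumbent))
  # the accepted best warms over the phase and stays within bounds
  temps <- out$policy@temps
  expect_true(all(diff(temps) >= 0))
  expect_gt(temps[length(temps)], temps[1])
  expect_true(all(temps >= 16 & temps <= 37))
  # and its return is at least the initial return
  expect_gte(out$R, returnValue(sim(init), w)$R)
})

test_that("an infeasible initial policy is rejected up front", {
  sim <- function(policy) fakeResult(1, 1, 1, 1, lac = 5)
  init <- new("TemperaturePolicy", temps = rep(16, 4), stepHours = 1)
  expect_error(optimizeTemperature(sim, init, c(1, 1, 1, 1)),
               "not feasible")
})

test_that("the glutathione minimiser returns the lower bound when it is feasible", {
  # zero perturbation: the unperturbed warming baseline already ends inside
  # the normal band, so the search should terminate at its lower bound
  sim <- function(gsh) {
    m <- williamsMediumE()
    m@components$amount_nmol[m@components$id == "gsh_e"] <- gsh
    suppressWarnings(
      simulatePhase(liverNet(), postScs(), mpPhase(warmingPolicy(), m),
                    cfg = liverCfg())
    )
  }
  out <- minimizeGsh(sim, mcConfig(n_iter = 60L, seed = 5L))
  expect_true(out$feasible)
  expect_identical(out$gsh, 2.22e-5)
  expect_gte(out$h2o2, 1e-9)
  expect_lte(out$h2o2, 1e-8)
  expect_true(all(out$trace$gsh >= 2.22e-5 & out$trace$gsh <= 25.2e-5))
  # deterministic under the seed
  out2 <- minimizeGsh(sim, mcConfig(n_iter = 60L, seed = 5L))
  expect_identical(out$gsh, out2$gsh)
  expect_identical(out$trace, out2$trace)
})

test_that("an unreachable band reports infeasibility at the upper bound", {
  sim <- function(gsh) fakeResult(1, 1, 1, 1)
  # the fake run reports no h2o2 column value in band
  sim <- function(gsh) {
    r <- fakeResult(1, 1, 1, 1)
    r@biomarkers$h2o2_M <- 5e-7
    r
  }
  out <- minimizeGsh(sim, mcConfig(n_iter = 10L))
  expect_false(out$feasible)
  expect_identical(out$gsh, 25.2e-5)
})

test_that("the inflammation sweep validates and formats its inputs", {
  expect_error(inflammationSweep(function(p) NULL, c(3, 1)), "ascending")
  empty <- inflammationSweep(function(p) NULL, numeric(0))
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("perturbation", "h2o2_initial_M", "o2_consumed",
                    "gsh_gssg_ratio", "etc_atp", "energy_charge")
                  %in% names(empty)))
})
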