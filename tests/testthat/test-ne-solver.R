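# The Nash-equilibrium core: node minimisation and the successive
# substitution outer loop, checked against closed forms and brute force.

test_that("a symmetric isomerisation splits 50/50", {
  net <- isoNet(K = 1)
  st <- new("SystemState", amounts = c(A = 1, B = 0), temperature = 298)
  sol <- solveNode(net, "n1", st, 298)
  expect_equal(unname(sol$extents["iso"]), 0.5, tolerance = 1e-6)
  expect_lte(sol$gibbs, sol$gibbs0)
})

test_that("one-reaction equilibria match K = exp(-dG0/RT) to 3 significant figures", {
  # grid-search oracle over the extent, then the solver, for several K
  for (K in c(0.25, 1, 3, 10, 40)) {
    net <- isoNet(K)
    st <- new("SystemState", amounts = c(A = 1, B = 0), temperature = 298)
    # independent 1-D oracle: minimise the mixture Gibbs energy on a grid
    g0 <- c(0, -log(K))
    obj <- function(xi) mixtureGibbs(c(1 - xi, xi), g0)
    grid <- seq(1e-6, 1 - 1e-6, length.out = 20001)
    oracle <- grid[which.min(vapply(grid, obj, numeric(1)))]
    sol <- solveNode(net, "n1", st, 298)
    xb <- unname(sol$extents["iso"])
    expect_equal(xb, oracle, tolerance = 1e-4)
    expect_equal(xb / (1 - xb), K, tolerance = 5e-4) # 3 sig figs
  }
})

test_that("a K = 3 isomerisation reaches product:reactant of 3", {
  net <- isoNet(3)
  st <- new("SystemState", amounts = c(A = 1, B = 0), temperature = 298)
  sol <- solveNode(net, "n1", st, 298)
  ratio <- sol$extents[["iso"]] / (1 - sol$extents[["iso"]])
  expect_equal(ratio, 3, tolerance = 1e-4)
})

test_that("irreversible reactions are clamped at the zero-extent bound", {
  # equilibrium lies in the reverse direction, start from all-B
  net <- isoNet(K = 0.1, irreversible = TRUE)
  st <- new("SystemState", amounts = c(A = 0, B = 1), temperature = 298)
  sol <- solveNode(net, "n1", st, 298)
  expect_equal(unname(sol$extents["iso"]), 0)
  expect_equal(sol$gibbs, sol$gibbs0)
})

test_that("capacity bounds cap the extent", {
  net <- isoNet(K = 10)
  st <- new("SystemState", amounts = c(A = 1, B = 0), temperature = 298)
  sol <- solveNode(net, "n1", st, 298,
                   solverSettings(capacity = c(iso = 0.3)))
  expect_equal(unname(sol$extents["iso"]), 0.3, tolerance = 1e-9)
})

test_that("a two-node chain agrees with whole-network minimisation", {
  # A -> B at node 1, B -> C at node 2; global equilibrium is the
  # mass-action composition 1 : K1 : K1 K2
  RT <- 8.314e-3 * 298
  K1 <- 2
  K2 <- 3
  sp <- data.frame(
    id = c("A", "B", "C"), name = c("A", "B", "C"), formula = "C6H12O6",
    charge = 0, dGf0 = c(0, -RT * log(K1), -RT * log(K1 * K2)), dHf0 = 0,
    compartment = "c", stringsAsFactors = FALSE
  )
  net <- metabolicNetwork(sp, list(
    new("Reaction", id = "r1", stoich = c(A = -1, B = 1), node = "n1"),
    new("Reaction", id = "r2", stoich = c(B = -1, C = 1), node = "n2")
  ))
  st <- new("SystemState", amounts = c(A = 1, B = 0, C = 0),
            temperature = 298)
  out <- neIterate(net, st, 298, solverSettings(eps = 1e-6, maxOuter = 500))
  expect_true(out$report$converged)
  # brute-force 2-D grid oracle over both extents
  g0 <- c(0, -log(K1), -log(K1 * K2))
  G <- function(x1, x2) {
    n <- c(1 - x1, x1 - x2, x2)
    if (any(n < -1e-12)) return(Inf)
    sum(n) * mixtureGibbs(pmax(n, 0), g0)
  }
  grid <- expand.grid(x1 = seq(0, 1, 2e-3), x2 = seq(0, 1, 2e-3))
  grid <- grid[grid$x2 <= grid$x1, ]
  v <- mapply(G, grid$x1, grid$x2)
  best <- grid[which.min(v), ]
  bruteAmounts <- c(1 - best$x1, best$x1 - best$x2, best$x2)
  expect_equal(unname(out$state@amounts), bruteAmounts, tolerance = 5e-3)
  # and the analytic mass-action composition to the outer tolerance
  expect_equal(unname(out$state@amounts),
               c(1, K1, K1 * K2) / (1 + K1 + K1 * K2), tolerance = 1e-3)
})

test_that("a single-node network converges within two outer iterations", {
  net <- isoNet(2)
  st <- new("SystemState", amounts = c(A = 1, B = 0), temperature = 298)
  out <- neIterate(net, st, 298)
  expect_true(out$report$converged)
  expect_lte(out$report$outer_iterations, 2L)
})

test_that("an exhausted step budget returns the state unchanged", {
  net <- isoNet(2)
  st <- new("SystemState", amounts = c(A = 1, B = 0), temperature = 298)
  out <- neIterate(net, st, 298, solverSettings(maxOuter = 0L))
  expect_false(out$report$converged)
  expect_identical(out$state@amounts, st@amounts)
  expect_true(all(out$extents == 0))
})

test_that("element and charge totals are conserved by every outer iteration", {
  net <- liverNet()
  st <- initialLiverState(net)
  tot0 <- elementTotals(net, st@amounts)
  out <- suppressWarnings(neIterate(net, st, 289.15, solverSettings(
    capacity = c(R_MNT = 0.05, R_LEAK = 0)
  )))
  tot1 <- elementTotals(net, out$state@amounts)
  expect_lt(max(abs(tot1 - tot0) / pmax(abs(tot0), 1)), 1e-9)
})

test_that("the solver is deterministic and never increases the objective", {
  net <- liverNet()
  st <- initialLiverState(net)
  sets <- solverSettings(capacity = c(R_MNT = 0.05, R_LEAK = 0))
  a <- suppressWarnings(neIterate(net, st, 310.15, sets))
  b <- suppressWarnings(neIterate(net, st, 310.15, sets))
  expect_identical(a$extents, b$extents)
  expect_identical(a$state@amounts, b$state@amounts)
  for (nd in nodeIds(net)) {
    sol <- solveNode(net, nd, st, 310.15, sets)
    expect_lte(sol$gibbs, sol$gibbs0 + 1e-9 * (1 + abs(sol$gibbs0)))
  }
})
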