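## The Nash-equilibrium flux computation.  Each node (one NLP sub-problem per
## enzyme group) minimises the extensive dimensionless Gibbs energy of its
## component set over its reaction extents, subject to non-negative amounts
## and irreversibility bounds; the outer loop sweeps the nodes by successive
## substitution, holding every other node's current optimal fluxes fixed, and
## stops when the 2-norm of the transport-flux change falls below tolerance.
##
## The inner NLP is a cyclic coordinate descent (compiled, src/cd_solve.cpp):
## the ideal-mixture Gibbs energy is convex in the extents and its derivative
## along one extent is monotone, so each coordinate step is an exact
## safeguarded bisection.  Descent is monotone from the always-feasible zero
## extent, so the objective never ends above its starting value and the
## solve is deterministic.

#' Default solver settings
#'
#' @param eps outer-loop tolerance on the 2-norm of the transport-flux change
#' @param maxOuter outer iteration budget
#' @param damping successive-substitution damping factor in (0, 1]; 1 = none
#'   (the sweep halves it automatically if the plain iteration oscillates)
#' @param seed seed for the stochastic components built on top of the solver
#'   (the solver itself is deterministic)
#' @param capacity named numeric of per-reaction extent upper bounds
#'   (nmol/cell per step); missing means unbounded
#' @param maxRounds coordinate-descent round budget for one node solve
#' @return list of settings
#' @export
solverSettings <- function(eps = 1e-3, maxOuter = 80L, damping = 1,
                           seed = 1L, capacity = numeric(0),
                           maxRounds = 200L) {
  list(eps = eps, maxOuter = maxOuter, damping = damping, seed = seed,
       capacity = capacity, maxRounds = maxRounds)
}

## per-node solve structures, computed once per network sweep
.nodeStructs <- function(net, settings) {
  lapply(net@nodes, function(nd) {
    rids <- net@reactions$id[net@reactions$node == nd]
    comp <- nodeComponents(net, nd)
    S <- net@stoich[comp, rids, drop = FALSE]
    idx <- match(comp, net@species$id)
    cap <- rep(Inf, length(rids))
    if (length(settings$capacity)) {
      hit <- intersect(names(settings$capacity), rids)
      cap[match(hit, rids)] <- settings$capacity[hit]
    }
    list(node = nd, rids = rids, comp = comp, S = S, idx = idx,
         irr = net@reactions$irreversible[match(rids, net@reactions$id)],
         cap = cap)
  })
}

.solveNodeFast <- function(ns, amounts, g0all, maxRounds) {
  n0 <- pmax(amounts[ns$comp], 0)
  sol <- cdSolveNode(ns$S, n0, g0all[ns$idx], ns$irr, ns$cap,
                     maxRounds = maxRounds)
  setNames(sol$xi, ns$rids)
}

#' Minimise the Gibbs energy of one network node
#'
#' Solves the node's NLP: minimise the dimensionless mixture Gibbs energy of
#' the node's component set over its reaction extents, subject to
#' non-negative amounts, extent lower bounds of zero for irreversible
#' reactions, and optional capacity bounds.  The zero extent is always
#' feasible and the coordinate descent is monotone, so the returned solution
#' never has a higher objective than the zero-extent start.
#'
#' @param net a [MetabolicNetwork-class]
#' @param node node id
#' @param state a [SystemState-class] (amounts for the node components are
#'   read from it)
#' @param T absolute temperature, K
#' @param settings list from [solverSettings()]
#' @return list with `extents` (named), `gibbs` (objective at solution),
#'   `gibbs0` (objective at zero extent), `status`
#' @export
solveNode <- function(net, node, state, T, settings = solverSettings()) {
  if (!node %in% net@nodes) stop("no such node: ", node)
  g0all <- gibbsHelmholtz(net@species$dGf0, net@species$dHf0, T)
  ns <- .nodeStructs(net, settings)[[match(node, net@nodes)]]
  n0 <- pmax(state@amounts[ns$comp], 0)
  if (sum(n0) <= 0) stop("node ", node, " has no material")
  g0 <- g0all[ns$idx]
  sol <- cdSolveNode(ns$S, n0, g0, ns$irr, ns$cap,
                     maxRounds = settings$maxRounds)
  f0 <- mixtureGibbs(n0, g0) * sum(n0) # extensive reference
  status <- if (sol$gibbs <= f0 + 1e-9 * (1 + abs(f0))) "ok" else "no-improvement"
  list(extents = setNames(sol$xi, ns$rids), gibbs = sol$gibbs, gibbs0 = f0,
       status = status)
}

## private RNG stream, isolated from the global .Random.seed
.makeRng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  with_state <- function(fn) {
    function(...) {
      prev <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(prev)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", prev, globalenv())
      })
      fn(...)
    }
  }
  list(runif = with_state(stats::runif), rnorm = with_state(stats::rnorm),
       sample = with_state(base::sample.int))
}

#' One Nash-equilibrium time step by successive substitution
#'
#' Sweeps all nodes in fixed (network) order.  Node j is solved from the
#' start-of-step state with every other node's current optimal extents
#' applied, then its own extents are updated (Gauss-Seidel successive
#' substitution).  After each sweep the transport-flux vector is compared to
#' the previous sweep; the iteration stops when the 2-norm of the difference
#' is below `settings$eps` or the outer budget is exhausted.
#'
#' @param net a [MetabolicNetwork-class]
#' @param state start-of-step [SystemState-class]
#' @param T absolute temperature, K
#' @param settings list from [solverSettings()]
#' @return list with `state` (end-of-step), `extents` (named vector over all
#'   reactions), `report` (outer_iterations, final_norm, converged,
#'   tolerance), `nodeStatus`
#' @export
neIterate <- function(net, state, T, settings = solverSettings()) {
  rids <- net@reactions$id
  trans <- rids[net@reactions$transport]
  xi <- setNames(numeric(length(rids)), rids)
  report <- list(outer_iterations = 0L, final_norm = NA_real_,
                 converged = FALSE, tolerance = settings$eps)
  status <- setNames(rep("not-run", length(net@nodes)), net@nodes)
  if (settings$maxOuter < 1L) {
    return(list(state = state, extents = xi, report = report,
                nodeStatus = status))
  }
  g0all <- gibbsHelmholtz(net@species$dGf0, net@species$dHf0, T)
  structs <- .nodeStructs(net, settings)
  S <- net@stoich
  a <- state@amounts
  damp <- settings$damping
  prevNrm <- Inf
  for (it in seq_len(settings$maxOuter)) {
    ## incremental successive substitution: each node re-optimises from the
    ## current running state and its extent increment accumulates, so the
    ## state stays feasible throughout and the iteration is block-coordinate
    ## descent on the whole-network Gibbs energy.  Damping shrinks the
    ## increments if the plain sweep oscillates
    if (it > 0.75 * settings$maxOuter) {
      damp <- min(damp, 0.25)
    } else if (it > settings$maxOuter / 2 && damp == 1) {
      damp <- 0.5
    }
    inc2 <- 0
    trInc2 <- 0
    for (ns in structs) {
      ## capacity bounds are per step: debit the extents already accumulated
      nsEff <- ns
      nsEff$cap <- pmax(ns$cap - xi[ns$rids], 0)
      delta <- damp * .solveNodeFast(nsEff, a, g0all, settings$maxRounds)
      status[ns$node] <- "ok"
      xi[ns$rids] <- xi[ns$rids] + delta
      a[ns$comp] <- a[ns$comp] + drop(ns$S %*% delta)
      inc2 <- inc2 + sum(delta^2)
      trInc2 <- trInc2 + sum(delta[ns$rids %in% trans]^2)
    }
    ## the tear streams are the transport fluxes, but nodes couple through
    ## shared cofactor pools too, so the stopping norm covers the transport
    ## increments and the full extent increment alike.  A small but growing
    ## increment (an exchange cycle bootstrapping from a trace pool) is not
    ## convergence, so the norm must also be non-increasing
    nrm <- max(sqrt(trInc2), sqrt(inc2))
    report$outer_iterations <- it
    report$final_norm <- nrm
    if (nrm < settings$eps && nrm <= prevNrm) {
      report$converged <- TRUE
      break
    }
    prevNrm <- nrm
  }
  if (min(a) < -1e-6) {
    warning("negative amounts after NE step (min ", format(min(a)), ")")
  }
  newState <- new("SystemState", amounts = pmax(a, 0), temperature = T,
                  time = state@time)
  list(state = newState, extents = xi, report = report, nodeStatus = status)
}
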