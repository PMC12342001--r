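## Monte Carlo optimisation layer: gradual-warming temperature-policy search
## under the viability and physiology acceptance rules, and minimisation of
## glutathione supplementation subject to the hydrogen-peroxide band.

#' Monte Carlo configuration
#'
#' @param n_iter iteration budget
#' @param seed RNG seed (all proposals are drawn from a private stream)
#' @param proposal_scale half-normal scale of temperature increments, degrees C
#' @param gsh_bounds lower/upper bounds on the glutathione supplement,
#'   nmol/cell
#' @param h2o2_band normal mitochondrial [H2O2] band, M
#' @param perturbation hydrogen peroxide perturbation at the start of machine
#'   perfusion, nmol/cell
#' @param resolution termination resolution of the supplement search,
#'   nmol/cell
#' @param t_range feasible temperature range of a policy, degrees C
#' @return list of settings
#' @export
mcConfig <- function(n_iter = 200L, seed = 1L, proposal_scale = 4,
                     gsh_bounds = c(2.22e-5, 25.2e-5),
                     h2o2_band = c(1e-9, 1e-8), perturbation = 0,
                     resolution = 1e-6, t_range = c(16, 37)) {
  stopifnot(gsh_bounds[1] < gsh_bounds[2], h2o2_band[1] < h2o2_band[2],
            n_iter >= 0)
  list(n_iter = as.integer(n_iter), seed = seed,
       proposal_scale = proposal_scale, gsh_bounds = gsh_bounds,
       h2o2_band = h2o2_band, perturbation = perturbation,
       resolution = resolution, t_range = t_range)
}

#' Scalar return of a machine-perfusion run
#'
#' R = w1*Glu + w2*ATP + w3*Mev + w4*EC, with Glu the glucose consumed
#' (nmol/cell), ATP the net ATP change (nmol/cell), Mev the mevalonate (bile
#' proxy) produced (nmol/cell) and EC the final energy charge.
#'
#' @param result a [SimulationResult-class]
#' @param weights numeric length 4 (w1..w4)
#' @return list with the four metrics, the weights and the scalar `R`
#' @export
returnValue <- function(result, weights = c(1, 1, 1, 1)) {
  stopifnot(length(weights) == 4)
  b <- result@biomarkers[nrow(result@biomarkers), ]
  m <- c(Glu = b$glucose_consumed, ATP = b$net_atp, Mev = b$net_bile,
         EC = b$energy_charge)
  list(Glu = unname(m[1]), ATP = unname(m[2]), Mev = unname(m[3]),
       EC = unname(m[4]), weights = weights, R = sum(weights * m))
}

#' Default return-function weights
#'
#' The four metrics live on different scales, so each weight is the
#' reciprocal of the metric's magnitude in a reference (baseline) run; the
#' weighted metrics then enter the return on equal footing.
#'
#' @param baseline a baseline [SimulationResult-class]
#' @param floor smallest magnitude used for normalisation
#' @return numeric length 4
#' @export
defaultWeights <- function(baseline, floor = 1e-6) {
  rv <- returnValue(baseline)
  1 / pmax(abs(c(rv$Glu, rv$ATP, rv$Mev, rv$EC)), floor)
}

#' Liver viability of a perfusion run
#'
#' TRUE iff final lactate <= 2.3 mM and final pH > 7.3.
#'
#' @param result a [SimulationResult-class]
#' @return logical
#' @export
checkViability <- function(result) {
  b <- result@biomarkers[nrow(result@biomarkers), ]
  isTRUE(b$lactate_mM <= 2.3 && b$ph > 7.3)
}

#' Monte Carlo optimisation of the gradual-warming temperature policy
#'
#' Starting from a feasible (monotone, viable) policy, each iteration picks a
#' random step k and adds a half-normal increment to temperatures k..N
#' (clamped to the configured range), which preserves monotonicity by
#' construction.  A proposal is accepted iff the return R strictly
#' increases, the policy is monotone, all six physiology criteria hold and
#' the viability constraints (lactate <= 2.3 mM, pH > 7.3) are met.
#'
#' @param simulate function(policy) -> [SimulationResult-class]; must
#'   simulate machine perfusion from a fixed post-SCS state
#' @param initial a [TemperaturePolicy-class] (or numeric vector, degrees C)
#' @param weights return-function weights (w1..w4)
#' @param config list from [mcConfig()]
#' @return list with `policy` (best accepted), `R`, `trace` (data.frame, one
#'   row per iteration), `accepted` (count)
#' @export
optimizeTemperature <- function(simulate, initial, weights,
                                config = mcConfig()) {
  if (is.numeric(initial)) {
    initial <- new("TemperaturePolicy", temps = initial, stepHours = 1)
  }
  rng <- .makeRng(config$seed)
  inc <- initial@temps
  res0 <- simulate(initial)
  if (!checkViability(res0) || !physiologyCheck(res0)$pass) {
    stop("initial temperature policy is not feasible")
  }
  Rinc <- returnValue(res0, weights)$R
  n <- length(inc)
  trace <- vector("list", config$n_iter)
  acc <- 0L
  for (it in seq_len(config$n_iter)) {
    k <- rng$sample(n, 1L)
    delta <- abs(rng$rnorm(1, 0, config$proposal_scale))
    prop <- inc
    prop[k:n] <- pmin(pmax(prop[k:n] + delta, config$t_range[1]),
                      config$t_range[2])
    prop <- cummax(prop) # monotone by construction; guard against clamping
    res <- simulate(new("TemperaturePolicy", temps = prop,
                        stepHours = initial@stepHours))
    rv <- returnValue(res, weights)
    viable <- checkViability(res)
    phys <- physiologyCheck(res)$pass
    better <- rv$R > Rinc
    verdict <- better && viable && phys
    fail <- if (verdict) "" else if (!better) "no-R-increase" else
      if (!phys) "physiology" else "viability"
    trace[[it]] <- data.frame(
      iteration = it, step = k, delta = delta, R = rv$R, R_incumbent = Rinc,
      viable = viable, physiology = phys, accepted = verdict,
      failed = fail, policy = paste(signif(prop, 4), collapse = "/"),
      stringsAsFactors = FALSE
    )
    if (verdict) {
      inc <- prop
      Rinc <- rv$R
      acc <- acc + 1L
    }
  }
  list(
    policy = new("TemperaturePolicy", temps = inc,
                 stepHours = initial@stepHours),
    R = Rinc,
    trace = if (config$n_iter > 0) do.call(rbind, trace) else data.frame(),
    accepted = acc
  )
}

#' Monte Carlo minimisation of glutathione supplementation
#'
#' Finds the smallest glutathione supplement in the configured bounds such
#' that the end-of-perfusion mitochondrial [H2O2] lies inside the normal
#' band.  The search shrinks a Monte Carlo envelope around the best feasible
#' supplement: proposals are drawn uniformly between the lower bound and the
#' incumbent, and a feasible proposal replaces the incumbent.  The search
#' stops at the configured resolution; if the incumbent converges onto the
#' lower bound and the lower bound itself is feasible, the bound is
#' returned.
#'
#' @param simulate function(gsh_supplement) -> [SimulationResult-class] for
#'   machine perfusion with the supplement in the perfusate
#' @param config list from [mcConfig()]
#' @return list with `gsh` (nmol/cell), `feasible` (logical; FALSE when even
#'   the upper bound fails), `h2o2` (final concentration at `gsh`, M),
#'   `evaluations` (count), `trace`
#' @export
minimizeGsh <- function(simulate, config = mcConfig()) {
  L <- config$gsh_bounds[1]
  U <- config$gsh_bounds[2]
  band <- config$h2o2_band
  rng <- .makeRng(config$seed)
  evals <- 0L
  feasible <- function(s) {
    res <- simulate(s)
    evals <<- evals + 1L
    h <- res@biomarkers$h2o2_M[nrow(res@biomarkers)]
    list(ok = h >= band[1] && h <= band[2], h2o2 = h)
  }
  fU <- feasible(U)
  trace <- list(data.frame(gsh = U, feasible = fU$ok, h2o2 = fU$h2o2))
  if (!fU$ok) {
    return(list(gsh = U, feasible = FALSE, h2o2 = fU$h2o2,
                evaluations = evals, trace = do.call(rbind, trace)))
  }
  best <- U
  hbest <- fU$h2o2
  for (it in seq_len(config$n_iter)) {
    if (best - L <= config$resolution) break
    s <- rng$runif(1, L, best)
    fs <- feasible(s)
    trace[[length(trace) + 1L]] <-
      data.frame(gsh = s, feasible = fs$ok, h2o2 = fs$h2o2)
    if (fs$ok) {
      best <- s
      hbest <- fs$h2o2
    }
  }
  if (best - L <= config$resolution) {
    fL <- feasible(L)
    trace[[length(trace) + 1L]] <-
      data.frame(gsh = L, feasible = fL$ok, h2o2 = fL$h2o2)
    if (fL$ok) {
      best <- L
      hbest <- fL$h2o2
    }
  }
  list(gsh = best, feasible = TRUE, h2o2 = hbest, evaluations = evals,
       trace = do.call(rbind, trace))
}

#' Hydrogen peroxide perturbation sweep (inflammation regime)
#'
#' One machine-perfusion simulation per perturbation (sorted ascending),
#' with the glutathione supplement fixed at the perfusate's tabulated
#' amount.  Returns the Fig-style table of end-of-phase responses.
#'
#' @param simulate function(perturbation) -> [SimulationResult-class]
#' @param perturbations nmol/cell, ascending
#' @param volume per-cell volume for the concentration axis, nmol/(cell mM)
#' @return data.frame with columns perturbation, h2o2_initial_M,
#'   o2_consumed, gsh_gssg_ratio, etc_atp, energy_charge
#' @export
inflammationSweep <- function(simulate, perturbations,
                              volume = defaultVolume()) {
  if (is.unsorted(perturbations)) {
    stop("perturbations must be sorted ascending")
  }
  rows <- lapply(perturbations, function(p) {
    res <- simulate(p)
    b <- res@biomarkers[nrow(res@biomarkers), ]
    data.frame(
      perturbation = p,
      h2o2_initial_M = p / volume / 1000,
      o2_consumed = b$o2_consumed,
      gsh_gssg_ratio = b$gsh_gssg_ratio,
      etc_atp = 5 * sum(res@extents[, "R_OXP"]),
      energy_charge = b$energy_charge
    )
  })
  if (!length(rows)) {
    return(data.frame(perturbation = numeric(0), h2o2_initial_M = numeric(0),
                      o2_consumed = numeric(0), gsh_gssg_ratio = numeric(0),
                      etc_atp = numeric(0), energy_charge = numeric(0)))
  }
  do.call(rbind, rows)
}
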