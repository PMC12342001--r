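## Protocol engine: static cold storage and machine perfusion phases over the
## Nash-equilibrium core, with reactive-oxygen-species bookkeeping (purine
## degradation during hypoxia, electron-transport-chain leakage during
## perfusion, cytochrome-c-oxidase dysfunction above the oxidative-stress
## threshold) and the per-step biomarker panel.

#' Simulation configuration
#'
#' @param volume intracellular per-cell volume, nmol/(cell mM), used for all
#'   concentration/amount conversions
#' @param o2PerStep extracellular oxygen made available at each machine
#'   perfusion step, nmol/cell (perfusate oxygenation)
#' @param scsXoRate forced per-hour extent through each purine-degradation
#'   reaction during hypoxic cold storage, nmol/cell (the hypoxic superoxide
#'   source; clamped by substrate availability)
#' @param maintenanceAtp maintenance ATP load at 37 C, nmol/cell per h
#' @param maintenanceQ10 Q10 factor for the temperature scaling of the
#'   maintenance load
#' @param dysfunctionThreshold mitochondrial [H2O2] (M) above which
#'   cytochrome-c-oxidase dysfunction sets in (oxidative-stress threshold)
#' @param dysfunctionSteepness dimensionless steepness of the dysfunction
#'   attenuation
#' @param h2o2Band normal mitochondrial [H2O2] band, M
#' @param solventWater extracellular water replenished after a flush (the
#'   media tables list solutes only), nmol/cell
#' @param oxpCapacity per-step cap on the oxidative-phosphorylation extent,
#'   nmol/cell (scalar or one value per step; Inf = thermodynamics only).
#'   The cytochrome-oxidase attenuation multiplies this cap, so a finite
#'   reference capacity makes the dysfunction response strict
#' @param catCapacity catalase throughput at 37 C, nmol/cell per step; the
#'   strong cold suppression (see `catQ10`) saturates the catalase channel
#'   at cold steps so that marginal peroxide loads fall on glutathione
#'   peroxidase, as they do in the mitochondrial matrix
#' @param catQ10 Q10 factor of the catalase capacity
#' @return list of configuration values
#' @export
simConfig <- function(volume = defaultVolume(), o2PerStep = 4,
                      scsXoRate = 2e-4, maintenanceAtp = 0.45,
                      maintenanceQ10 = 2.2, dysfunctionThreshold = 3e-8,
                      dysfunctionSteepness = 0.002, h2o2Band = c(1e-9, 1e-8),
                      solventWater = 5.54, oxpCapacity = Inf,
                      catCapacity = 2e-3, catQ10 = 20) {
  list(volume = volume, o2PerStep = o2PerStep, scsXoRate = scsXoRate,
       maintenanceAtp = maintenanceAtp, maintenanceQ10 = maintenanceQ10,
       dysfunctionThreshold = dysfunctionThreshold,
       dysfunctionSteepness = dysfunctionSteepness, h2o2Band = h2o2Band,
       solventWater = solventWater, oxpCapacity = oxpCapacity,
       catCapacity = catCapacity, catQ10 = catQ10)
}

#' Construct a protocol phase
#'
#' @param kind "SCS" or "MP"
#' @param duration phase duration, h
#' @param temperature constant temperature (degrees C) or a
#'   [TemperaturePolicy-class] with one entry per step
#' @param medium the [Medium-class] applied to the extracellular space at
#'   phase start
#' @param nSteps number of time steps (default: one per hour)
#' @param hypoxic no oxygen supply (default TRUE for SCS)
#' @param leakFraction fraction of ETC oxygen consumption diverted to
#'   superoxide during MP
#' @return a [ProtocolPhase-class]
#' @export
protocolPhase <- function(kind, duration, temperature, medium,
                          nSteps = as.integer(duration),
                          hypoxic = identical(kind, "SCS"),
                          leakFraction = 0.02) {
  new("ProtocolPhase", kind = kind, duration = duration,
      nSteps = as.integer(nSteps), temperature = temperature,
      medium = medium, hypoxic = hypoxic, leakFraction = leakFraction)
}

#' Adenylate energy charge
#'
#' Atkinson's index (ATP + ADP/2) / (ATP + ADP + AMP), in [0, 1].
#'
#' @param atp,adp,amp pool sizes, nmol/cell
#' @return dimensionless energy charge
#' @export
energyCharge <- function(atp, adp, amp) {
  tot <- atp + adp + amp
  if (any(tot <= 0)) stop("empty adenylate pool")
  (atp + 0.5 * adp) / tot
}

#' Cytosolic pH from the tracked proton pool
#'
#' @param state a [SystemState-class]
#' @param volume per-cell volume, nmol/(cell mM)
#' @return pH (-log10 of the molar proton concentration)
#' @export
computePh <- function(state, volume = defaultVolume()) {
  h <- state@amounts["h_c"]
  if (is.na(h) || h <= 0) stop("proton pool must be positive")
  unname(-log10(h / volume / 1000))
}

#' Classify a hydrogen peroxide concentration
#'
#' Bands: normal [1e-9, 1e-8] M, elevated (1e-8, 3e-8), stress [3e-8, 1e-7),
#' damage >= 1e-7 M; concentrations below 1e-9 are reported as "low".
#'
#' @param h2o2_conc mitochondrial [H2O2], M
#' @return one of "low", "normal", "elevated", "stress", "damage"
#' @export
classifyRos <- function(h2o2_conc) {
  if (any(h2o2_conc < 0)) stop("concentration must be non-negative")
  ifelse(h2o2_conc < 1e-9, "low",
    ifelse(h2o2_conc <= 1e-8, "normal",
      ifelse(h2o2_conc < 3e-8, "elevated",
        ifelse(h2o2_conc < 1e-7, "stress", "damage"))))
}

## multiplicative attenuation of the oxphos node's O2-reduction capacity,
## = 1 below the stress threshold, smoothly decreasing above it
.dysfunction <- function(conc, cfg) {
  thr <- cfg$dysfunctionThreshold
  exp(-cfg$dysfunctionSteepness * pmax(0, conc - thr) / thr)
}

## apply a forced extent through one reaction, clamped so no consumed species
## goes negative; returns the applied extent
.applyForced <- function(a, S, rid, extent) {
  col <- S[, rid]
  cons <- col < 0
  if (any(cons)) {
    extent <- min(extent, min(a[names(col)[cons]] / -col[cons]))
  }
  extent <- max(extent, 0)
  list(amounts = a + col * extent, extent = extent)
}

#' Simulate one protocol phase
#'
#' Each step sets the temperature from the schedule, injects the phase's
#' superoxide source (SCS: a fixed forced extent through the
#' purine-degradation chain, clamped by substrate and residual-oxygen
#' availability; MP: electron-transport leakage routed to superoxide at
#' `leakFraction` of the oxygen consumed that step), applies the
#' ROS-dependent cytochrome-c-oxidase attenuation as an oxygen-availability
#' cap on the oxidative-phosphorylation node, runs the Nash-equilibrium
#' iteration, and records the biomarker panel.
#'
#' @param net the [MetabolicNetwork-class]
#' @param state start-of-phase [SystemState-class]
#' @param phase a [ProtocolPhase-class]
#' @param settings solver settings from [solverSettings()]
#' @param cfg simulation configuration from [simConfig()]
#' @param flush apply the phase medium to the extracellular space at phase
#'   start (default TRUE)
#' @return a [SimulationResult-class]
#' @export
simulatePhase <- function(net, state, phase, settings = solverSettings(),
                          cfg = simConfig(), flush = TRUE) {
  S <- net@stoich
  rids <- colnames(S)
  n <- phase@nSteps
  if (n == 0L || phase@duration == 0) {
    ## zero-duration phase: state unchanged, empty series
    return(new("SimulationResult",
               biomarkers = data.frame(), extents = ext0 <- matrix(
                 0, 0, length(rids), dimnames = list(NULL, rids)),
               finalState = state, convergence = list(), phase = phase))
  }
  stepH <- phase@duration / n
  sched <- if (is(phase@temperature, "TemperaturePolicy")) {
    if (length(phase@temperature@temps) != n) {
      stop("temperature policy length must equal the number of steps")
    }
    phase@temperature@temps
  } else {
    rep(phase@temperature, n)
  }
  if (flush) state <- applyFlush(state, phase@medium, net)
  a0 <- state@amounts
  ## media tables list solutes; the aqueous solvent itself is replenished
  a0["h2o_e"] <- max(a0["h2o_e"], cfg$solventWater)
  a <- a0
  ext <- matrix(0, n, length(rids), dimnames = list(NULL, rids))
  conv <- vector("list", n)
  rows <- vector("list", n)
  snaps <- vector("list", n)
  f <- phase@leakFraction

  for (s in seq_len(n)) {
    TK <- sched[s] + 273.15
    if (!phase@hypoxic) a["o2_e"] <- max(a["o2_e"], cfg$o2PerStep)
    h2o2M <- a["h2o2_m"] / cfg$volume / 1000
    phi <- .dysfunction(h2o2M, cfg)
    forced <- setNames(numeric(length(rids)), rids)
    if (phase@hypoxic) {
      for (rid in c("R_ADA", "R_XO1", "R_XO2")) {
        ap <- .applyForced(a, S, rid, cfg$scsXoRate * stepH)
        a <- ap$amounts
        forced[rid] <- forced[rid] + ap$extent
      }
    }
    mnt <- cfg$maintenanceAtp * cfg$maintenanceQ10^((TK - 310.15) / 10) * stepH
    o2avail <- sum(a[c("o2_e", "o2_c", "o2_m")])
    ## R_LEAK is bookkeeping for the prescribed electron leakage, never a
    ## spontaneous route: its NE extent is capped at zero and it runs only
    ## as the forced injection below
    oxpCap <- rep_len(cfg$oxpCapacity, n)[s]
    catCap <- cfg$catCapacity * cfg$catQ10^((TK - 310.15) / 10)
    settings$capacity <- c(R_MNT = unname(mnt),
                           R_OXP = unname(phi * min(oxpCap, o2avail)),
                           R_CAT = unname(catCap), R_LEAK = 0)
    st <- new("SystemState", amounts = a, temperature = TK,
              time = state@time + (s - 1) * stepH)
    ne <- neIterate(net, st, TK, settings)
    a <- ne$state@amounts
    xi <- ne$extents
    conv[[s]] <- ne$report
    if (!ne$report$converged) {
      warning("NE iteration did not converge at step ", s,
              " (norm ", format(ne$report$final_norm), ")")
    }
    leakO2 <- 0
    if (!phase@hypoxic && f > 0) {
      ## superoxide-forming O2 is exactly leakFraction of the O2 consumed
      ## this step (consumed = useful + leaked): leak = f/(1-f) * useful
      useful <- unname(xi["R_OXP"])
      ap <- .applyForced(a, S, "R_LEAK", f / (1 - f) * useful / 2)
      a <- ap$amounts
      forced["R_LEAK"] <- forced["R_LEAK"] + ap$extent
      leakO2 <- 2 * ap$extent
    }
    ## let the ROS node finish processing the step's superoxide/peroxide
    ## (dismutation draws on the trace proton pool, so this solve gets a
    ## generous coordinate-descent budget)
    st2 <- new("SystemState", amounts = a, temperature = TK, time = st@time)
    rosSettings <- settings
    rosSettings$maxRounds <- settings$maxRounds * 40L
    ## the catalase budget is per step: subtract what the NE pass used
    rosSettings$capacity["R_CAT"] <- max(0, catCap - unname(xi["R_CAT"]))
    ros <- solveNode(net, "ros", st2, TK, rosSettings)
    a <- a + drop(S[, names(ros$extents), drop = FALSE] %*% ros$extents)
    a <- pmax(a, 0)
    xi[names(ros$extents)] <- xi[names(ros$extents)] + ros$extents
    ext[s, ] <- xi + forced
    snaps[[s]] <- a
    useO2 <- unname(xi["R_OXP"])
    rows[[s]] <- data.frame(
      step = s, time = state@time + s * stepH, temperature_C = sched[s],
      energy_charge = energyCharge(a["atp_c"], a["adp_c"], a["amp_c"]),
      ph = -log10(a["h_c"] / cfg$volume / 1000),
      lactate_mM = a["lac_c"] / cfg$volume,
      h2o2_M = a["h2o2_m"] / cfg$volume / 1000,
      superoxide_M = a["o2s_m"] / cfg$volume / 1000,
      gsh_mM = (a["gsh_c"] + a["gsh_m"]) / cfg$volume,
      gsh_gssg_ratio = if (a["gssg_m"] > 0) {
        (a["gsh_c"] + a["gsh_m"]) / a["gssg_m"]
      } else {
        NA_real_
      },
      o2_step = useO2 + leakO2, o2_useful_step = useO2,
      o2_to_superoxide_step = leakO2,
      dysfunction = phi, converged = ne$report$converged,
      row.names = NULL
    )
  }
  bm <- do.call(rbind, rows)
  ## cumulative phase-net quantities (cell's perspective, relative to the
  ## post-flush start of the phase)
  delta <- function(ids, sgn) {
    sgn * vapply(snaps, function(v) sum(v[ids]) - sum(a0[ids]), numeric(1))
  }
  bm$o2_consumed <- cumsum(bm$o2_step)
  bm$o2_useful <- cumsum(bm$o2_useful_step)
  bm$o2_to_superoxide <- cumsum(bm$o2_to_superoxide_step)
  bm$gsh_consumed <- delta(c("gsh_e", "gsh_c", "gsh_m"), -1)
  bm$gssg_synthesized <- delta("gssg_m", +1)
  bm$net_atp <- delta("atp_c", +1)
  bm$net_bile <- delta("mev_c", +1)
  bm$net_h2o2 <- delta("h2o2_m", +1)
  bm$glucose_consumed <- delta(c("glc_e", "glc_c"), -1)
  final <- new("SystemState", amounts = a,
               temperature = sched[n] + 273.15,
               time = state@time + phase@duration)
  new("SimulationResult", biomarkers = bm, extents = ext,
      finalState = final, convergence = conv, phase = phase)
}

setMethod("show", "SimulationResult", function(object) {
  n <- nrow(object@biomarkers)
  last <- object@biomarkers[n, ]
  cat("SimulationResult:", object@phase@kind, "phase,", n, "steps,",
      format(object@phase@duration), "h\n")
  cat(sprintf("  final: EC %.3f | pH %.2f | lactate %.3f mM | [H2O2] %.3g M\n",
              last$energy_charge, last$ph, last$lactate_mM, last$h2o2_M))
})

#' Evaluate the six physiological-solution criteria
#'
#' A phase solution is physiologically meaningful iff (1) glycolysis produced
#' net ATP, (2) the ratio of net Krebs-cycle ATP to glucose consumed lies in
#' [0, 2], (3) oxidative phosphorylation synthesised ATP, (4) the committed
#' malonyl-CoA step ran forward only, (5) fatty-acid synthesis consumed ATP,
#' and (6) a net amount of glutathione disulfide was produced.
#'
#' @param result a [SimulationResult-class]
#' @return list of the six booleans plus `pass`
#' @export
physiologyCheck <- function(result) {
  tot <- colSums(result@extents)
  glyAtp <- 2 * tot["R_GLY"]
  gluCons <- tot["R_GLY"]
  krebsAtp <- tot["R_TCA"]
  ratio <- if (gluCons > 1e-12) krebsAtp / gluCons else 0
  gssg <- tot["R_GPX"]
  out <- list(
    glycolysis_net_atp_positive = unname(glyAtp > 0),
    krebs_atp_per_glucose_in_0_2 = unname(ratio >= 0 & ratio <= 2),
    oxphos_synthesizes_atp = unname(5 * tot["R_OXP"] > 0),
    malonyl_coa_forward_only = all(result@extents[, "R_ACC"] > -1e-9),
    fa_synthesis_consumes_atp = unname(tot["R_ACC"] > 0),
    net_gssg_produced = unname(gssg > 0)
  )
  out$pass <- all(unlist(out))
  out
}
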