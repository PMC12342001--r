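## Orchestration and reporting: a run configuration (YAML with JSON
## fallback) drives the full pipeline -- UW flush, static cold storage,
## machine perfusion or one of the Monte Carlo optimisers -- and every run
## writes a time-series CSV, a summary JSON carrying the seed and a
## configuration hash, and (for the optimisers) an acceptance-trace CSV.

#' Assemble a run configuration
#'
#' @param ... overrides of the default fields (nested lists are replaced
#'   whole)
#' @return list: seed, outputDir, scs/mp phase settings, simulation,
#'   solver and Monte Carlo settings, sweep perturbations
#' @export
runConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    outputDir = "perfusion-out",
    network = NULL,             # path to a network JSON; NULL = built-in
    scs = list(duration = 6, temperature = 4, nSteps = 6L),
    mp = list(duration = 8, temperature = 16, nSteps = 8L,
              leakFraction = 0.02),
    sim = list(),               # overrides for simConfig()
    solver = list(),            # overrides for solverSettings()
    mc = list(),                # overrides for mcConfig()
    perturbations = c(1, 25, 50, 100, 200, 300) * 1e-7
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a run configuration from YAML (JSON fallback)
#' @param path configuration file
#' @return configuration list (defaults filled in)
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  obj <- tryCatch(yaml::read_yaml(path),
                  error = function(e) jsonlite::read_json(path,
                                                          simplifyVector = TRUE))
  do.call(runConfig, obj)
}

.cfgHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

.buildContext <- function(cfg) {
  net <- if (is.null(cfg$network)) {
    buildReducedLiverNetwork()
  } else {
    readMetabolicNetwork(cfg$network)
  }
  sim <- do.call(simConfig, cfg$sim)
  solver <- do.call(solverSettings, c(cfg$solver, list(seed = cfg$seed)))
  mc <- do.call(mcConfig, c(cfg$mc[setdiff(names(cfg$mc), "seed")],
                            list(seed = cfg$seed)))
  scs <- protocolPhase("SCS", cfg$scs$duration, cfg$scs$temperature,
                       uwSolution(), nSteps = as.integer(cfg$scs$nSteps))
  list(net = net, sim = sim, solver = solver, mc = mc, scs = scs)
}

.mpPhase <- function(cfg, temperature, medium = williamsMediumE()) {
  protocolPhase("MP", cfg$mp$duration, temperature, medium,
                nSteps = as.integer(cfg$mp$nSteps),
                leakFraction = cfg$mp$leakFraction)
}

## perfusate with a different glutathione supplement
.wmeWithGsh <- function(gsh) {
  m <- williamsMediumE()
  m@components$amount_nmol[m@components$id == "gsh_e"] <- gsh
  m
}

.writeOutputs <- function(cfg, name, biomarkers, summary, trace = NULL) {
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  summary$seed <- cfg$seed
  summary$config_hash <- .cfgHash(cfg)
  if (!is.null(biomarkers) && nrow(biomarkers)) {
    utils::write.csv(biomarkers,
                     file.path(cfg$outputDir, paste0(name, "-timeseries.csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(summary,
                       file.path(cfg$outputDir, paste0(name, "-summary.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (!is.null(trace) && nrow(trace)) {
    utils::write.csv(trace, file.path(cfg$outputDir, paste0(name, "-trace.csv")),
                     row.names = FALSE)
  }
  invisible(file.path(cfg$outputDir, paste0(name, "-summary.json")))
}

.phaseSummary <- function(result) {
  b <- result@biomarkers[nrow(result@biomarkers), ]
  conv <- vapply(result@convergence, function(x) isTRUE(x$converged), logical(1))
  list(
    final = as.list(b),
    physiology = physiologyCheck(result),
    ne_converged_steps = sum(conv),
    ne_steps = length(conv)
  )
}

#' Run the baseline protocol (UW flush, SCS, machine perfusion)
#'
#' @param cfg configuration from [runConfig()] or [readRunConfig()]
#' @return invisibly, a list with the SCS and MP [SimulationResult-class]
#'   objects and the path of the summary JSON
#' @export
runBaseline <- function(cfg = runConfig()) {
  ctx <- .buildContext(cfg)
  st <- initialLiverState(ctx$net, volume = ctx$sim$volume)
  scsRes <- simulatePhase(ctx$net, st, ctx$scs, ctx$solver, ctx$sim)
  mpRes <- simulatePhase(ctx$net, scsRes@finalState,
                         .mpPhase(cfg, cfg$mp$temperature), ctx$solver,
                         ctx$sim)
  bm <- rbind(cbind(phase = "SCS", scsRes@biomarkers),
              cbind(phase = "MP", mpRes@biomarkers))
  path <- .writeOutputs(cfg, "baseline", bm, list(
    scs = .phaseSummary(scsRes), mp = .phaseSummary(mpRes)
  ))
  invisible(list(scs = scsRes, mp = mpRes, summary = path))
}

#' Run the Monte Carlo temperature-policy optimisation
#'
#' @param cfg configuration from [runConfig()]
#' @return invisibly, list with the optimizer output, the final simulation
#'   under the best policy, and the summary path
#' @export
runOptTemp <- function(cfg = runConfig()) {
  ctx <- .buildContext(cfg)
  st <- initialLiverState(ctx$net, volume = ctx$sim$volume)
  scsRes <- simulatePhase(ctx$net, st, ctx$scs, ctx$solver, ctx$sim)
  post <- scsRes@finalState
  simulate <- function(policy) {
    simulatePhase(ctx$net, post, .mpPhase(cfg, policy), ctx$solver, ctx$sim)
  }
  init <- new("TemperaturePolicy",
              temps = rep(cfg$mp$temperature, cfg$mp$nSteps),
              stepHours = cfg$mp$duration / cfg$mp$nSteps)
  weights <- defaultWeights(simulate(init))
  opt <- optimizeTemperature(simulate, init, weights, ctx$mc)
  best <- simulate(opt$policy)
  path <- .writeOutputs(cfg, "opt-temp", best@biomarkers, list(
    policy_C = opt$policy@temps, R = opt$R, accepted = opt$accepted,
    weights = weights, mp = .phaseSummary(best)
  ), trace = opt$trace)
  invisible(list(optimizer = opt, mp = best, summary = path))
}

#' Run the Monte Carlo glutathione-supplement minimisation
#'
#' @param cfg configuration from [runConfig()]; `cfg$mc$perturbation` sets
#'   the hydrogen peroxide perturbation applied at the start of perfusion
#' @param policy temperature policy for the perfusion (default: the
#'   configured constant temperature)
#' @return invisibly, list with the minimizer output and the summary path
#' @export
runMinGsh <- function(cfg = runConfig(), policy = NULL) {
  ctx <- .buildContext(cfg)
  st <- initialLiverState(ctx$net, volume = ctx$sim$volume)
  scsRes <- simulatePhase(ctx$net, st, ctx$scs, ctx$solver, ctx$sim)
  post <- scsRes@finalState
  if (is.null(policy)) policy <- cfg$mp$temperature
  simulate <- function(gsh) {
    start <- perturbH2O2(post, ctx$mc$perturbation)
    simulatePhase(ctx$net, start, .mpPhase(cfg, policy, .wmeWithGsh(gsh)),
                  ctx$solver, ctx$sim)
  }
  res <- minimizeGsh(simulate, ctx$mc)
  path <- .writeOutputs(cfg, "min-gsh", NULL, list(
    gsh_nmol = res$gsh, feasible = res$feasible, h2o2_M = res$h2o2,
    evaluations = res$evaluations, perturbation = ctx$mc$perturbation
  ), trace = res$trace)
  invisible(c(res, list(summary = path)))
}

#' Run the hydrogen peroxide inflammation sweep
#'
#' @param cfg configuration from [runConfig()]; `cfg$perturbations` sets the
#'   sweep, ascending, in nmol/cell
#' @param policy temperature policy for the perfusion (default: the
#'   configured constant temperature)
#' @return invisibly, list with the sweep table and the summary path
#' @export
runSweep <- function(cfg = runConfig(), policy = NULL) {
  ctx <- .buildContext(cfg)
  st <- initialLiverState(ctx$net, volume = ctx$sim$volume)
  scsRes <- simulatePhase(ctx$net, st, ctx$scs, ctx$solver, ctx$sim)
  post <- scsRes@finalState
  if (is.null(policy)) policy <- cfg$mp$temperature
  ## pin the oxphos capacity to the unperturbed run's per-step extents so
  ## that the dysfunction attenuation -- not thermodynamic side effects of
  ## the scrubbed peroxide (catalase releases oxygen) -- governs the sweep
  refSim <- ctx$sim
  ref <- simulatePhase(ctx$net, post, .mpPhase(cfg, policy), ctx$solver,
                       refSim)
  refSim$oxpCapacity <- as.numeric(ref@extents[, "R_OXP"])
  simulate <- function(p) {
    simulatePhase(ctx$net, perturbH2O2(post, p), .mpPhase(cfg, policy),
                  ctx$solver, refSim)
  }
  tab <- inflammationSweep(simulate, cfg$perturbations,
                           volume = ctx$sim$volume)
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tab, file.path(cfg$outputDir, "sweep.csv"),
                   row.names = FALSE)
  path <- .writeOutputs(cfg, "sweep", NULL, list(
    n = nrow(tab), perturbations = cfg$perturbations
  ))
  invisible(list(table = tab, summary = path))
}
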