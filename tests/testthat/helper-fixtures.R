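# Shared fixtures, built once per test run and cached.  The expensive ones
# (the post-cold-storage state, the baseline perfusion) are reused across
# test files.

.fx <- new.env(parent = emptyenv())

fxCache <- function(name, expr) {
  if (!exists(name, envir = .fx)) {
    assign(name, force(expr), envir = .fx)
  }
  get(name, envir = .fx)
}

liverNet <- function() fxCache("net", buildReducedLiverNetwork())

liverCfg <- function() fxCache("cfg", simConfig())

scsPhase <- function() protocolPhase("SCS", 6, 4, uwSolution())

mpPhase <- function(temperature = 16, medium = williamsMediumE()) {
  protocolPhase("MP", 8, temperature, medium)
}

## UW flush + 6 h SCS at 4 C on the built-in network
scsRun <- function() {
  fxCache("scs", suppressWarnings(
    simulatePhase(liverNet(), initialLiverState(liverNet()), scsPhase(),
                  cfg = liverCfg())
  ))
}

postScs <- function() scsRun()@finalState

## 8 h machine perfusion at a constant 16 C from the post-SCS state
baselineMp <- function() {
  fxCache("mp16", suppressWarnings(
    simulatePhase(liverNet(), postScs(), mpPhase(), cfg = liverCfg())
  ))
}

warmingPolicy <- function(n = 8) {
  new("TemperaturePolicy", temps = seq(16, 37, length.out = n), stepHours = 1)
}

## perfusion under the linear warming policy (in-band end-of-phase peroxide)
warmMp <- function() {
  fxCache("mpwarm", suppressWarnings(
    simulatePhase(liverNet(), postScs(), mpPhase(warmingPolicy()),
                  cfg = liverCfg())
  ))
}

mpSimulator <- function(cfg = liverCfg()) {
  function(policy) {
    suppressWarnings(
      simulatePhase(liverNet(), postScs(), mpPhase(policy), cfg = cfg)
    )
  }
}

## a tiny one-reaction isomerisation network A <-> B with a chosen
## equilibrium constant at temperature T
isoNet <- function(K, T = 298, irreversible = FALSE) {
  RT <- 8.314e-3 * T
  sp <- data.frame(
    id = c("A", "B"), name = c("A", "B"), formula = "C6H12O6", charge = 0,
    dGf0 = c(0, -RT * log(K)), dHf0 = 0, compartment = "c",
    stringsAsFactors = FALSE
  )
  metabolicNetwork(sp, list(
    new("Reaction", id = "iso", stoich = c(A = -1, B = 1), node = "n1",
        irreversible = irreversible)
  ))
}

## element/charge totals of a state (pseudo-element charge included)
elementTotals <- function(net, amounts) {
  E <- perfusionNE:::elementMatrix(speciesTable(net))
  drop(E %*% amounts[colnames(E)])
}
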