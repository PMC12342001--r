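#' @import methods
NULL

#' Reaction: one stoichiometric conversion catalysed at a network node
#'
#' Coefficients are signed (products positive, reactants negative) and may be
#' non-integer.  A transport reaction moves one molecule between two
#' compartments (coefficients -1/+1 on the two compartment copies).
#'
#' @slot id reaction identifier, unique within a network
#' @slot enzyme enzyme name and/or EC number ("" for transport steps)
#' @slot stoich named numeric vector, species id -> signed coefficient
#' @slot node identifier of the node (NLP sub-problem) that owns the reaction
#' @slot irreversible if TRUE the extent is bounded below by zero
#' @slot transport TRUE for inter-compartment transport steps
#' @exportClass Reaction
setClass("Reaction",
  representation(
    id = "character", enzyme = "character", stoich = "numeric",
    node = "character", irreversible = "logical", transport = "logical"
  ),
  prototype(
    enzyme = "", node = NA_character_,
    irreversible = FALSE, transport = FALSE
  )
)

setValidity("Reaction", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id)) {
    msg <- c(msg, "'id' must be a single non-empty string")
  }
  s <- object@stoich
  if (is.null(names(s)) || any(!nzchar(names(s)))) {
    msg <- c(msg, "'stoich' must be a named numeric vector")
  }
  if (any(s == 0) || anyDuplicated(names(s))) {
    msg <- c(msg, "'stoich' must have unique names and no zero coefficients")
  }
  if (!any(s < 0) || !any(s > 0)) {
    msg <- c(msg, "reaction needs at least one reactant and one product")
  }
  if (length(msg)) msg else TRUE
})

#' MetabolicNetwork: compartmentalised reaction network with thermodynamic data
#'
#' @slot species data.frame with columns id, name, formula, charge,
#'   dGf0 (kJ/mol at 298 K), dHf0 (kJ/mol at 298 K), compartment
#' @slot reactions data.frame with columns id, enzyme, node, irreversible,
#'   transport
#' @slot stoich numeric matrix, species x reactions, signed coefficients
#' @slot compartments character vector of compartment ids
#' @slot nodes character vector of node ids in (deterministic) sweep order
#' @exportClass MetabolicNetwork
setClass("MetabolicNetwork",
  representation(
    species = "data.frame", reactions = "data.frame",
    stoich = "matrix", compartments = "character", nodes = "character"
  )
)

#' Medium: a flush or perfusate composition
#'
#' Component rows carry both the tabulated amount (nmol/cell) and, where the
#' source table provides them, the mass concentration (g/L), molecular weight
#' and molarity (mM).  `asPrinted` flags rows whose printed molarity is not
#' reproduced by 1000 * gL / MW; such rows are stored verbatim, never
#' silently corrected.
#'
#' @slot name medium name
#' @slot components data.frame: id, conc_mM, amount_nmol, mass_gL, mw,
#'   asPrinted
#' @slot percellVolume nmol per (cell * mM) conversion factor implied by the
#'   source table
#' @exportClass Medium
setClass("Medium",
  representation(
    name = "character", components = "data.frame", percellVolume = "numeric"
  )
)

#' SystemState: per-species amounts plus temperature and clock
#'
#' @slot amounts named numeric vector of amounts, nmol/cell, over all species
#' @slot temperature absolute temperature, K
#' @slot time elapsed protocol time, h
#' @exportClass SystemState
setClass("SystemState",
  representation(amounts = "numeric", temperature = "numeric", time = "numeric"),
  prototype(temperature = 310.15, time = 0)
)

setValidity("SystemState", function(object) {
  msg <- character()
  if (is.null(names(object@amounts))) msg <- c(msg, "'amounts' must be named")
  if (any(!is.finite(object@amounts))) msg <- c(msg, "'amounts' must be finite")
  if (length(object@temperature) != 1L || object@temperature <= 0) {
    msg <- c(msg, "'temperature' must be a single positive value (K)")
  }
  if (length(msg)) msg else TRUE
})

#' TemperaturePolicy: discrete monotone warming schedule
#'
#' @slot temps per-step temperatures, degrees C, non-decreasing
#' @slot stepHours duration of one step, h
#' @exportClass TemperaturePolicy
setClass("TemperaturePolicy",
  representation(temps = "numeric", stepHours = "numeric"),
  prototype(stepHours = 1)
)

setValidity("TemperaturePolicy", function(object) {
  if (length(object@temps) < 1L) return("'temps' must be non-empty")
  if (any(diff(object@temps) < 0)) {
    return("'temps' must be non-decreasing (T1 <= T2 <= ... <= TN)")
  }
  if (object@stepHours <= 0) return("'stepHours' must be positive")
  TRUE
})

#' ProtocolPhase: one stage of the preservation protocol
#'
#' @slot kind "SCS" (static cold storage) or "MP" (machine perfusion)
#' @slot duration phase duration, h
#' @slot nSteps number of discrete time steps
#' @slot temperature constant temperature in degrees C, or a TemperaturePolicy
#' @slot medium the Medium perfusing/flushing the extracellular space
#' @slot hypoxic TRUE when no oxygen is supplied (SCS)
#' @slot leakFraction fraction of consumed O2 diverted to superoxide (MP)
#' @exportClass ProtocolPhase
setClass("ProtocolPhase",
  representation(
    kind = "character", duration = "numeric", nSteps = "integer",
    temperature = "ANY", medium = "Medium", hypoxic = "logical",
    leakFraction = "numeric"
  ),
  prototype(hypoxic = FALSE, leakFraction = 0.02)
)

setValidity("ProtocolPhase", function(object) {
  msg <- character()
  if (!object@kind %in% c("SCS", "MP")) msg <- c(msg, "'kind' must be SCS or MP")
  if (object@duration < 0) msg <- c(msg, "'duration' must be non-negative")
  if (object@nSteps < 0L) msg <- c(msg, "'nSteps' must be non-negative")
  if (object@leakFraction < 0 || object@leakFraction > 0.05) {
    msg <- c(msg, "'leakFraction' must lie in [0, 0.05]")
  }
  if (length(msg)) msg else TRUE
})

#' SimulationResult: per-step time series from one protocol phase
#'
#' @slot biomarkers data.frame, one row per step (time, temperature and the
#'   biomarker panel)
#' @slot extents numeric matrix, steps x reactions, net reaction extents
#'   (nmol/cell) including forced (injected) extents
#' @slot finalState SystemState at the end of the phase
#' @slot convergence list of per-step ConvergenceReport lists
#' @slot phase the ProtocolPhase that was simulated
#' @exportClass SimulationResult
setClass("SimulationResult",
  representation(
    biomarkers = "data.frame", extents = "matrix", finalState = "SystemState",
    convergence = "list", phase = "ProtocolPhase"
  )
)
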