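## SystemState accessors and the state-level protocol operations: medium
## flush and hydrogen-peroxide perturbation.

#' @describeIn initialLiverState amounts accessor (named, nmol/cell)
#' @param state a SystemState
#' @export
amounts <- function(state) state@amounts

#' @describeIn initialLiverState temperature accessor (K)
#' @export
temperatureK <- function(state) state@temperature

setMethod("show", "SystemState", function(object) {
  cat("SystemState:", length(object@amounts), "species, T =",
      format(object@temperature), "K, t =", format(object@time), "h\n")
  nz <- sort(object@amounts[object@amounts > 0], decreasing = TRUE)
  cat("  top amounts (nmol/cell):\n")
  print(utils::head(round(nz, 6), 8))
})

#' Flush the extracellular compartment with a medium
#'
#' Replacement semantics: every extracellular species is set to the medium's
#' tabulated amount (zero if the medium does not contain it); intracellular
#' amounts are untouched.  Flushing twice equals flushing once.
#'
#' @param state a [SystemState-class]
#' @param m a [Medium-class]
#' @param net the [MetabolicNetwork-class] defining compartments
#' @return the flushed [SystemState-class]
#' @export
applyFlush <- function(state, m, net) {
  a <- state@amounts
  extra <- net@species$id[net@species$compartment == "e"]
  comp <- mediumComponents(m)
  unknown <- setdiff(comp$id, net@species$id)
  if (length(unknown)) {
    stop("medium component(s) not in network: ", paste(unknown, collapse = ", "))
  }
  a[extra] <- 0
  a[comp$id] <- comp$amount_nmol
  new("SystemState", amounts = a, temperature = state@temperature,
      time = state@time)
}

#' Perturb mitochondrial hydrogen peroxide
#'
#' Adds `amount` nmol/cell of H2O2 to the mitochondrial pool; everything else
#' is unchanged.  Perturbations are additive.
#'
#' @param state a [SystemState-class]
#' @param amount nmol/cell to add (>= 0)
#' @return the perturbed [SystemState-class]
#' @export
perturbH2O2 <- function(state, amount) {
  if (amount < 0) stop("perturbation amount must be non-negative")
  a <- state@amounts
  a["h2o2_m"] <- a["h2o2_m"] + amount
  new("SystemState", amounts = a, temperature = state@temperature,
      time = state@time)
}
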