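## Elemental bookkeeping and the thermodynamic formulas used everywhere else:
## reaction Gibbs energy / enthalpy from formation values, the Gibbs-Helmholtz
## temperature correction, and the ideal-mixture Gibbs energy that each network
## node minimises.

## IUPAC element symbols accepted in molecular formulas.
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Se", "Br", "I", "Mo"
)

#' Physical constants used throughout
#'
#' @return list with `R_gas` (8.314 J/(mol K)) and `T0` (298 K), the
#'   reference temperature of all tabulated formation values.
#' @export
thermoConstants <- function() list(R_gas = 8.314, T0 = 298)

#' Parse a molecular formula into element counts
#'
#' @param formula molecular formula string, e.g. `"C10H18N3O6S"`.  An element
#'   symbol may be followed by an integer count (default 1); repeated symbols
#'   accumulate.
#' @return named integer vector of element counts
#' @examples
#' parseFormula("H2O2")
#' parseFormula("C10H18N3O6S")
#' @export
parseFormula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (!nzchar(formula)) stop("empty molecular formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("malformed molecular formula: '", formula, "'")
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  bad <- setdiff(sym, .ELEMENTS)
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  out <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  out <- setNames(as.integer(out), names(out))
  out[out > 0L]
}

## element x species composition matrix; charge enters as a pseudo-element so
## a single matrix expresses both mass and charge conservation.
elementMatrix <- function(species) {
  comp <- lapply(species$formula, parseFormula)
  elems <- unique(unlist(lapply(comp, names)))
  E <- matrix(0, nrow = length(elems) + 1L, ncol = nrow(species),
              dimnames = list(c(elems, "charge"), species$id))
  for (i in seq_along(comp)) E[names(comp[[i]]), i] <- comp[[i]]
  E["charge", ] <- species$charge
  E
}

#' Check element and charge balance of a reaction
#'
#' Mass conservation is the hard constraint of every node's minimisation, so
#' any network is validated reaction-by-reaction with this report.
#'
#' @param reaction a [Reaction-class] object
#' @param species species table (data.frame with id, formula, charge, ...)
#' @return list with `elements` (named residual vector, products minus
#'   reactants, per element), `charge` (charge residual) and `balanced`
#' @export
checkBalance <- function(reaction, species) {
  s <- reaction@stoich
  missing <- setdiff(names(s), species$id)
  if (length(missing)) {
    stop("species not in table: ", paste(missing, collapse = ", "))
  }
  sub <- species[match(names(s), species$id), , drop = FALSE]
  E <- elementMatrix(sub)
  res <- drop(E %*% s)
  list(
    elements = res[setdiff(names(res), "charge")],
    charge = unname(res["charge"]),
    balanced = all(abs(res) < 1e-9)
  )
}

#' Standard reaction Gibbs energy or enthalpy from formation values
#'
#' Sum over products of coefficient times formation value minus the same sum
#' over reactants (signed coefficients make this a single sum).  Linear in the
#' stoichiometry and antisymmetric under reversal.
#'
#' @param reaction a [Reaction-class]
#' @param species species table with `dGf0` and `dHf0` columns (kJ/mol, 298 K)
#' @param property `"G"` for Gibbs energy, `"H"` for enthalpy
#' @return kJ/mol at the 298 K reference temperature
#' @export
reactionDelta <- function(reaction, species, property = c("G", "H")) {
  property <- match.arg(property)
  s <- reaction@stoich
  if (!length(s)) return(0)
  idx <- match(names(s), species$id)
  if (anyNA(idx)) {
    stop("species not in table: ", paste(names(s)[is.na(idx)], collapse = ", "))
  }
  f <- if (property == "G") species$dGf0[idx] else species$dHf0[idx]
  if (any(!is.finite(f))) {
    stop("missing formation value for: ",
         paste(names(s)[!is.finite(f)], collapse = ", "))
  }
  sum(s * f)
}

#' Gibbs-Helmholtz temperature correction
#'
#' Converts a standard value at the reference temperature T0 into the
#' dimensionless standard Gibbs energy at temperature T:
#' \deqn{\Delta G^0(T)/RT = \Delta G^0(T_0)/RT_0 +
#'       (\Delta H^0(T_0)/R)\,(1/T - 1/T_0)}
#' so an exothermic reaction becomes less favourable on warming and the
#' correction vanishes at T = T0.
#'
#' @param dG0 standard Gibbs energy at T0, kJ/mol (vectorised)
#' @param dH0 standard enthalpy at T0, kJ/mol
#' @param T absolute temperature, K
#' @param T0 reference temperature, K (default 298)
#' @return dimensionless \eqn{\Delta G^0(T)/RT}
#' @export
gibbsHelmholtz <- function(dG0, dH0, T, T0 = thermoConstants()$T0) {
  if (any(T <= 0)) stop("temperature must be positive (K)")
  R <- thermoConstants()$R_gas / 1000 # kJ/(mol K)
  dG0 / (R * T0) + (dH0 / R) * (1 / T - 1 / T0)
}

## x*log(x) with the continuity value 0 at x = 0, so species may be fully
## consumed without the objective diverging.
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Dimensionless Gibbs energy of an ideal mixture
#'
#' The objective each node minimises: \eqn{G/RT = \sum_i x_i(\Delta G_i^0/RT +
#' \ln x_i)} with mole fractions computed within the node's component set and
#' ideal-solution activities equal to mole fractions.
#'
#' @param amounts non-negative species amounts (nmol/cell), at least one
#'   positive
#' @param g0 per-species dimensionless formation energies \eqn{\Delta
#'   G^0/RT} (same order as `amounts`)
#' @return dimensionless G/RT (per mole of mixture)
#' @export
mixtureGibbs <- function(amounts, g0) {
  stopifnot(length(amounts) == length(g0))
  if (any(amounts < 0)) stop("amounts must be non-negative")
  n <- sum(amounts)
  if (n <= 0) stop("all-zero amounts")
  x <- amounts / n
  sum(x * g0) + sum(xlogx(x))
}
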