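## Flush and perfusate compositions.  Both media reproduce their source tables
## verbatim, including rows whose printed molarity disagrees with g/L divided
## by molecular weight; such rows are flagged `asPrinted` and never silently
## corrected (the recomputed value is always available through
## molarityFromMassConc).

#' Molarity from mass concentration
#'
#' @param mass_conc mass concentration, g/L (>= 0)
#' @param mw molecular weight, g/mol (> 0)
#' @return molarity, mM (1000 * mass_conc / mw)
#' @examples
#' molarityFromMassConc(0.292, 146.07) # glutamine, 1.9990 mM
#' @export
molarityFromMassConc <- function(mass_conc, mw) {
  if (any(mw <= 0)) stop("molecular weight must be positive")
  if (any(mass_conc < 0)) stop("mass concentration must be non-negative")
  1000 * mass_conc / mw
}

#' Construct a Medium
#' @param name medium name
#' @param components data.frame with at least id and amount_nmol; optional
#'   conc_mM, mass_gL, mw, asPrinted
#' @param percellVolume nmol per (cell * mM) implied by the source table
#' @return a [Medium-class]
#' @export
medium <- function(name, components, percellVolume) {
  for (col in c("conc_mM", "mass_gL", "mw")) {
    if (is.null(components[[col]])) {
      components[[col]] <- rep(NA_real_, nrow(components))
    }
  }
  if (is.null(components$asPrinted)) {
    components$asPrinted <- rep(FALSE, nrow(components))
  }
  new("Medium", name = name, components = components,
      percellVolume = percellVolume)
}

#' University of Wisconsin flush solution (reduced)
#'
#' Only the constituents relevant to the model are carried: adenosine,
#' glutathione and water.  Amounts are the tabulated nmol/cell values; the
#' implied per-cell volume of this table is 1e-4 nmol/(cell mM).
#'
#' @return a [Medium-class]
#' @export
uwSolution <- function() {
  comp <- data.frame(
    id = c("gsh_e", "ado_e", "h2o_e"),
    name = c("Glutathione", "Adenosine", "Water"),
    conc_mM = c(3, 5, NA),
    amount_nmol = c(0.0003, 0.0005, 5.54),
    stringsAsFactors = FALSE
  )
  medium("UW solution", comp, percellVolume = 1e-4)
}

#' Williams Medium E perfusate (reduced)
#'
#' The ten tabulated components with mass concentration (g/L), molecular
#' weight, per-cell amount (nmol/cell) and molarity (mM) exactly as printed in
#' the source table.  Rows whose molarity column is not reproduced by
#' 1000*gL/MW (glucose, glutathione, L-serine, L-aspartate, L-cysteine,
#' bicarbonate) are flagged `asPrinted = TRUE`.  The glutamine row implies the
#' per-cell volume 0.2221/1.9990 ~= 0.1111 nmol/(cell mM), which is also the
#' simulator's default intracellular conversion volume.
#'
#' @return a [Medium-class]
#' @export
williamsMediumE <- function() {
  comp <- data.frame(
    id = c("glc_e", "gln_e", "gsh_e", "ser_e", "gly_e", "ala_e", "arg_e",
           "asp_e", "cys_e", "hco3_e"),
    name = c("Glucose", "Glutamine", "Glutathione", "L-serine", "Glycine",
             "L-alanine", "L-arginine", "L-aspartate", "L-cysteine",
             "Bicarbonate"),
    mass_gL = c(2, 0.292, 0.00005, 0.01, 0.05, 0.09, 0.05, 0.03, 0.04, 2),
    mw = c(180.06, 146.07, 307.08, 105.04, 75.03, 89.09, 174.11, 133.04,
           121.02, 60.99),
    amount_nmol = c(1.2340, 0.2221, 2.22e-5, 0.1057, 0.0740, 0.1122, 0.0319,
                    0.0250, 0.0367, 3.6432),
    conc_mM = c(11.074, 1.9990, 0.00247, 0.9520, 0.6664, 1.0102, 0.2872,
                0.2254, 0.3306, 32.6943),
    stringsAsFactors = FALSE
  )
  recomputed <- molarityFromMassConc(comp$mass_gL, comp$mw)
  comp$asPrinted <- abs(recomputed - comp$conc_mM) > 5e-5
  medium("Williams Medium E", comp, percellVolume = 0.2221 / 1.9990)
}

#' @describeIn medium component table accessor
#' @param m a Medium
#' @export
mediumComponents <- function(m) m@components

#' @describeIn medium per-cell volume accessor, nmol/(cell mM)
#' @export
percellVolume <- function(m) m@percellVolume

setMethod("show", "Medium", function(object) {
  cat("Medium:", object@name, "-", nrow(object@components), "components,",
      "per-cell volume", format(object@percellVolume), "nmol/(cell mM)\n")
  print(object@components[, c("id", "amount_nmol", "conc_mM")],
        row.names = FALSE)
})

#' Write / read a medium as TSV (column-for-column with the source tables)
#' @param m a [Medium-class]
#' @param path TSV path
#' @export
writeMediumTSV <- function(m, path) {
  tab <- m@components
  attr(tab, "name") <- NULL
  utils::write.table(
    cbind(tab, percellVolume = m@percellVolume, medium = m@name),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname writeMediumTSV
#' @return `readMediumTSV`: a [Medium-class]
#' @export
readMediumTSV <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  medium(tab$medium[1], tab[, setdiff(names(tab), c("percellVolume", "medium"))],
         percellVolume = tab$percellVolume[1])
}
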