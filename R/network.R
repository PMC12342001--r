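## MetabolicNetwork construction, accessors, validation and (de)serialisation.
## JSON is the canonical on-disk format; a two-table TSV dialect mirrors it.

#' Parse a reaction equation string
#'
#' Accepts `"2 A + B = C + 2 D"`; `=` separates reactants from products and
#' coefficients default to 1 (decimal coefficients allowed).
#'
#' @param equation equation string
#' @return named numeric stoichiometry vector (products +, reactants -)
#' @export
parseEquation <- function(equation) {
  sides <- strsplit(equation, "=", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("equation must contain exactly one '=': ", equation)
  term <- function(txt, sign) {
    parts <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    if (!length(parts)) stop("empty reaction side in: ", equation)
    out <- numeric(0)
    for (p in parts) {
      tok <- strsplit(p, "[[:space:]]+")[[1]]
      if (length(tok) == 1L) {
        coef <- 1
        id <- tok
      } else if (length(tok) == 2L && grepl("^[0-9.]+$", tok[1])) {
        coef <- as.numeric(tok[1])
        id <- tok[2]
      } else {
        stop("malformed term '", p, "' in: ", equation)
      }
      out[id] <- (if (is.na(out[id])) 0 else out[id]) + sign * coef
    }
    out
  }
  lhs <- term(sides[1], -1)
  rhs <- term(sides[2], +1)
  s <- c(lhs, rhs)
  s <- tapply(s, factor(names(s), levels = unique(names(s))), sum)
  s <- setNames(as.numeric(s), names(s))
  s[s != 0]
}

#' Render a stoichiometry vector as an equation string
#' @param stoich named signed stoichiometry vector
#' @return equation string `"a X + b Y = c Z"`
#' @export
writeEquation <- function(stoich) {
  side <- function(s) {
    paste(ifelse(s == 1, names(s), paste(format(s, trim = TRUE), names(s))),
          collapse = " + ")
  }
  lhs <- -stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  paste(side(lhs), "=", side(rhs))
}

#' Construct a metabolic network
#'
#' @param species data.frame with columns id, name, formula, charge, dGf0,
#'   dHf0, compartment
#' @param reactions list of [Reaction-class] objects (sweep order = node order
#'   of first appearance)
#' @param validate check element/charge balance of every reaction (default
#'   TRUE)
#' @return a [MetabolicNetwork-class]
#' @export
metabolicNetwork <- function(species, reactions, validate = TRUE) {
  stopifnot(is.data.frame(species), is.list(reactions))
  if (anyDuplicated(species$id)) stop("duplicate species ids")
  rid <- vapply(reactions, function(r) r@id, character(1))
  if (anyDuplicated(rid)) stop("duplicate reaction ids")
  S <- matrix(0, nrow(species), length(reactions),
              dimnames = list(species$id, rid))
  for (r in reactions) {
    miss <- setdiff(names(r@stoich), species$id)
    if (length(miss)) {
      stop("reaction ", r@id, " references unknown species: ",
           paste(miss, collapse = ", "))
    }
    S[names(r@stoich), r@id] <- r@stoich
  }
  rtab <- data.frame(
    id = rid,
    enzyme = vapply(reactions, function(r) r@enzyme, character(1)),
    node = vapply(reactions, function(r) r@node, character(1)),
    irreversible = vapply(reactions, function(r) r@irreversible, logical(1)),
    transport = vapply(reactions, function(r) r@transport, logical(1)),
    stringsAsFactors = FALSE
  )
  net <- new("MetabolicNetwork",
    species = species, reactions = rtab, stoich = S,
    compartments = unique(species$compartment),
    nodes = unique(rtab$node)
  )
  if (validate) validateNetwork(net)
  net
}

#' Validate every reaction and transport edge of a network
#'
#' Errors if any reaction fails element/charge balance, or a transport edge
#' does not connect the same molecule across two distinct compartments.
#'
#' @param net a [MetabolicNetwork-class]
#' @return invisibly TRUE
#' @export
validateNetwork <- function(net) {
  E <- elementMatrix(net@species)
  res <- E %*% net@stoich
  bad <- colnames(res)[colSums(abs(res) > 1e-9) > 0]
  if (length(bad)) {
    stop("unbalanced reaction(s): ", paste(bad, collapse = ", "))
  }
  for (id in net@reactions$id[net@reactions$transport]) {
    s <- net@stoich[, id]
    s <- s[s != 0]
    if (length(s) != 2L || sum(s) != 0) {
      stop("transport ", id, " must move one species 1:1 between compartments")
    }
    sp <- net@species[match(names(s), net@species$id), ]
    if (sp$compartment[1] == sp$compartment[2]) {
      stop("transport ", id, " must connect two distinct compartments")
    }
    if (sp$formula[1] != sp$formula[2] || sp$charge[1] != sp$charge[2]) {
      stop("transport ", id, " must carry the same molecule on both sides")
    }
  }
  invisible(TRUE)
}

#' @describeIn metabolicNetwork species table accessor
#' @param net a MetabolicNetwork
#' @export
speciesTable <- function(net) net@species

#' @describeIn metabolicNetwork reaction table accessor (with equation strings)
#' @export
reactionTable <- function(net) {
  tab <- net@reactions
  tab$equation <- vapply(tab$id, function(id) {
    s <- net@stoich[, id]
    writeEquation(s[s != 0])
  }, character(1))
  tab
}

#' @describeIn metabolicNetwork stoichiometry matrix (species x reactions)
#' @export
stoichiometry <- function(net) net@stoich

#' @describeIn metabolicNetwork node ids in sweep order
#' @export
nodeIds <- function(net) net@nodes

#' Retrieve one reaction as a Reaction object
#' @param net a [MetabolicNetwork-class]
#' @param id reaction id
#' @return a [Reaction-class]
#' @export
getReaction <- function(net, id) {
  i <- match(id, net@reactions$id)
  if (is.na(i)) stop("no such reaction: ", id)
  s <- net@stoich[, id]
  new("Reaction",
    id = id, enzyme = net@reactions$enzyme[i], stoich = s[s != 0],
    node = net@reactions$node[i],
    irreversible = net@reactions$irreversible[i],
    transport = net@reactions$transport[i]
  )
}

## species ids participating in a node's reactions (the node's component set)
nodeComponents <- function(net, node) {
  rids <- net@reactions$id[net@reactions$node == node]
  rownames(net@stoich)[rowSums(abs(net@stoich[, rids, drop = FALSE])) > 0]
}

setMethod("show", "MetabolicNetwork", function(object) {
  cat("MetabolicNetwork:", nrow(object@species), "species,",
      nrow(object@reactions), "reactions (",
      sum(object@reactions$transport), "transport ),",
      length(object@nodes), "nodes,",
      length(object@compartments), "compartments\n")
  cat("  compartments:", paste(object@compartments, collapse = ", "), "\n")
  cat("  nodes:", paste(object@nodes, collapse = ", "), "\n")
})

#' Write a network to JSON (canonical format)
#' @param net a [MetabolicNetwork-class]
#' @param path output file path
#' @export
writeMetabolicNetwork <- function(net, path) {
  obj <- list(
    species = net@species,
    reactions = reactionTable(net),
    compartments = net@compartments,
    nodes = net@nodes
  )
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a network from JSON
#' @param path file written by [writeMetabolicNetwork()]
#' @return a [MetabolicNetwork-class]
#' @export
readMetabolicNetwork <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rx <- lapply(seq_len(nrow(obj$reactions)), function(i) {
    r <- obj$reactions[i, ]
    new("Reaction",
      id = r$id, enzyme = r$enzyme, stoich = parseEquation(r$equation),
      node = r$node, irreversible = r$irreversible, transport = r$transport
    )
  })
  metabolicNetwork(as.data.frame(obj$species), rx)
}

#' Write a network as two TSV tables
#'
#' `<stem>-species.tsv` holds the species records and
#' `<stem>-reactions.tsv` the reactions with equation strings.
#'
#' @param net a [MetabolicNetwork-class]
#' @param stem path stem for the two files
#' @export
writeNetworkTSV <- function(net, stem) {
  utils::write.table(net@species, paste0(stem, "-species.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(reactionTable(net), paste0(stem, "-reactions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' Read a network from the TSV dialect
#' @param stem path stem used by [writeNetworkTSV()]
#' @return a [MetabolicNetwork-class]
#' @export
readNetworkTSV <- function(stem) {
  sp <- utils::read.table(paste0(stem, "-species.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  rt <- utils::read.table(paste0(stem, "-reactions.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  rx <- lapply(seq_len(nrow(rt)), function(i) {
    new("Reaction",
      id = rt$id[i], enzyme = rt$enzyme[i],
      stoich = parseEquation(rt$equation[i]), node = rt$node[i],
      irreversible = rt$irreversible[i], transport = rt$transport[i]
    )
  })
  metabolicNetwork(sp, rx)
}
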