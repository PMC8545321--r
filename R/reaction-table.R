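#' Read/write atom-mapped reactions in the structured table dialect
#'
#' A plain-text alternative to reaction SMILES that carries the atom-map
#' index sets directly: one row per molecule with columns `reaction_id`,
#' `role` (`reactant` or `product`), `compound_id`, `atom_indices`
#' (comma-joined map indices of the non-hydrogen atoms) and optional
#' `coa_indices` (comma-joined subset forming a Coenzyme A moiety, enabling
#' [decomposeReaction()]'s contraction). Round-trips exactly.
#'
#' @param path TSV file path
#' @return for `readReactionTable`, a list of [atomMappedReaction()]
#'   objects; for `writeReactionTable`, the path, invisibly
#' @export
readReactionTable <- function(path) {
  tb <- .readTsv(path)
  need <- c("reaction_id", "role", "compound_id", "atom_indices")
  if (!all(need %in% names(tb))) {
    stop("reaction table ", path, " lacks column(s) ",
         paste(setdiff(need, names(tb)), collapse = ", "), call. = FALSE)
  }
  if (!all(tb$role %in% c("reactant", "product"))) {
    stop("role must be 'reactant' or 'product' in ", path, call. = FALSE)
  }
  parseIdx <- function(s) {
    if (is.na(s) || !nzchar(s)) integer(0)
    else as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  }
  lapply(split(tb, factor(tb$reaction_id, levels = unique(tb$reaction_id))),
         function(sub) {
    mkSide <- function(role) {
      rows <- sub[sub$role == role, , drop = FALSE]
      side <- lapply(seq_len(nrow(rows)), function(i) {
        atoms <- parseIdx(rows$atom_indices[i])
        if ("coa_indices" %in% names(rows)) {
          coa <- parseIdx(rows$coa_indices[i])
          if (length(coa)) attr(atoms, "coa") <- coa
        }
        atoms
      })
      stats::setNames(side, rows$compound_id)
    }
    atomMappedReaction(sub$reaction_id[1], mkSide("reactant"),
                       mkSide("product"))
  })
}

#' @rdname readReactionTable
#' @param rxns list of [atomMappedReaction()] objects
#' @export
writeReactionTable <- function(rxns, path) {
  rows <- lapply(rxns, function(rxn) {
    oneSide <- function(side, role) {
      data.frame(
        reaction_id = rxn$reaction_id, role = role,
        compound_id = names(side),
        atom_indices = vapply(side, function(a) {
          paste(as.integer(a), collapse = ",")
        }, ""),
        coa_indices = vapply(side, function(a) {
          paste(as.integer(attr(a, "coa") %||% integer(0)), collapse = ",")
        }, ""),
        stringsAsFactors = FALSE)
    }
    rbind(oneSide(rxn$reactants, "reactant"),
          oneSide(rxn$products, "product"))
  })
  .writeTsv(do.call(rbind, rows), path)
}
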