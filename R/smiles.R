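# Minimal SMILES atom tokenizer: extracts, per molecule, the number of
# non-hydrogen atoms and the atom-map indices they carry. No chemistry is
# interpreted beyond atom identity — bonds, rings, charges and
# stereodescriptors are skipped — which is all the CAR needs.
.ORGANIC2 <- c("Cl", "Br")
.ORGANIC1 <- c("B", "C", "N", "O", "P", "S", "F", "I",
               "b", "c", "n", "o", "p", "s", "*")

#' Parse one atom-mapped SMILES molecule
#'
#' Counts non-hydrogen atoms and collects their atom-map indices (the
#' `:n` suffixes inside bracket atoms). Hydrogens — explicit `[H]` atoms or
#' hydrogen counts inside brackets — never enter the counts, and a map
#' index on a hydrogen is ignored.
#'
#' @param smiles one SMILES string (no `.` separators)
#' @return list with `heavy` (atom count) and `maps` (integer vector of map
#'   indices carried by heavy atoms)
#' @export
parseMappedSmiles <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  i <- 1L
  n <- length(chars)
  heavy <- 0L
  maps <- integer(0)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in SMILES: ", smiles,
                      call. = FALSE)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      elem <- sub("^[0-9]*", "", body)               # isotope prefix
      elem <- regmatches(elem, regexpr("^[A-Za-z][a-z]?|^\\*", elem))
      isH <- length(elem) == 1L && elem %in% c("H", "Hh")
      if (!isH) {
        heavy <- heavy + 1L
        m <- regmatches(body, regexpr(":[0-9]+$", body))
        if (length(m)) maps <- c(maps, as.integer(substring(m, 2)))
      }
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% .ORGANIC2) {
      heavy <- heavy + 1L
      i <- i + 2L
    } else if (ch %in% .ORGANIC1) {
      heavy <- heavy + 1L
      i <- i + 1L
    } else {
      # bonds, branches, ring closures, %nn, charges outside brackets
      i <- i + 1L
    }
  }
  list(heavy = heavy, maps = maps)
}

# Strip atom-map numbers so that structurally identical molecule strings
# coincide; used as the fallback compound id for unnamed SMILES input.
.stripMaps <- function(smiles) gsub(":[0-9]+]", "]", smiles)

#' Read atom-mapped reaction SMILES
#'
#' TSV with a header; required columns `reaction_id` and `smiles` (one
#' `reactants>>products` record with atom-map numbers, molecules separated
#' by `.`). An optional `compound_ids` column names the molecules in the
#' same layout (`id1.id2>>id3`); without it, the map-stripped SMILES string
#' itself serves as the (deterministic) compound id, so identical
#' structures written identically coincide across reactions.
#'
#' A mapped atom must carry the same index on both sides; hydrogens are
#' ignored. The result feeds [decomposeReactions()].
#'
#' @param path TSV file path
#' @return list of [atomMappedReaction()] objects
#' @export
readReactionSmiles <- function(path) {
  tb <- .readTsv(path)
  need <- c("reaction_id", "smiles")
  if (!all(need %in% names(tb))) {
    stop("reaction SMILES file ", path, " lacks column(s) ",
         paste(setdiff(need, names(tb)), collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(tb)), function(r) {
    rs <- strsplit(tb$smiles[r], ">>", fixed = TRUE)[[1]]
    if (length(rs) != 2L) {
      stop("line ", r + 1L, " of ", path,
           ": expected one 'reactants>>products' record", call. = FALSE)
    }
    sides <- lapply(rs, function(s) strsplit(s, ".", fixed = TRUE)[[1]])
    idsGiven <- "compound_ids" %in% names(tb) &&
      !is.na(tb$compound_ids[r]) && nzchar(tb$compound_ids[r])
    nameSide <- function(mols, ids) {
      parsed <- lapply(mols, parseMappedSmiles)
      if (is.null(ids)) ids <- .stripMaps(mols)
      if (length(ids) != length(mols)) {
        stop("line ", r + 1L, " of ", path,
             ": compound_ids does not match the molecule count",
             call. = FALSE)
      }
      stats::setNames(lapply(parsed, `[[`, "maps"), ids)
    }
    ids <- if (idsGiven) {
      idSides <- strsplit(tb$compound_ids[r], ">>", fixed = TRUE)[[1]]
      lapply(idSides, function(s) strsplit(s, ".", fixed = TRUE)[[1]])
    } else list(NULL, NULL)
    atomMappedReaction(tb$reaction_id[r],
                       reactants = nameSide(sides[[1]], ids[[1]]),
                       products = nameSide(sides[[2]], ids[[2]]))
  })
}
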