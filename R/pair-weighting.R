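#' Conserved Atom Ratio (CAR) of a reactant-product pair
#'
#' The CAR scores how many non-hydrogen atoms a substrate shares with a
#' product in a reaction. With `n_c` conserved atoms out of `n_r` reactant
#' and `n_p` product heavy atoms, the reactant- and product-relative ratios
#' are `CAR_r = n_c / n_r` and `CAR_p = n_c / n_p`, and
#'
#' \deqn{CAR = \frac{CAR_r + CAR_p}{2} \cdot (1 - |CAR_r - CAR_p|)}
#'
#' i.e. the mean ratio damped by a correction factor that penalises size
#' mismatch between the two molecules. The result is clamped to `[0, 1]`;
#' it equals 1 exactly when the two molecules have identical heavy-atom sets
#' (`n_c = n_r = n_p`) and 0 when no atom is conserved. Hydrogens never
#' enter the counts.
#'
#' @param n_c number of conserved (shared) non-hydrogen atoms
#' @param n_r total non-hydrogen atoms in the reactant (>= 1)
#' @param n_p total non-hydrogen atoms in the product (>= 1)
#' @return numeric vector of CAR values in `[0, 1]` (inputs are recycled)
#' @examples
#' computeCAR(5, 6, 5)   # 0.76389
#' computeCAR(7, 10, 7)  # retained moiety
#' computeCAR(3, 10, 3)  # leaving CO2-like fragment
#' @export
computeCAR <- function(n_c, n_r, n_p) {
  n <- max(length(n_c), length(n_r), length(n_p))
  n_c <- rep_len(n_c, n); n_r <- rep_len(n_r, n); n_p <- rep_len(n_p, n)
  if (any(!is.finite(n_r)) || any(!is.finite(n_p)) || any(!is.finite(n_c))) {
    stop("atom counts must be finite numbers", call. = FALSE)
  }
  if (any(n_r < 1) || any(n_p < 1)) {
    stop("n_r and n_p must be >= 1 (CAR is undefined for atom-free molecules)",
         call. = FALSE)
  }
  if (any(n_c < 0) || any(n_c > pmin(n_r, n_p))) {
    stop("n_c must satisfy 0 <= n_c <= min(n_r, n_p)", call. = FALSE)
  }
  car_r <- n_c / n_r
  car_p <- n_c / n_p
  car <- (car_r + car_p) / 2 * (1 - abs(car_r - car_p))
  pmin(pmax(car, 0), 1)
}

#' Construct an atom-mapped reaction
#'
#' A reaction is a set of reactant and product molecules, each represented
#' only by the set of atom-map indices carried by its non-hydrogen atoms
#' (hydrogens are omitted throughout). A conserved atom carries the same
#' index on both sides; each index appears at most once among the reactants
#' and at most once among the products. Stoichiometric duplicates are given
#' as separate molecule entries with disjoint index sets.
#'
#' A molecule that carries a Coenzyme A moiety may annotate the moiety's map
#' indices via `attr(atoms, "coa")`; [contractCoA()] and [decomposeReaction()]
#' use the annotation to collapse the moiety to a single pseudo-atom.
#'
#' @param reaction_id reaction identifier
#' @param reactants,products named lists of integer vectors; names are
#'   compound ids (duplicates allowed), values the molecules' atom-map index
#'   sets
#' @param direction logical; `TRUE` (default) marks the reaction
#'   bidirectional, matching the undirected graph semantics
#' @return an object of class `AtomMappedReaction` (a validated list)
#' @examples
#' # decarboxylation: 10-atom substrate -> 7-atom product + CO2 (3 atoms)
#' rxn <- atomMappedReaction("R1",
#'   reactants = list(C00001 = 1:10),
#'   products  = list(C00002 = 1:7, C00011 = 8:10))
#' decomposeReaction(rxn)
#' @export
atomMappedReaction <- function(reaction_id, reactants, products,
                               direction = TRUE) {
  stopifnot(is.character(reaction_id), length(reaction_id) == 1L)
  checkSide <- function(side, what) {
    if (!is.list(side) || is.null(names(side)) || any(names(side) == "")) {
      stop("every ", what, " molecule must be a named list entry", call. = FALSE)
    }
    idx <- unlist(lapply(side, as.integer), use.names = FALSE)
    if (anyDuplicated(idx)) {
      stop("atom-map index used more than once among ", what,
           " of reaction ", reaction_id, call. = FALSE)
    }
    for (nm in names(side)) {
      coa <- attr(side[[nm]], "coa")
      if (!is.null(coa) && !all(coa %in% side[[nm]])) {
        stop("CoA moiety annotation of ", nm,
             " refers to indices not in the molecule", call. = FALSE)
      }
    }
    side
  }
  out <- list(reaction_id = reaction_id,
              reactants = checkSide(reactants, "reactants"),
              products = checkSide(products, "products"),
              direction = isTRUE(direction))
  class(out) <- "AtomMappedReaction"
  out
}

#' @export
print.AtomMappedReaction <- function(x, ...) {
  cat(sprintf("AtomMappedReaction %s: %d reactant(s) >> %d product(s)\n",
              x$reaction_id, length(x$reactants), length(x$products)))
  invisible(x)
}

# Contract an annotated CoA moiety to one pseudo-atom. Pseudo indices are
# negative so they can never collide with real map indices; the i-th CoA
# molecule on each side receives -i, so the moiety counts as one conserved
# atom when present on both sides.
.contractSide <- function(side, carriers) {
  nxt <- 0L
  for (j in seq_along(side)) {
    if (!names(side)[j] %in% carriers) next
    coa <- attr(side[[j]], "coa")
    if (is.null(coa) || length(coa) == 0L) next
    nxt <- nxt - 1L
    rest <- setdiff(as.integer(side[[j]]), as.integer(coa))
    side[[j]] <- c(rest, nxt)
  }
  side
}

#' Collapse Coenzyme A moieties to a single pseudo-atom
#'
#' CoA is a large cofactor: two thioesters share its ~48 heavy atoms, so an
#' acyl-group swap scores a deceptively high CAR. When a CoA-carrying
#' compound occurs among the reactants *and* among the products, the moiety
#' is therefore treated as a single atom on each side before atoms are
#' counted, letting the attached acyl chemistry dominate the ratio. The
#' pseudo-atom itself counts as conserved.
#'
#' Carriers are identified by compound id (`coaCarriers`, typically from the
#' compound table's `coa_carrier` column); the moiety's map indices must be
#' annotated on the molecule (see [atomMappedReaction()]). If carriers occur
#' on one side only, nothing is contracted and a warning is raised —
#' contraction is only meaningful when the moiety is shared.
#'
#' @param rxn an [atomMappedReaction()]
#' @param coaCarriers character vector of CoA-carrying compound ids
#' @return the reaction with moieties collapsed (or unchanged)
#' @export
contractCoA <- function(rxn, coaCarriers) {
  stopifnot(inherits(rxn, "AtomMappedReaction"))
  hasAnno <- function(side) {
    any(vapply(seq_along(side), function(j) {
      names(side)[j] %in% coaCarriers &&
        length(attr(side[[j]], "coa")) > 0L
    }, logical(1)))
  }
  onR <- hasAnno(rxn$reactants)
  onP <- hasAnno(rxn$products)
  if (!onR && !onP) return(rxn)
  if (xor(onR, onP)) {
    warning("reaction ", rxn$reaction_id,
            ": CoA carrier on one side only; moiety left uncontracted",
            call. = FALSE)
    return(rxn)
  }
  rxn$reactants <- .contractSide(rxn$reactants, coaCarriers)
  rxn$products <- .contractSide(rxn$products, coaCarriers)
  rxn
}

#' Decompose an atom-mapped reaction into weighted reactant-product pairs
#'
#' Splits a reaction into all reactant x product combinations and computes,
#' for each pair, the conserved-atom count (`n_c`, the intersection of the
#' two map-index sets), the heavy-atom totals `n_r` and `n_p`, and the CAR
#' (see [computeCAR()]). Pairs with `n_c = 0` are retained — filtering
#' happens at graph build. Degenerate cases follow fixed rules:
#' \itemize{
#'   \item a molecule with zero heavy atoms yields no pairs (CAR undefined;
#'     warning);
#'   \item a compound occurring on both sides yields a self-pair, which is
#'     dropped with a warning (self-edges cannot join loop-less paths);
#'   \item stoichiometric duplicates produce several candidate pairs per
#'     `(substrate, product)` id combination; the one with maximal `n_c` is
#'     kept.
#' }
#'
#' CoA contraction is applied per pair: when substrate and product are both
#' flagged carriers with annotated moieties, the moiety collapses to one
#' conserved pseudo-atom on each side before counting; pairs with CoA on
#' one side only (or none) keep their ordinary atom counts.
#'
#' @param rxn an [atomMappedReaction()]
#' @param coaCarriers compound ids whose annotated CoA moiety should be
#'   contracted (see [contractCoA()]); empty by default
#' @param contract logical; apply per-pair CoA contraction
#' @return data.frame with columns `reaction_id`, `substrate_id`,
#'   `product_id`, `n_c`, `n_r`, `n_p`, `car_r`, `car_p`, `car`
#' @export
decomposeReaction <- function(rxn, coaCarriers = character(),
                              contract = TRUE) {
  stopifnot(inherits(rxn, "AtomMappedReaction"))
  coaOf <- function(side, j) {
    if (!contract || !names(side)[j] %in% coaCarriers) return(integer(0))
    as.integer(attr(side[[j]], "coa") %||% integer(0))
  }
  rows <- list()
  for (i in seq_along(rxn$reactants)) {
    rid <- names(rxn$reactants)[i]
    ratoms <- as.integer(rxn$reactants[[i]])
    rcoa <- coaOf(rxn$reactants, i)
    for (j in seq_along(rxn$products)) {
      pid <- names(rxn$products)[j]
      patoms <- as.integer(rxn$products[[j]])
      pcoa <- coaOf(rxn$products, j)
      if (length(ratoms) == 0L || length(patoms) == 0L) {
        warning("reaction ", rxn$reaction_id, ": pair ", rid, " -> ", pid,
                " involves a molecule with no heavy atoms; pair rejected",
                call. = FALSE)
        next
      }
      if (rid == pid) {
        warning("reaction ", rxn$reaction_id, ": self-pair for compound ",
                rid, " dropped", call. = FALSE)
        next
      }
      if (length(rcoa) && length(pcoa)) {
        # both sides carry an annotated CoA moiety: one shared pseudo-atom
        ra <- c(setdiff(ratoms, rcoa), -1L)
        pa <- c(setdiff(patoms, pcoa), -1L)
      } else {
        ra <- ratoms
        pa <- patoms
      }
      n_c <- length(intersect(ra, pa))
      rows[[length(rows) + 1L]] <- data.frame(
        reaction_id = rxn$reaction_id, substrate_id = rid, product_id = pid,
        n_c = n_c, n_r = length(ra), n_p = length(pa),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(reaction_id = character(), substrate_id = character(),
                      product_id = character(), n_c = integer(),
                      n_r = integer(), n_p = integer(), car_r = numeric(),
                      car_p = numeric(), car = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  # stoichiometric duplicates: keep the maximal mapping per id combination
  key <- paste(out$substrate_id, out$product_id, sep = "\r")
  out <- out[order(key, -out$n_c), , drop = FALSE]
  out <- out[!duplicated(paste(out$substrate_id, out$product_id, sep = "\r")), ,
             drop = FALSE]
  out$car_r <- out$n_c / out$n_r
  out$car_p <- out$n_c / out$n_p
  out$car <- computeCAR(out$n_c, out$n_r, out$n_p)
  rownames(out) <- NULL
  out[order(out$substrate_id, out$product_id), , drop = FALSE]
}

#' Decompose a list of atom-mapped reactions
#'
#' @param rxns list of [atomMappedReaction()] objects
#' @inheritParams decomposeReaction
#' @return row-bound pair table (see [decomposeReaction()])
#' @export
decomposeReactions <- function(rxns, coaCarriers = character(),
                               contract = TRUE) {
  tabs <- lapply(rxns, decomposeReaction, coaCarriers = coaCarriers,
                 contract = contract)
  out <- do.call(rbind, tabs)
  if (is.null(out)) out <- decomposeReaction(
    atomMappedReaction("empty", stats::setNames(list(1L), "x"),
                       stats::setNames(list(1L), "y")))[0, ]
  rownames(out) <- NULL
  out
}
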