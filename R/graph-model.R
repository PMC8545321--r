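#' Merge stereoisomers on the InChIKey connectivity block
#'
#' Compounds whose InChIKeys share the first fourteen characters (the
#' connectivity block, which ignores stereochemistry, charge and isotopes)
#' are collapsed into one graph node, so D-/L- stereoisomers of the same
#' skeleton become a single metabolite. Compounds without a key — or with a
#' malformed one (not 27 characters with dashes at positions 15 and 26;
#' treated as absent, with a warning) — map to themselves. The node id of a
#' merged group is its lexicographically smallest member id.
#'
#' @param compounds compound table: data.frame with column `compound_id`
#'   and optionally `inchikey`
#' @return named character vector mapping each `compound_id` to its node id
#' @export
mergeStereoisomers <- function(compounds) {
  stopifnot(is.data.frame(compounds), "compound_id" %in% names(compounds))
  ids <- as.character(compounds$compound_id)
  if (anyDuplicated(ids)) {
    stop("compound table contains duplicated compound_id values", call. = FALSE)
  }
  keys <- if ("inchikey" %in% names(compounds)) {
    as.character(compounds$inchikey)
  } else rep(NA_character_, length(ids))
  keys[!is.na(keys) & keys == ""] <- NA_character_
  ok <- !is.na(keys)
  valid <- ok & nchar(keys) == 27L &
    substr(keys, 15, 15) == "-" & substr(keys, 26, 26) == "-" &
    !grepl("-", paste0(substr(keys, 1, 14), substr(keys, 16, 25),
                       substr(keys, 27, 27)), fixed = TRUE)
  if (any(ok & !valid)) {
    warning("malformed InChIKey for ",
            paste(ids[ok & !valid], collapse = ", "),
            "; treated as absent", call. = FALSE)
  }
  block <- ifelse(valid, substr(keys, 1, 14), paste0("\rself\r", ids))
  rep_id <- vapply(split(ids, block), function(g) sort(g)[1], "")
  stats::setNames(rep_id[block], ids)
}

#' CAR-to-distance transforms
#'
#' Converts an edge's CAR into a graph distance so that atom-conserving
#' pairs lie close together. Three transforms are available, all equal to 1
#' at CAR = 1 and strictly decreasing in CAR:
#' \describe{
#'   \item{`default`}{\eqn{d = 1 / CAR}}
#'   \item{`sqrt`}{\eqn{d = \sqrt{1 / CAR}} — softens the atom-conservation
#'     penalty, favouring short routes}
#'   \item{`exp`}{\eqn{d = e^{1/CAR} / e} — sharpens it, favouring
#'     atom-conserving routes even when long}
#' }
#'
#' @param car numeric vector of CARs in `(0, 1]`
#' @param transform `"default"`, `"sqrt"` or `"exp"`
#' @return numeric vector of distances (all >= 1)
#' @examples
#' transformDistance(0.5, "default")  # 2
#' transformDistance(0.5, "sqrt")     # sqrt(2)
#' transformDistance(0.5, "exp")      # e
#' @export
transformDistance <- function(car, transform = c("default", "sqrt", "exp")) {
  transform <- match.arg(transform)
  if (any(!is.finite(car)) || any(car <= 0) || any(car > 1)) {
    stop("car must lie in (0, 1]; zero-CAR pairs must not become edges",
         call. = FALSE)
  }
  switch(transform,
         default = 1 / car,
         sqrt = sqrt(1 / car),
         exp = exp(1 / car - 1))
}

#' Build the CAR-weighted pair graph
#'
#' Assembles an undirected graph from a table of weighted reactant-product
#' pairs: pairs with `car = 0` are dropped (no atoms conserved, warning),
#' compound ids are mapped through [mergeStereoisomers()], pairs collapsing
#' onto a single node become self-edges and are dropped (warning), parallel
#' pairs between the same two nodes collapse into one edge carrying the
#' maximum CAR and the union of supporting reaction ids, and excluded
#' compounds (free CoA by default) are removed together with their incident
#' edges. Edge distances follow the chosen transform.
#'
#' @param pairs pair table with columns `substrate_id`, `product_id`, `car`
#'   and optionally `reaction_id` (see [decomposeReaction()] /
#'   [readPairTable()])
#' @param compounds optional compound table (see [mergeStereoisomers()]);
#'   compounds absent from it become bare nodes
#' @param transform CAR-to-distance transform, see [transformDistance()]
#' @param exclusions compound ids to remove from the graph; defaults to free
#'   Coenzyme A (`"C00010"`)
#' @return a [PairGraph-class]
#' @export
buildPairGraph <- function(pairs, compounds = NULL,
                           transform = c("default", "sqrt", "exp"),
                           exclusions = "C00010") {
  transform <- match.arg(transform)
  stopifnot(is.data.frame(pairs),
            all(c("substrate_id", "product_id", "car") %in% names(pairs)))
  if (is.null(pairs$reaction_id)) {
    pairs$reaction_id <- rep(NA_character_, nrow(pairs))
  }
  if (nrow(pairs) == 0L) {
    warning("empty pair list: building an empty graph", call. = FALSE)
  }
  ids <- unique(c(pairs$substrate_id, pairs$product_id))
  map <- if (!is.null(compounds)) mergeStereoisomers(compounds)
         else stats::setNames(character(0), character(0))
  bare <- setdiff(ids, names(map))
  map <- c(map, stats::setNames(bare, bare))

  if (any(pairs$car < 0 | pairs$car > 1)) {
    stop("pair CARs must lie in [0, 1]", call. = FALSE)
  }
  drop0 <- pairs$car == 0
  if (any(drop0)) {
    warning(sum(drop0), " zero-CAR pair(s) dropped", call. = FALSE)
  }
  pairs <- pairs[!drop0, , drop = FALSE]

  a <- unname(map[pairs$substrate_id])
  b <- unname(map[pairs$product_id])
  self <- a == b
  if (any(self)) {
    warning(sum(self), " pair(s) collapsed onto one node (self-edge) dropped",
            call. = FALSE)
  }
  pairs <- pairs[!self, , drop = FALSE]
  a <- a[!self]; b <- b[!self]

  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  ord <- order(key, -pairs$car)
  edges <- data.frame(lo = lo[ord], hi = hi[ord], car = pairs$car[ord],
                      rid = pairs$reaction_id[ord], key = key[ord],
                      stringsAsFactors = FALSE)
  rids <- vapply(split(edges$rid, edges$key), function(r) {
    paste(sort(unique(stats::na.omit(r))), collapse = ";")
  }, "")
  first <- !duplicated(edges$key)
  coll <- edges[first, , drop = FALSE]
  coll$reactions <- unname(rids[coll$key])
  coll <- coll[order(coll$lo, coll$hi), , drop = FALSE]

  nodes <- sort(unique(unname(map)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(map)) {
    members <- vapply(split(names(map), unname(map)), function(m) {
      paste(sort(m), collapse = ";")
    }, "")
    igraph::V(g)$members <- unname(members[nodes])
  }
  if (nrow(coll) > 0) {
    g <- igraph::add_edges(g, rbind(coll$lo, coll$hi),
                           car = coll$car,
                           distance = transformDistance(coll$car, transform),
                           reactions = coll$reactions)
  }

  excl <- unique(unname(map[intersect(exclusions, names(map))]))
  excl <- intersect(excl, nodes)
  if (length(excl)) g <- igraph::delete_vertices(g, excl)

  methods::new("PairGraph", graph = g, transform = transform,
               nodeMap = map, excludedNodes = as.character(exclusions),
               carThreshold = NA_real_)
}

#' Unweighted view of a pair graph above a CAR threshold
#'
#' Keeps only edges whose CAR is strictly greater than `carThreshold` and
#' sets every distance to 1, yielding the undirected, unweighted network on
#' which component structure, diameter and two-sided breadth-first searches
#' are defined. Nodes are kept even if they lose all edges.
#'
#' @param graph a [PairGraph-class]
#' @param carThreshold CAR threshold in `[0, 1]`; edges with
#'   `car > carThreshold` survive
#' @return a [PairGraph-class] with `transform = "unweighted"`
#' @export
thresholdSubgraph <- function(graph, carThreshold) {
  stopifnot(methods::is(graph, "PairGraph"),
            is.numeric(carThreshold), length(carThreshold) == 1L,
            carThreshold >= 0, carThreshold <= 1)
  g <- graph@graph
  if (igraph::ecount(g) > 0) {
    drop <- igraph::E(g)[igraph::E(g)$car <= carThreshold]
    g <- igraph::delete_edges(g, drop)
    if (igraph::ecount(g) > 0) igraph::E(g)$distance <- 1
  }
  methods::new("PairGraph", graph = g, transform = "unweighted",
               nodeMap = graph@nodeMap, excludedNodes = graph@excludedNodes,
               carThreshold = carThreshold)
}
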