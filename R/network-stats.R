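#' Graph-theoretical diagnostics of a pair graph
#'
#' Computes standard statistics of the weighted pair graph and of its
#' unweighted view above a CAR threshold: node/edge counts (undirected
#' edges and the 2-per-edge directed-arc convention), the number of
#' connected components, the size of the biggest component in absolute
#' terms and as a percentage of the thresholded graph, and the biggest
#' component's diameter — the longest shortest path in hops, i.e. the
#' largest number of biotransformation steps separating two connected
#' metabolites. The diameter is computed exactly by all-pairs
#' breadth-first search.
#'
#' Component-size ties break by edge count, then by smallest node id.
#'
#' @param graph a [PairGraph-class] (weighted, or already thresholded)
#' @param carThreshold CAR threshold defining the unweighted view
#' @return a [NetworkReport-class]
#' @export
analyzeNetwork <- function(graph, carThreshold = 0.34) {
  stopifnot(methods::is(graph, "PairGraph"))
  nNodes <- igraph::vcount(graph@graph)
  nEdges <- igraph::ecount(graph@graph)
  if (nNodes == 0L) {
    warning("empty graph: all statistics are zero", call. = FALSE)
    return(methods::new("NetworkReport",
      nNodes = 0L, nEdges = 0L, nArcs = 0L,
      carThreshold = carThreshold, nNodesThresholded = 0L,
      nEdgesThresholded = 0L, nComponents = 0L,
      biggestComponentNodes = 0L, biggestComponentEdges = 0L,
      nodeFraction = 0, edgeFraction = 0, diameter = 0L))
  }
  tg <- thresholdSubgraph(graph, carThreshold)@graph
  comp <- igraph::components(tg)
  compEdges <- integer(comp$no)
  if (igraph::ecount(tg) > 0) {
    ends <- igraph::ends(tg, igraph::E(tg), names = FALSE)
    tab <- table(comp$membership[ends[, 1]])
    compEdges[as.integer(names(tab))] <- as.integer(tab)
  }
  firstNode <- vapply(seq_len(comp$no), function(i) {
    min(igraph::V(tg)$name[comp$membership == i])
  }, "")
  best <- order(-comp$csize, -compEdges, firstNode)[1]
  bcNodes <- igraph::V(tg)[comp$membership == best]
  bc <- igraph::induced_subgraph(tg, bcNodes)
  diam <- if (igraph::vcount(bc) > 1L) {
    max(igraph::distances(bc, weights = NA))
  } else 0
  nT <- as.integer(igraph::vcount(tg))
  eT <- as.integer(igraph::ecount(tg))
  methods::new("NetworkReport",
    nNodes = as.integer(nNodes), nEdges = as.integer(nEdges),
    nArcs = 2L * as.integer(nEdges),
    carThreshold = carThreshold,
    nNodesThresholded = nT, nEdgesThresholded = eT,
    nComponents = as.integer(comp$no),
    biggestComponentNodes = as.integer(comp$csize[best]),
    biggestComponentEdges = compEdges[best],
    nodeFraction = if (nT > 0) 100 * comp$csize[best] / nT else 0,
    edgeFraction = if (eT > 0) 100 * compEdges[best] / eT else 0,
    diameter = as.integer(diam))
}

#' Warn when source and target cannot be connected
#'
#' A pathway search between two compounds lying in different components of
#' the thresholded network cannot yield any well-conserving pathway; this
#' check emits a structured warning (class `carpath_disconnected`) in that
#' case so callers can decide whether to search the full weighted graph
#' anyway.
#'
#' @param graph a [PairGraph-class]
#' @param source,target compound or node ids
#' @param carThreshold CAR threshold of the view on which connectivity is
#'   judged
#' @return `TRUE` (invisibly) when connected, `FALSE` (after warning) when
#'   not
#' @export
connectivityCheck <- function(graph, source, target, carThreshold = 0.34) {
  stopifnot(methods::is(graph, "PairGraph"))
  src <- .resolveNode(graph, source, "source")
  tgt <- .resolveNode(graph, target, "target")
  tg <- thresholdSubgraph(graph, carThreshold)@graph
  comp <- igraph::components(tg)
  if (comp$membership[src] != comp$membership[tgt]) {
    warning(warningCondition(
      sprintf(paste0("'%s' and '%s' lie in different components of the ",
                     "CAR > %.3g network; no atom-conserving pathway ",
                     "connects them"), src, tgt, carThreshold),
      class = "carpath_disconnected"))
    return(invisible(FALSE))
  }
  invisible(TRUE)
}
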