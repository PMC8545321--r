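#' @import methods
NULL

setOldClass("igraph")

#' PairGraph: a CAR-weighted graph of reactant-product pairs
#'
#' Compound nodes (stereoisomers merged on the InChIKey connectivity block)
#' connected by undirected edges, one per reactant-product pair, each carrying
#' the pair's Conserved Atom Ratio (CAR), the distance derived from it under
#' the active transform, and the identifiers of the supporting reactions.
#'
#' @slot graph the backing \pkg{igraph} object; vertex attribute `name` holds
#'   node ids, `members` the merged compound ids (semicolon-joined); edge
#'   attributes `car`, `distance`, `reactions`.
#' @slot transform one of `"default"` (1/CAR), `"sqrt"` (sqrt(1/CAR)),
#'   `"exp"` (exp(1/CAR - 1)), or `"unweighted"` for thresholded views.
#' @slot nodeMap named character vector mapping every input compound id to
#'   its node id.
#' @slot excludedNodes compound/node ids removed at build time (free CoA by
#'   default).
#' @slot carThreshold CAR threshold of an unweighted view (`NA` for the full
#'   weighted graph).
#'
#' @seealso [buildPairGraph()], [thresholdSubgraph()], [yenKShortest()]
#' @export
setClass("PairGraph",
  representation(
    graph = "igraph",
    transform = "character",
    nodeMap = "character",
    excludedNodes = "character",
    carThreshold = "numeric"
  )
)

setValidity("PairGraph", function(object) {
  msg <- character()
  g <- object@graph
  if (!object@transform %in% c("default", "sqrt", "exp", "unweighted")) {
    msg <- c(msg, "transform must be one of default, sqrt, exp, unweighted")
  }
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (igraph::any_loop(g)) msg <- c(msg, "graph must not contain self-edges")
  if (igraph::any_multiple(g)) msg <- c(msg, "graph must not contain parallel edges")
  if (igraph::ecount(g) > 0) {
    car <- igraph::E(g)$car
    d <- igraph::E(g)$distance
    if (is.null(car) || any(is.na(car)) || any(car <= 0) || any(car > 1)) {
      msg <- c(msg, "edge CARs must lie in (0, 1]")
    }
    if (is.null(d) || any(is.na(d)) || any(d < 1 - 1e-12)) {
      msg <- c(msg, "edge distances must be >= 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' PathwaySet: ranked pathways returned by a search
#'
#' An ordered collection of loop-less pathways between one source and one
#' target node, ranked by pathway score (the sum of per-step CAR-derived
#' distances; lower is better).
#'
#' @slot pathways list of pathways; each is a list with elements `nodes`
#'   (character vector, source first), `reactions` (list of character vectors,
#'   one set per step), `stepCars`, `stepDistances`, `score`, `averageCar`,
#'   `length`.
#' @slot source,target resolved node ids of the query endpoints.
#' @slot transform distance transform the scores were computed under.
#' @slot k maximum number of pathways requested.
#'
#' @seealso [yenKShortest()], [twoSidedUnweightedSearch()],
#'   [writePathwayTable()]
#' @export
setClass("PathwaySet",
  representation(
    pathways = "list",
    source = "character",
    target = "character",
    transform = "character",
    k = "numeric"
  )
)

setValidity("PathwaySet", function(object) {
  msg <- character()
  for (p in object@pathways) {
    if (anyDuplicated(p$nodes)) msg <- c(msg, "pathways must be loop-less")
    if (p$length != length(p$nodes) - 1L || p$length != length(p$reactions)) {
      msg <- c(msg, "pathway length must equal steps and reaction sets")
    }
  }
  sc <- vapply(object@pathways, `[[`, numeric(1), "score")
  if (is.unsorted(sc + 1e-9 * seq_along(sc) * 0)) {
    if (any(diff(sc) < -1e-9)) msg <- c(msg, "scores must be non-decreasing with rank")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' RocTable: ROC analysis of CAR as a main-pair classifier
#'
#' Per-cutoff confusion statistics for predicting the "main" biotransformation
#' pair of a reaction from its CAR, plus the area under the ROC curve and the
#' Youden-optimal cutoff.
#'
#' @slot table data.frame with columns `cutoff`, `tp`, `fp`, `sensitivity`,
#'   `specificity`, `youden`, cutoffs strictly increasing.
#' @slot auc area under the ROC curve (trapezoidal).
#' @slot optimalCutoff smallest cutoff maximising Youden's index
#'   (sensitivity + specificity - 1).
#' @slot youdenMax the maximal Youden's index.
#' @slot nPositive,nNegative class sizes of the labelled input.
#'
#' @seealso [rocAnalysis()]
#' @export
setClass("RocTable",
  representation(
    table = "data.frame",
    auc = "numeric",
    optimalCutoff = "numeric",
    youdenMax = "numeric",
    nPositive = "integer",
    nNegative = "integer"
  )
)

setValidity("RocTable", function(object) {
  msg <- character()
  tb <- object@table
  need <- c("cutoff", "tp", "fp", "sensitivity", "specificity", "youden")
  if (!all(need %in% names(tb))) {
    msg <- c(msg, paste("table must have columns", paste(need, collapse = ", ")))
  } else {
    if (is.unsorted(tb$cutoff, strictly = TRUE)) {
      msg <- c(msg, "cutoffs must be strictly increasing")
    }
    if (any(tb$sensitivity < 0 | tb$sensitivity > 1) ||
        any(tb$specificity < 0 | tb$specificity > 1)) {
      msg <- c(msg, "sensitivity and specificity must lie in [0, 1]")
    }
    if (max(abs(tb$youden - (tb$sensitivity + tb$specificity - 1))) > 1e-9) {
      msg <- c(msg, "youden must equal sensitivity + specificity - 1")
    }
  }
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' NetworkReport: diagnostics of a thresholded pair graph
#'
#' Standard statistics of the weighted pair graph and of its unweighted view
#' obtained by keeping only edges with CAR above a threshold: component
#' structure, biggest-component size (absolute and as a fraction of the
#' thresholded graph), and the hop-metric diameter of the biggest component.
#'
#' @slot nNodes,nEdges node and undirected edge counts of the full weighted
#'   graph; `nArcs` is the directed-arc convention (2 x edges).
#' @slot carThreshold CAR threshold defining the unweighted view.
#' @slot nNodesThresholded,nEdgesThresholded counts after thresholding
#'   (isolated nodes are kept).
#' @slot nComponents number of connected components of the thresholded view.
#' @slot biggestComponentNodes,biggestComponentEdges size of the biggest
#'   component (most nodes; ties broken by edge count, then by smallest node
#'   id).
#' @slot nodeFraction,edgeFraction biggest-component share of the thresholded
#'   graph, in percent.
#' @slot diameter longest shortest path (hops) within the biggest component.
#'
#' @seealso [analyzeNetwork()], [connectivityCheck()]
#' @export
setClass("NetworkReport",
  representation(
    nNodes = "integer",
    nEdges = "integer",
    nArcs = "integer",
    carThreshold = "numeric",
    nNodesThresholded = "integer",
    nEdgesThresholded = "integer",
    nComponents = "integer",
    biggestComponentNodes = "integer",
    biggestComponentEdges = "integer",
    nodeFraction = "numeric",
    edgeFraction = "numeric",
    diameter = "integer"
  )
)

setValidity("NetworkReport", function(object) {
  msg <- character()
  if (object@nodeFraction < 0 || object@nodeFraction > 100 ||
      object@edgeFraction < 0 || object@edgeFraction > 100) {
    msg <- c(msg, "fractions must lie in [0, 100]")
  }
  if (object@biggestComponentNodes > 0 &&
      object@diameter > object@biggestComponentNodes - 1L) {
    msg <- c(msg, "diameter cannot exceed biggest component size - 1")
  }
  if (length(msg)) msg else TRUE
})
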