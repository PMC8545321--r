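#' @rdname PairGraph-class
setMethod("numNodes", "PairGraph", function(object) igraph::vcount(object@graph))

#' @rdname PairGraph-class
setMethod("numEdges", "PairGraph", function(object) igraph::ecount(object@graph))

#' @rdname PairGraph-class
setMethod("nodeIds", "PairGraph", function(object) {
  sort(igraph::V(object@graph)$name)
})

#' @rdname PairGraph-class
setMethod("graphTransform", "PairGraph", function(object) object@transform)

#' @rdname PairGraph-class
setMethod("nodeMap", "PairGraph", function(object) object@nodeMap)

#' @describeIn PairGraph-class edge list as a data.frame with columns
#'   `node_a`, `node_b`, `car`, `distance`, `reaction_ids`
#'   (semicolon-joined), in deterministic row order.
setMethod("edgeTable", "PairGraph", function(object) {
  g <- object@graph
  if (igraph::ecount(g) == 0) {
    return(data.frame(node_a = character(), node_b = character(),
                      car = numeric(), distance = numeric(),
                      reaction_ids = character(), stringsAsFactors = FALSE))
  }
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  a <- pmin(ends[, 1], ends[, 2])
  b <- pmax(ends[, 1], ends[, 2])
  tb <- data.frame(node_a = a, node_b = b,
                   car = igraph::E(g)$car,
                   distance = igraph::E(g)$distance,
                   reaction_ids = igraph::E(g)$reactions,
                   stringsAsFactors = FALSE)
  tb <- tb[order(tb$node_a, tb$node_b), , drop = FALSE]
  rownames(tb) <- NULL
  tb
})

setMethod("show", "PairGraph", function(object) {
  cat(sprintf("PairGraph: %d nodes, %d edges (transform = %s)\n",
              numNodes(object), numEdges(object), object@transform))
  if (!is.na(object@carThreshold)) {
    cat(sprintf("  unweighted view, CAR threshold %.3g\n", object@carThreshold))
  }
  if (length(object@excludedNodes)) {
    cat("  excluded:", paste(object@excludedNodes, collapse = ", "), "\n")
  }
  if (numEdges(object) > 0) {
    cat(sprintf("  CAR range: [%.3f, %.3f]\n",
                min(igraph::E(object@graph)$car),
                max(igraph::E(object@graph)$car)))
  }
  invisible(NULL)
})

#' @rdname PathwaySet-class
setMethod("pathwayScores", "PathwaySet", function(object) {
  vapply(object@pathways, `[[`, numeric(1), "score")
})

#' @rdname PathwaySet-class
setMethod("averageCars", "PathwaySet", function(object) {
  vapply(object@pathways, `[[`, numeric(1), "averageCar")
})

#' @describeIn PathwaySet-class node sequences, as a list of character
#'   vectors ordered by rank.
setMethod("pathwayNodes", "PathwaySet", function(object) {
  lapply(object@pathways, `[[`, "nodes")
})

#' @describeIn PathwaySet-class number of pathways found.
#' @export
setMethod("length", "PathwaySet", function(x) length(x@pathways))

#' Flatten a PathwaySet to a ranked result table
#'
#' One row per pathway with columns `index`, `pathway_length`,
#' `intermediates` (`->`-joined node ids), `reaction_ids` (`->`-joined
#' representatives, the smallest id per step), `pathway_score` and
#' `average_car`, mirroring the layout of ranked search output tables.
#'
#' @param x a [PathwaySet-class]
#' @param row.names,optional,... ignored (S3 compatibility)
#' @return a data.frame ordered by rank
#' @export
as.data.frame.PathwaySet <- function(x, row.names = NULL, optional = FALSE, ...) {
  ps <- x@pathways
  data.frame(
    index = seq_along(ps),
    pathway_length = vapply(ps, `[[`, numeric(1), "length"),
    intermediates = vapply(ps, function(p) paste(p$nodes, collapse = "->"), ""),
    reaction_ids = vapply(ps, function(p) {
      paste(vapply(p$reactions, function(r) sort(r)[1], ""), collapse = "->")
    }, ""),
    pathway_score = vapply(ps, `[[`, numeric(1), "score"),
    average_car = vapply(ps, `[[`, numeric(1), "averageCar"),
    stringsAsFactors = FALSE
  )
}

setMethod("show", "PathwaySet", function(object) {
  cat(sprintf("PathwaySet: %d pathway(s) %s -> %s (transform = %s, k = %d)\n",
              length(object), object@source, object@target,
              object@transform, as.integer(object@k)))
  if (length(object) > 0) {
    tb <- as.data.frame(object)
    tb$pathway_score <- formatRound2(tb$pathway_score)
    tb$average_car <- formatRound2(tb$average_car)
    print(utils::head(tb, 10), row.names = FALSE)
    if (nrow(tb) > 10) cat("  ...", nrow(tb) - 10, "more\n")
  }
  invisible(NULL)
})

#' @rdname RocTable-class
setMethod("aucValue", "RocTable", function(object) object@auc)

#' @rdname RocTable-class
setMethod("optimalCutoff", "RocTable", function(object) object@optimalCutoff)

#' @rdname RocTable-class
setMethod("youdenMax", "RocTable", function(object) object@youdenMax)

#' @describeIn RocTable-class the per-cutoff table as a data.frame.
setMethod("rocPoints", "RocTable", function(object) object@table)

setMethod("show", "RocTable", function(object) {
  cat(sprintf("RocTable: %d cutoffs, %d positives / %d negatives\n",
              nrow(object@table), object@nPositive, object@nNegative))
  cat(sprintf("  AUC = %.4f; Youden max = %.4f at cutoff %.2f\n",
              object@auc, object@youdenMax, object@optimalCutoff))
  invisible(NULL)
})

#' Plot the ROC curve of a RocTable
#'
#' @param x a [RocTable-class]
#' @param y ignored
#' @param ... passed on to [plot()]
#' @export
setMethod("plot", signature(x = "RocTable", y = "missing"), function(x, y, ...) {
  tb <- x@table
  fpr <- c(0, rev(1 - tb$specificity), 1)
  tpr <- c(0, rev(tb$sensitivity), 1)
  graphics::plot(fpr, tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x@auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(NULL)
})

setMethod("show", "NetworkReport", function(object) {
  cat("NetworkReport\n")
  cat(sprintf("  weighted graph: %d nodes, %d edges (%d directed arcs)\n",
              object@nNodes, object@nEdges, object@nArcs))
  cat(sprintf("  unweighted view (CAR > %.3g): %d nodes, %d edges\n",
              object@carThreshold, object@nNodesThresholded,
              object@nEdgesThresholded))
  cat(sprintf("  components: %d; biggest: %d nodes (%.1f%%), %d edges (%.1f%%)\n",
              object@nComponents, object@biggestComponentNodes,
              object@nodeFraction, object@biggestComponentEdges,
              object@edgeFraction))
  cat(sprintf("  diameter of biggest component: %d\n", object@diameter))
  invisible(NULL)
})

#' Convert a NetworkReport to a flat named list
#'
#' @param x a [NetworkReport-class]
#' @param ... ignored
#' @return named list of the report fields, suitable for JSON output
#' @export
as.list.NetworkReport <- function(x, ...) {
  list(
    n_nodes = x@nNodes, n_edges = x@nEdges, n_arcs = x@nArcs,
    car_threshold = x@carThreshold,
    n_nodes_thresholded = x@nNodesThresholded,
    n_edges_thresholded = x@nEdgesThresholded,
    n_components = x@nComponents,
    biggest_component_nodes = x@biggestComponentNodes,
    biggest_component_edges = x@biggestComponentEdges,
    node_fraction = x@nodeFraction, edge_fraction = x@edgeFraction,
    diameter = x@diameter
  )
}
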