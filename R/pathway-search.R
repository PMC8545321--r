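SCORE_TOL <- 1e-9

# Resolve a compound id to a graph node: compound ids go through the
# stereoisomer merge table; ids that already are node names pass through.
.resolveNode <- function(graph, id, what = "compound") {
  nm <- igraph::V(graph@graph)$name
  if (id %in% names(graph@nodeMap)) {
    node <- unname(graph@nodeMap[[id]])
    if (!node %in% nm) {
      stop(what, " id '", id, "' maps to node '", node,
           "', which is not in the graph (excluded?)", call. = FALSE)
    }
    return(node)
  }
  if (id %in% nm) return(id)
  stop("unknown ", what, " id '", id, "'", call. = FALSE)
}

.dijkstra <- function(g, from, to) {
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = from, to = to,
                           weights = igraph::E(g)$distance,
                           output = "vpath"))
  v <- sp$vpath[[1]]
  if (length(v) == 0) NULL else igraph::as_ids(v)
}

.pathScore <- function(g, nodes) {
  n <- length(nodes)
  eids <- igraph::get_edge_ids(g, rbind(nodes[-n], nodes[-1]))
  sum(igraph::E(g)$distance[eids])
}

.pathKey <- function(nodes) paste(nodes, collapse = "\r")

# Deterministic candidate order: score (1e-9 tolerance), then step count,
# then lexicographic node sequence.
.pathOrder <- function(scores, lens, keys) {
  order(round(scores / SCORE_TOL) * SCORE_TOL, lens, keys)
}

# Yen's k-shortest loop-less path algorithm on an igraph with a `distance`
# edge attribute. Candidates longer than maxLength steps are discarded but
# do not count toward k; on ties at the kth score the candidate pool is
# drained so the returned set is independent of extraction order.
.yenCore <- function(g, src, tgt, k, maxLength) {
  p1 <- .dijkstra(g, src, tgt)
  if (is.null(p1)) return(list())
  allPaths <- list(list(nodes = p1, score = .pathScore(g, p1)))
  seen <- new.env(parent = emptyenv())
  assign(.pathKey(p1), TRUE, envir = seen)
  cand <- list()

  nKept <- as.integer(length(p1) - 1L <= maxLength)
  kthScore <- if (nKept >= 1L) allPaths[[1]]$score else Inf

  repeat {
    if (nKept >= k) {
      # drain score ties at the kth position, then stop
      if (!length(cand)) break
      cs <- vapply(cand, `[[`, numeric(1), "score")
      if (min(cs) > kthScore + SCORE_TOL) break
    }
    prev <- allPaths[[length(allPaths)]]$nodes
    for (i in seq_len(length(prev) - 1L)) {
      root <- prev[seq_len(i)]
      rmEdges <- character(0)
      for (p in allPaths) {
        pn <- p$nodes
        if (length(pn) > i && identical(pn[seq_len(i)], root)) {
          rmEdges <- c(rmEdges, pn[i], pn[i + 1L])
        }
      }
      gg <- g
      if (length(rmEdges)) {
        eids <- igraph::get_edge_ids(gg, rmEdges, error = FALSE)
        eids <- unique(eids[eids > 0])
        if (length(eids)) gg <- igraph::delete_edges(gg, eids)
      }
      if (i > 1L) gg <- igraph::delete_vertices(gg, root[seq_len(i - 1L)])
      spur <- .dijkstra(gg, root[i], tgt)
      if (is.null(spur)) next
      total <- c(root[seq_len(i - 1L)], spur)
      key <- .pathKey(total)
      if (!is.null(mget(key, envir = seen, ifnotfound = list(NULL))[[1]])) next
      assign(key, TRUE, envir = seen)
      cand[[length(cand) + 1L]] <- list(nodes = total,
                                        score = .pathScore(g, total))
    }
    if (!length(cand)) break
    cs <- vapply(cand, `[[`, numeric(1), "score")
    ls <- vapply(cand, function(p) length(p$nodes), integer(1))
    ks <- vapply(cand, function(p) .pathKey(p$nodes), "")
    best <- .pathOrder(cs, ls, ks)[1]
    chosen <- cand[[best]]
    cand[[best]] <- NULL
    allPaths[[length(allPaths) + 1L]] <- chosen
    if (length(chosen$nodes) - 1L <= maxLength) {
      nKept <- nKept + 1L
      if (nKept == k) kthScore <- chosen$score
    }
  }

  keep <- Filter(function(p) length(p$nodes) - 1L <= maxLength, allPaths)
  if (!length(keep)) return(list())
  cs <- vapply(keep, `[[`, numeric(1), "score")
  ls <- vapply(keep, function(p) length(p$nodes), integer(1))
  ks <- vapply(keep, function(p) .pathKey(p$nodes), "")
  keep <- keep[.pathOrder(cs, ls, ks)]
  keep[seq_len(min(k, length(keep)))]
}

.asPathway <- function(g, nodes) {
  n <- length(nodes)
  eids <- igraph::get_edge_ids(g, rbind(nodes[-n], nodes[-1]))
  cars <- igraph::E(g)$car[eids]
  dists <- igraph::E(g)$distance[eids]
  reacts <- strsplit(igraph::E(g)$reactions[eids], ";", fixed = TRUE)
  reacts <- lapply(reacts, function(r) if (length(r)) r else NA_character_)
  list(nodes = nodes, reactions = reacts, stepCars = cars,
       stepDistances = dists, score = sum(dists),
       averageCar = mean(cars), length = n - 1L)
}

.emptyPathwaySet <- function(graph, src, tgt, k, transform) {
  methods::new("PathwaySet", pathways = list(), source = src, target = tgt,
               transform = transform, k = as.numeric(k))
}

#' Yen's k-shortest loop-less pathway search
#'
#' Finds up to `k` simple (no repeated metabolite) pathways from a source to
#' a target compound, ranked by pathway score — the sum of per-step
#' CAR-derived distances, so the best-scoring pathways are the short,
#' atom-conserving ones. Ties in score break by step count, then by
#' lexicographic node sequence, making the output fully deterministic.
#' Candidate pathways longer than `maxLength` reaction steps are discarded
#' without counting toward `k`.
#'
#' Source and target may be given as compound ids (resolved through the
#' stereoisomer merge table) or node ids. If the two endpoints lie in
#' different components the result is empty and a connectivity warning is
#' raised (see [connectivityCheck()]).
#'
#' @param graph a [PairGraph-class]
#' @param source,target compound or node ids; must differ
#' @param k maximum number of pathways to return (>= 1)
#' @param maxLength maximum pathway length in reaction steps
#' @param transform optionally override the graph's CAR-to-distance
#'   transform for this query (edge distances are recomputed from CARs)
#' @return a [PathwaySet-class], ranked best first
#' @examples
#' fx <- makeHubShortcut()
#' g <- buildPairGraph(fx$pairs, fx$compounds, transform = "exp")
#' yenKShortest(g, "C10000", "C10007", k = 2)
#' @export
yenKShortest <- function(graph, source, target, k = 10, maxLength = 100,
                         transform = NULL) {
  stopifnot(methods::is(graph, "PairGraph"), k >= 1, maxLength >= 1)
  src <- .resolveNode(graph, source, "source")
  tgt <- .resolveNode(graph, target, "target")
  if (src == tgt) {
    stop("source and target resolve to the same node ('", src, "')",
         call. = FALSE)
  }
  g <- graph@graph
  activeTransform <- graph@transform
  if (!is.null(transform) && !identical(transform, graph@transform)) {
    transform <- match.arg(transform, c("default", "sqrt", "exp"))
    if (igraph::ecount(g) > 0) {
      igraph::E(g)$distance <- transformDistance(igraph::E(g)$car, transform)
    }
    activeTransform <- transform
  }
  paths <- .yenCore(g, src, tgt, as.integer(k), as.integer(maxLength))
  if (!length(paths)) {
    comp <- igraph::components(g)
    if (comp$membership[src] != comp$membership[tgt]) {
      warning("source '", src, "' and target '", tgt,
              "' lie in different components: no pathway can connect them",
              call. = FALSE)
    }
    return(.emptyPathwaySet(graph, src, tgt, k, activeTransform))
  }
  methods::new("PathwaySet",
               pathways = lapply(paths, function(p) .asPathway(g, p$nodes)),
               source = src, target = tgt, transform = activeTransform,
               k = as.numeric(k))
}

#' Score a pathway from its per-step CARs
#'
#' The pathway score is the sum of the per-step distances under the chosen
#' transform (lower is better); the average CAR is the arithmetic mean of
#' the per-step CARs and summarises how well the pathway conserves atoms.
#'
#' @param edgeCars ordered, non-empty numeric vector of per-step CARs in
#'   `(0, 1]`
#' @inheritParams transformDistance
#' @return list with elements `score` and `averageCar`
#' @examples
#' scorePathway(c(0.5, 0.8), "default")  # score 3.25, average 0.65
#' @export
scorePathway <- function(edgeCars, transform = c("default", "sqrt", "exp")) {
  if (length(edgeCars) == 0L) {
    stop("edgeCars must be a non-empty vector of per-step CARs", call. = FALSE)
  }
  transform <- match.arg(transform)
  list(score = sum(transformDistance(edgeCars, transform)),
       averageCar = mean(edgeCars))
}

#' Two-sided breadth-first search on an unweighted view
#'
#' On the thresholded, unweighted network (every edge distance 1) the
#' shortest pathways can be found much faster by breadth-first search
#' expanding simultaneously from the source and from the target; the two
#' hop-distance fields meet in the middle and every minimum-hop simple path
#' lies on nodes where they sum to the minimum. Pathways are returned
#' ordered by hop count, then lexicographically; loop-less and `k`/
#' `maxLength` semantics match [yenKShortest()]. Ranks beyond the
#' minimum-hop layer are filled by the unit-weight k-shortest search.
#'
#' @param graph an unweighted [PairGraph-class] view, as returned by
#'   [thresholdSubgraph()]
#' @inheritParams yenKShortest
#' @return a [PathwaySet-class]
#' @export
twoSidedUnweightedSearch <- function(graph, source, target, k = 10,
                                     maxLength = 100) {
  stopifnot(methods::is(graph, "PairGraph"), k >= 1, maxLength >= 1)
  if (graph@transform != "unweighted") {
    stop("two-sided search requires an unweighted view; ",
         "call thresholdSubgraph() first", call. = FALSE)
  }
  src <- .resolveNode(graph, source, "source")
  tgt <- .resolveNode(graph, target, "target")
  if (src == tgt) {
    stop("source and target resolve to the same node ('", src, "')",
         call. = FALSE)
  }
  g <- graph@graph
  ds <- igraph::distances(g, v = src, weights = NA)[1, ]
  if (!is.finite(ds[[tgt]])) {
    warning("source '", src, "' and target '", tgt,
            "' lie in different components: no pathway can connect them",
            call. = FALSE)
    return(.emptyPathwaySet(graph, src, tgt, k, "unweighted"))
  }
  dmin <- ds[[tgt]]
  if (dmin > maxLength) {
    return(.emptyPathwaySet(graph, src, tgt, k, "unweighted"))
  }
  dt <- igraph::distances(g, v = tgt, weights = NA)[1, ]
  # enumerate all minimum-hop paths along nodes where the two BFS fields meet
  paths <- list()
  walk <- function(node, acc) {
    if (node == tgt) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible(NULL))
    }
    for (nb in igraph::as_ids(igraph::neighbors(g, node))) {
      if (ds[[nb]] == ds[[node]] + 1 && ds[[nb]] + dt[[nb]] == dmin) {
        walk(nb, c(acc, nb))
      }
    }
  }
  walk(src, src)
  keys <- vapply(paths, .pathKey, "")
  paths <- paths[order(lengths(paths), keys)]
  if (length(paths) < k) {
    # deeper ranks: fall back to the loop-less k-shortest search on unit
    # weights (includes and reproduces the minimum-hop layer)
    more <- .yenCore(g, src, tgt, as.integer(k), as.integer(maxLength))
    paths <- lapply(more, `[[`, "nodes")
  }
  paths <- paths[seq_len(min(k, length(paths)))]
  methods::new("PathwaySet",
               pathways = lapply(paths, function(p) .asPathway(g, p)),
               source = src, target = tgt, transform = "unweighted",
               k = as.numeric(k))
}

#' Run independent searches from several source compounds
#'
#' Each source is searched independently against the same target; results
#' are identical to single [yenKShortest()] calls and independent of
#' execution order. A failing source (e.g. an unknown id) yields an error
#' condition in its slot without affecting the others.
#'
#' @param graph a [PairGraph-class]
#' @param sources character vector of source compound/node ids
#' @inheritParams yenKShortest
#' @return named list, one [PathwaySet-class] (or `condition` on error) per
#'   source
#' @export
multiSourceSearch <- function(graph, sources, target, k = 10,
                              maxLength = 100, transform = NULL) {
  out <- lapply(sources, function(s) {
    tryCatch(yenKShortest(graph, s, target, k = k, maxLength = maxLength,
                          transform = transform),
             error = function(e) e)
  })
  stats::setNames(out, sources)
}
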