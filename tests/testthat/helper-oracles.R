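# Independent oracles: brute-force re-implementations kept deliberately
# separate from the package's code paths.

# Direct evaluation of the CAR definition, term by term.
refCAR <- function(n_c, n_r, n_p) {
  car_r <- n_c / n_r
  car_p <- n_c / n_p
  mean_car <- (car_r + car_p) / 2
  factor <- 1 - abs(car_r - car_p)
  max(0, min(1, mean_car * factor))
}

# Adjacency list (named list of neighbour vectors) from an edge table.
refAdjacency <- function(edges) {
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$node_a[i]; b <- edges$node_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Exhaustive enumeration of all simple paths between two nodes (recursive
# depth-first search).
refSimplePaths <- function(edges, src, tgt) {
  adj <- refAdjacency(edges)
  out <- list()
  walk <- function(node, acc) {
    if (node == tgt) {
      out[[length(out) + 1L]] <<- acc
      return(invisible(NULL))
    }
    for (nb in adj[[node]]) {
      if (!nb %in% acc) walk(nb, c(acc, nb))
    }
  }
  if (src %in% names(adj) && tgt %in% names(adj)) walk(src, src)
  out
}

# Distance lookup for a path on an edge table with a `distance` column.
refPathScore <- function(path, edges) {
  s <- 0
  for (i in seq_len(length(path) - 1L)) {
    a <- min(path[i], path[i + 1L]); b <- max(path[i], path[i + 1L])
    hit <- edges$distance[edges$node_a == a & edges$node_b == b]
    s <- s + hit[1]
  }
  s
}

# Sort paths by (score rounded to 1e-9, length, lexicographic sequence).
refSortPaths <- function(paths, scores) {
  keys <- vapply(paths, paste, "", collapse = "\r")
  ord <- order(round(scores, 9), lengths(paths), keys)
  paths[ord]
}

# Single-source hop distances by hand-rolled breadth-first search.
refBFS <- function(adj, start) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[start] <- 0
  frontier <- start
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- character(0)
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (!is.finite(dist[[v]])) {
          dist[[v]] <- d
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# Connected components by union-find over the edge list.
refComponents <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$node_a[i]); rb <- find(edges$node_b[i])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(nodes, find, "")
}

# Diameter of the component containing most nodes, by all-pairs BFS.
refDiameter <- function(nodes, edges) {
  comp <- refComponents(nodes, edges)
  sizes <- table(comp)
  big <- names(sizes)[which.max(sizes)]
  members <- nodes[comp == big]
  if (length(members) < 2L) return(0)
  adj <- refAdjacency(edges)
  for (n in setdiff(members, names(adj))) adj[[n]] <- character(0)
  max(vapply(members, function(s) {
    d <- refBFS(adj[members], s)
    max(d[is.finite(d)])
  }, numeric(1)))
}

# Unweighted PairGraph straight from an edge data.frame (test convenience).
graphFromPairs <- function(pairs, transform = "default", exclusions = character(0)) {
  buildPairGraph(pairs, compounds = NULL, transform = transform,
                 exclusions = exclusions)
}
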