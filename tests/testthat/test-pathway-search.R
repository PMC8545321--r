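diamondGraph <- function() {
  pairs <- data.frame(
    reaction_id = paste0("R", 1:4),
    substrate_id = c("A", "B", "A", "C"),
    product_id = c("B", "D", "C", "D"),
    car = c(1, 1, 0.5, 0.5), stringsAsFactors = FALSE)
  graphFromPairs(pairs)
}

test_that("the high-CAR branch of a diamond ranks first", {
  ps <- yenKShortest(diamondGraph(), "A", "D", k = 2)
  expect_equal(length(ps), 2L)
  expect_identical(pathwayNodes(ps)[[1]], c("A", "B", "D"))
  expect_identical(pathwayNodes(ps)[[2]], c("A", "C", "D"))
  expect_equal(pathwayScores(ps), c(2, 4))
  expect_equal(averageCars(ps), c(1, 0.5))
})

test_that("k exceeding the number of simple paths returns them all, loop-less", {
  g <- diamondGraph()
  ps <- yenKShortest(g, "A", "D", k = 10)
  expect_equal(length(ps), 2L)
  for (p in pathwayNodes(ps)) expect_false(anyDuplicated(p) > 0)
})

test_that("k-shortest output equals exhaustive enumeration on seeded random graphs", {
  for (seed in 1:20) {
    fx <- makeRandomGraph(nNodes = 10, edgeProb = 0.35, seed = seed)
    g <- graphFromPairs(fx$pairs)
    et <- edgeTable(g)
    nodes <- nodeIds(g)
    src <- nodes[1]; tgt <- nodes[length(nodes)]
    expected <- refSimplePaths(et, src, tgt)
    got <- suppressWarnings(yenKShortest(g, src, tgt, k = 10000))
    expect_equal(length(got), length(expected))
    if (length(expected)) {
      scores <- vapply(expected, refPathScore, numeric(1), edges = et)
      expected <- refSortPaths(expected, scores)
      expect_identical(pathwayNodes(got), expected)
      expect_equal(pathwayScores(got), sort(round(scores, 9)),
                   tolerance = 1e-9)
    }
  }
})

test_that("k-shortest agrees with igraph's independent implementation", {
  fx <- makeRandomGraph(nNodes = 14, edgeProb = 0.3, seed = 99)
  g <- graphFromPairs(fx$pairs)
  nodes <- nodeIds(g)
  src <- nodes[1]; tgt <- nodes[length(nodes)]
  ours <- yenKShortest(g, src, tgt, k = 8)
  ref <- igraph::k_shortest_paths(g@graph, from = src, to = tgt, k = 8,
                                  weights = igraph::E(g@graph)$distance)
  refScores <- vapply(ref$vpaths, function(v) {
    refPathScore(igraph::as_ids(v), edgeTable(g))
  }, numeric(1))
  expect_equal(pathwayScores(ours), sort(refScores), tolerance = 1e-9)
})

test_that("scores are non-decreasing with rank under every transform", {
  fx <- makeRandomGraph(nNodes = 12, edgeProb = 0.35, seed = 5)
  for (tr in c("default", "sqrt", "exp")) {
    g <- graphFromPairs(fx$pairs, transform = tr)
    nodes <- nodeIds(g)
    ps <- suppressWarnings(
      yenKShortest(g, nodes[1], nodes[length(nodes)], k = 50))
    expect_true(all(diff(pathwayScores(ps)) >= -1e-9))
  }
})

test_that("a perfectly conserving path scores its own length under all transforms", {
  fx <- makeLinearChain(n = 5, car = 1)
  for (tr in c("default", "sqrt", "exp")) {
    g <- graphFromPairs(fx$pairs, transform = tr)
    ps <- yenKShortest(g, "C00001", "C00005", k = 1)
    expect_equal(pathwayScores(ps), 4)
    expect_equal(averageCars(ps), 1)
  }
})

test_that("scorePathway sums transformed distances and averages CARs", {
  expect_equal(scorePathway(c(1, 1), "default"),
               list(score = 2, averageCar = 1))
  s <- scorePathway(c(0.5, 0.8), "default")
  expect_equal(s$score, 3.25, tolerance = 1e-9)
  expect_equal(s$averageCar, 0.65, tolerance = 1e-9)
  se <- scorePathway(c(0.5, 0.8), "exp")
  expect_equal(se$score, exp(1) + exp(0.25), tolerance = 1e-9)
  expect_equal(se$score, 4.00230688, tolerance = 1e-7)
  expect_error(scorePathway(numeric(0)), "non-empty")
})

test_that("maxLength discards long candidates without eating into k", {
  # two 2-step routes (score 6 each) and one cheap 3-step route (score 3)
  pairs <- data.frame(
    reaction_id = paste0("R", 1:7),
    substrate_id = c("S", "M", "S", "N", "S", "P", "Q"),
    product_id = c("M", "T", "N", "T", "P", "Q", "T"),
    car = c(0.25, 0.5, 0.5, 0.25, 1, 1, 1), stringsAsFactors = FALSE)
  g <- graphFromPairs(pairs)
  full <- yenKShortest(g, "S", "T", k = 2)
  expect_equal(pathwayScores(full)[1], 3)          # the 3-step route wins
  capped <- yenKShortest(g, "S", "T", k = 2, maxLength = 2)
  expect_equal(length(capped), 2L)                 # k still filled
  expect_true(all(vapply(capped@pathways, `[[`, numeric(1), "length") <= 2))
  expect_equal(pathwayScores(capped), c(6, 6))
  # equal scores: lexicographic node order decides
  expect_identical(pathwayNodes(capped),
                   list(c("S", "M", "T"), c("S", "N", "T")))
})

test_that("equal-score pathways order by length then lexicographic sequence", {
  pairs <- data.frame(
    reaction_id = paste0("R", 1:4),
    substrate_id = c("A", "B", "A", "C"),
    product_id = c("B", "D", "C", "D"),
    car = c(0.5, 0.5, 0.5, 0.5), stringsAsFactors = FALSE)
  ps <- yenKShortest(graphFromPairs(pairs), "A", "D", k = 2)
  expect_identical(pathwayNodes(ps), list(c("A", "B", "D"), c("A", "C", "D")))
})

test_that("per-step reaction sets survive into results with sorted representatives", {
  pairs <- data.frame(
    reaction_id = c("R9", "R2", "R5"),
    substrate_id = c("A", "A", "B"), product_id = c("B", "B", "C"),
    car = c(0.8, 0.8, 0.9), stringsAsFactors = FALSE)
  ps <- yenKShortest(graphFromPairs(pairs), "A", "C", k = 1)
  expect_setequal(ps@pathways[[1]]$reactions[[1]], c("R2", "R9"))
  tb <- as.data.frame(ps)
  expect_identical(tb$reaction_ids, "R2->R5")
})

test_that("unknown endpoints, identical endpoints and disconnection are handled", {
  g <- diamondGraph()
  expect_error(yenKShortest(g, "nope", "D"), "nope")
  expect_error(yenKShortest(g, "A", "A"), "same node")
  pairs <- data.frame(reaction_id = c("R1", "R2"),
                      substrate_id = c("A", "X"), product_id = c("B", "Y"),
                      car = c(1, 1), stringsAsFactors = FALSE)
  gd <- graphFromPairs(pairs)
  expect_warning(ps <- yenKShortest(gd, "A", "Y"), "different components")
  expect_equal(length(ps), 0L)
})

test_that("two-sided search reproduces single-sided BFS shortest paths", {
  fx <- makeLinearChain(n = 4, car = 0.9)
  tg <- thresholdSubgraph(graphFromPairs(fx$pairs), 0.34)
  ps <- twoSidedUnweightedSearch(tg, "C00001", "C00004")
  expect_equal(length(ps), 1L)
  expect_equal(ps@pathways[[1]]$length, 3L)

  for (seed in c(3, 17, 29)) {
    fx <- makeRandomGraph(nNodes = 15, edgeProb = 0.25, seed = seed)
    g <- graphFromPairs(fx$pairs)
    tg <- thresholdSubgraph(g, 0.3)
    et <- edgeTable(tg)
    nodes <- nodeIds(tg)
    src <- nodes[1]; tgt <- nodes[length(nodes)]
    adj <- refAdjacency(et)
    if (!src %in% names(adj) || !tgt %in% names(adj)) next
    dist <- refBFS(adj, src)
    if (!is.finite(dist[[tgt]])) {
      expect_warning(ps <- twoSidedUnweightedSearch(tg, src, tgt),
                     "different components")
      expect_equal(length(ps), 0L)
    } else {
      ps <- twoSidedUnweightedSearch(tg, src, tgt, k = 1000)
      all_simple <- refSimplePaths(et, src, tgt)
      minhop <- Filter(function(p) length(p) - 1 == dist[[tgt]], all_simple)
      got_min <- Filter(function(p) length(p) - 1 == dist[[tgt]],
                        pathwayNodes(ps))
      expect_setequal(vapply(got_min, paste, "", collapse = ">"),
                      vapply(minhop, paste, "", collapse = ">"))
      hops <- vapply(ps@pathways, `[[`, numeric(1), "length")
      expect_true(all(diff(hops) >= 0))
    }
  }
})

test_that("two-sided search refuses a weighted graph", {
  expect_error(twoSidedUnweightedSearch(diamondGraph(), "A", "D"),
               "unweighted view")
})

test_that("multi-source searches equal independent single-source runs", {
  fx <- makeRandomGraph(nNodes = 12, edgeProb = 0.35, seed = 8)
  g <- graphFromPairs(fx$pairs)
  nodes <- nodeIds(g)
  tgt <- nodes[length(nodes)]
  sources <- nodes[1:3]
  multi <- suppressWarnings(multiSourceSearch(g, sources, tgt, k = 5))
  expect_named(multi, sources)
  for (s in sources) {
    single <- suppressWarnings(yenKShortest(g, s, tgt, k = 5))
    expect_identical(pathwayNodes(multi[[s]]), pathwayNodes(single))
    expect_equal(pathwayScores(multi[[s]]), pathwayScores(single))
  }
  expect_length(multiSourceSearch(g, character(0), tgt), 0L)
  mixed <- suppressWarnings(
    multiSourceSearch(g, c(nodes[1], "bogus"), tgt, k = 2))
  expect_s4_class(mixed[[nodes[1]]], "PathwaySet")
  expect_s3_class(mixed[["bogus"]], "condition")
})

test_that("a query can override the graph's transform", {
  fx <- makeHubShortcut()
  g <- buildPairGraph(fx$pairs, fx$compounds, transform = "default")
  ps <- yenKShortest(g, fx$source, fx$target, k = 1, transform = "sqrt")
  expect_equal(ps@transform, "sqrt")
  expect_identical(pathwayNodes(ps)[[1]], c(fx$source, fx$hub, fx$target))
})
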