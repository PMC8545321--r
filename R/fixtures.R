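# Run expr under a fixed seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

#' Hub-shortcut test network
#'
#' The motivating scenario for CAR weighting: a 2-step shortcut through a
#' promiscuous hub metabolite whose pairs conserve few atoms (CAR 0.2 per
#' step), against a 5-step chain of well-conserving biotransformations
#' (CAR 0.9 per step) between the same source and target. The transforms
#' disagree on which route wins: per-transform route scores are
#'
#' | transform | hub (2 steps) | chain (5 steps) | rank 1 |
#' |-----------|--------------:|----------------:|--------|
#' | default   | 10.0          | 5.5556          | chain  |
#' | sqrt      | 4.4721        | 5.2705          | hub    |
#' | exp       | 109.1963      | 5.5876          | chain  |
#'
#' The ground-truth table ships these hand-derived scores.
#'
#' @return list with `pairs` (weighted pair table), `compounds`,
#'   `source`, `target`, and `groundTruth` (route scores and ranks per
#'   transform)
#' @export
makeHubShortcut <- function() {
  hub <- "C10001"
  src <- "C10000"
  tgt <- "C10007"
  chain <- c(src, "C10003", "C10004", "C10005", "C10006", tgt)
  pairs <- data.frame(
    reaction_id = sprintf("R9%04d", 1:7),
    substrate_id = c(src, hub, chain[-6]),
    product_id = c(hub, tgt, chain[-1]),
    car = c(0.2, 0.2, rep(0.9, 5)),
    stringsAsFactors = FALSE)
  compounds <- data.frame(
    compound_id = sort(unique(c(pairs$substrate_id, pairs$product_id))),
    name = NA_character_, stringsAsFactors = FALSE)
  groundTruth <- data.frame(
    transform = rep(c("default", "sqrt", "exp"), each = 2),
    route = rep(c("hub", "chain"), 3),
    length = rep(c(2L, 5L), 3),
    score = c(10.0, 5.55555556,
              4.47213595, 5.27046277,
              109.19630007, 5.58759533),
    rank1 = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  list(pairs = pairs, compounds = compounds, source = src, target = tgt,
       hub = hub, chain = chain, groundTruth = groundTruth)
}

#' Coenzyme-A contraction test case
#'
#' Three thioester transformations over a shared 48-pseudo-atom CoA moiety
#' plus a small-molecule analog, with hand-derived CARs before and after
#' contraction:
#' \itemize{
#'   \item elongation `C20001 -> C20002` (acyl groups share 4 atoms):
#'     CAR 0.9197 uncontracted, 0.5078 contracted;
#'   \item elongation `C20002 -> C20003` (share 4): 0.9212 / 0.5493;
#'   \item acyl swap `C20001 -> C20003` (share 1 atom): 0.8475
#'     uncontracted — a deceptive near-1 edge — but 0.2558 contracted,
#'     below the 0.34 main-pair cutoff;
#'   \item `C20041 -> C20043` (no CoA): 0.375 with or without the flag.
#' }
#' Contraction therefore flips the best route from `C20001` to `C20003`
#' from the direct swap edge to the two-step elongation route.
#'
#' @return list with `reactions` (atom-mapped, CoA moieties annotated),
#'   `compounds` (with `coa_carrier` flags), and `groundTruth`
#' @export
makeCoaCase <- function() {
  coa <- 1:48
  withCoa <- function(atoms) { attr(atoms, "coa") <- coa; atoms }
  A <- withCoa(c(coa, 100:103))         # acyl-CoA, 4-atom acyl
  C <- withCoa(c(coa, 100:103, 110:112)) # elongated, 7-atom acyl
  B <- withCoa(c(coa, 103, 110:116))    # swapped, 8-atom acyl
  reactions <- list(
    atomMappedReaction("R91001",
      reactants = list(C20001 = A, C20011 = 110:112),
      products = list(C20002 = C)),
    atomMappedReaction("R91002",
      reactants = list(C20002 = C, C20012 = 113:116),
      products = list(C20003 = B, C20031 = 100:102)),
    atomMappedReaction("R91003",
      reactants = list(C20001 = A, C20013 = 110:116),
      products = list(C20003 = B, C20031 = 100:102)),
    atomMappedReaction("R91004",
      reactants = list(C20041 = c(49L, 50L), C20042 = c(51L, 52L)),
      products = list(C20043 = 49:52)))
  ids <- c("C20001", "C20002", "C20003", "C20011", "C20012", "C20013",
           "C20031", "C20041", "C20042", "C20043")
  compounds <- data.frame(
    compound_id = ids,
    coa_carrier = ids %in% c("C20001", "C20002", "C20003"),
    stringsAsFactors = FALSE)
  groundTruth <- data.frame(
    substrate_id = c("C20001", "C20002", "C20001", "C20041"),
    product_id = c("C20002", "C20003", "C20003", "C20043"),
    car_uncontracted = c(0.91966942, 0.92119325, 0.84749408, 0.375),
    car_contracted = c(0.50781250, 0.54928627, 0.25580247, 0.375),
    stringsAsFactors = FALSE)
  list(reactions = reactions, compounds = compounds,
       groundTruth = groundTruth)
}

#' Labelled pair populations for ROC validation
#'
#' Draws CAR scores for "main" and non-main pair populations from Beta
#' distributions (bounded on `[0, 1]`). The default shapes —
#' positives Beta(1.6, 1.4), negatives Beta(1.3, 5.75) — and the default
#' class sizes 5148/5599 emulate the curated reference pair set's
#' separation: the theoretical AUC of the two distributions is 0.880 and
#' their densities cross at CAR 0.341, so a well-behaved classifier
#' analysis should recover approximately those values.
#'
#' @param nPos,nNeg class sizes (>= 1)
#' @param posShape,negShape Beta shape pairs `c(alpha, beta)` for the
#'   positive and negative CAR populations
#' @param seed integer seed; the same seed reproduces the identical table
#' @return data.frame with columns `substrate_id`, `product_id`, `car`,
#'   `is_main`
#' @export
makeLabeledPairs <- function(nPos = 5148, nNeg = 5599,
                             posShape = c(1.6, 1.4),
                             negShape = c(1.3, 5.75), seed = 42) {
  stopifnot(nPos >= 1, nNeg >= 1)
  if (length(posShape) != 2L || length(negShape) != 2L ||
      any(c(posShape, negShape) <= 0)) {
    stop("Beta shape parameters must be two positive numbers per class",
         call. = FALSE)
  }
  .withSeed(seed, {
    n <- nPos + nNeg
    data.frame(
      substrate_id = sprintf("C%05d", seq_len(n)),
      product_id = sprintf("C%05d", seq_len(n) + n),
      car = c(stats::rbeta(nPos, posShape[1], posShape[2]),
              stats::rbeta(nNeg, negShape[1], negShape[2])),
      is_main = rep(c(TRUE, FALSE), c(nPos, nNeg)),
      stringsAsFactors = FALSE)
  })
}

#' Seeded random pair network
#'
#' Erdos-Renyi style undirected network with uniform CAR weights, used for
#' oracle-equivalence tests (exhaustive path enumeration, all-pairs BFS)
#' at desk scale.
#'
#' @param nNodes number of compounds (<= 50 keeps brute-force oracles fast)
#' @param edgeProb probability of an edge between any two compounds
#' @param carRange range the uniform CAR draws are scaled into
#' @param seed integer seed
#' @return list with `pairs` and `compounds`
#' @export
makeRandomGraph <- function(nNodes, edgeProb, carRange = c(0.1, 1),
                            seed = 1) {
  stopifnot(nNodes >= 2, edgeProb >= 0, edgeProb <= 1,
            length(carRange) == 2L, carRange[1] > 0, carRange[2] <= 1)
  .withSeed(seed, {
    ids <- sprintf("C%05d", seq_len(nNodes))
    comb <- utils::combn(ids, 2)
    keep <- stats::runif(ncol(comb)) < edgeProb
    m <- sum(keep)
    pairs <- data.frame(
      reaction_id = sprintf("R%05d", seq_len(m)),
      substrate_id = comb[1, keep], product_id = comb[2, keep],
      car = stats::runif(m, carRange[1], carRange[2]),
      stringsAsFactors = FALSE)
    list(pairs = pairs,
         compounds = data.frame(compound_id = ids, stringsAsFactors = FALSE))
  })
}

#' Linear chain network
#'
#' A path of `n` compounds joined by edges of constant CAR; the simplest
#' connected fixture.
#'
#' @param n number of compounds (>= 2)
#' @param car CAR of every step
#' @return list with `pairs` and `compounds`
#' @export
makeLinearChain <- function(n = 4, car = 1) {
  stopifnot(n >= 2)
  ids <- sprintf("C%05d", seq_len(n))
  list(
    pairs = data.frame(
      reaction_id = sprintf("R%05d", seq_len(n - 1)),
      substrate_id = ids[-n], product_id = ids[-1],
      car = rep(car, n - 1), stringsAsFactors = FALSE),
    compounds = data.frame(compound_id = ids, stringsAsFactors = FALSE))
}

#' Write a fixture to a directory
#'
#' Emits the TSV files the package's own loaders accept: `pairs.tsv` and
#' `compounds.tsv` always, `ground_truth.tsv` when the fixture ships one,
#' `reactions.tsv` (structured atom-map dialect) for reaction-level
#' fixtures, and `labeled_pairs.tsv` for labelled populations.
#'
#' @param fixture a fixture list, or a labelled-pair data.frame
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.data.frame(fixture)) {          # labelled pairs
    .writeTsv(fixture, file.path(dir, "labeled_pairs.tsv"))
    return(invisible(dir))
  }
  if (!is.null(fixture$pairs)) {
    tb <- fixture$pairs
    tb$car <- formatC(tb$car, format = "g", digits = 17)
    .writeTsv(tb, file.path(dir, "pairs.tsv"))
  }
  if (!is.null(fixture$compounds)) {
    .writeTsv(fixture$compounds, file.path(dir, "compounds.tsv"))
  }
  if (!is.null(fixture$groundTruth)) {
    .writeTsv(fixture$groundTruth, file.path(dir, "ground_truth.tsv"))
  }
  if (!is.null(fixture$reactions)) {
    writeReactionTable(fixture$reactions, file.path(dir, "reactions.tsv"))
  }
  invisible(dir)
}
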