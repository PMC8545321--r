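test_that("computeCAR reproduces hand-derived values", {
  expect_equal(computeCAR(6, 6, 6), 1.0)
  expect_equal(computeCAR(5, 6, 5), 0.7638889, tolerance = 1e-6)
  # decarboxylation: retained moiety outscores the leaving CO2 fragment
  expect_equal(computeCAR(7, 10, 7), 0.595, tolerance = 1e-9)
  expect_equal(computeCAR(3, 10, 3), 0.195, tolerance = 1e-9)
  expect_gt(computeCAR(7, 10, 7), computeCAR(3, 10, 3))
  expect_equal(computeCAR(0, 4, 9), 0)
})

test_that("computeCAR matches term-by-term evaluation on all small count triples", {
  for (n_r in 1:12) for (n_p in 1:12) {
    n_c <- 0:min(n_r, n_p)
    expect_equal(computeCAR(n_c, n_r, n_p),
                 vapply(n_c, refCAR, numeric(1), n_r = n_r, n_p = n_p),
                 tolerance = 1e-12)
  }
})

test_that("CAR is symmetric, bounded by the mean ratio, monotone for equal sizes", {
  for (a in 1:10) for (b in 1:10) {
    n_c <- min(a, b)
    expect_identical(computeCAR(n_c, a, b), computeCAR(n_c, b, a))
    cars <- computeCAR(0:n_c, a, b)
    means <- (0:n_c / a + 0:n_c / b) / 2
    expect_true(all(cars <= means + 1e-12))
    expect_true(all(cars >= 0 & cars <= 1))
    # every positive conserved count beats conserving nothing
    if (n_c >= 1) expect_true(all(cars[-1] > 0))
  }
  # between equal-sized molecules more conserved atoms always score higher
  for (a in 1:10) {
    expect_true(all(diff(computeCAR(0:a, a, a)) > 0))
  }
  # with unequal sizes the mismatch penalty can outgrow the mean: the CAR
  # is NOT monotone in n_c (a fully-mapped small fragment of a large
  # molecule outscores a larger shared core)
  expect_gt(computeCAR(1, 12, 2), computeCAR(2, 12, 2))
  # boundaries: nothing conserved vs identical molecules
  expect_equal(computeCAR(0, 7, 3), 0)
  expect_equal(computeCAR(7, 7, 7), 1)
  # CAR = 1 only when all three counts coincide
  expect_lt(computeCAR(5, 5, 6), 1)
  expect_lt(computeCAR(5, 6, 6), 1)
})

test_that("computeCAR rejects invalid atom counts", {
  expect_error(computeCAR(1, 0, 3), "n_r and n_p")
  expect_error(computeCAR(4, 3, 5), "n_c must satisfy")
  expect_error(computeCAR(-1, 3, 5), "n_c must satisfy")
})

test_that("decomposeReaction yields one pair per reactant-product combination", {
  rxn <- atomMappedReaction("R1",
    reactants = list(A = 1:6, B = 7:10),
    products = list(C = 1:6, D = 7:10))
  tab <- decomposeReaction(rxn)
  expect_equal(nrow(tab), 4L)
  expect_setequal(paste(tab$substrate_id, tab$product_id),
                  c("A C", "A D", "B C", "B D"))
})

test_that("an oxidoreduction splits into two aligned maximal-CAR pairs and two zero pairs", {
  # alcohol -> aldehyde with a nicotinamide-style cofactor pair: only
  # electrons/protons move, so each molecule maps fully onto its partner
  rxn <- atomMappedReaction("R2",
    reactants = list(alcohol = 1:6, nad = 7:50),
    products = list(aldehyde = 1:6, nadh = 7:50))
  tab <- decomposeReaction(rxn)
  aligned <- tab[tab$n_c > 0, ]
  cross <- tab[tab$n_c == 0, ]
  expect_equal(nrow(aligned), 2L)
  expect_equal(aligned$car, c(1, 1))
  expect_equal(nrow(cross), 2L)
  expect_equal(cross$car, c(0, 0))
})

test_that("decarboxylation pairs carry the hand-constructed atom counts", {
  rxn <- atomMappedReaction("R3",
    reactants = list(substrate = 1:10),
    products = list(product = 1:7, co2 = 8:10))
  tab <- decomposeReaction(rxn)
  main <- tab[tab$product_id == "product", ]
  leave <- tab[tab$product_id == "co2", ]
  expect_equal(main$n_c, 7L)
  expect_equal(leave$n_c, 3L)
  expect_equal(main$car, 0.595, tolerance = 1e-9)
  expect_equal(leave$car, 0.195, tolerance = 1e-9)
})

test_that("degenerate molecules and self-pairs are rejected with warnings", {
  rxn <- atomMappedReaction("R4",
    reactants = list(A = 1:4, empty = integer(0)),
    products = list(B = 1:4))
  expect_warning(tab <- decomposeReaction(rxn), "no heavy atoms")
  expect_equal(nrow(tab), 1L)

  carrier <- atomMappedReaction("R5",
    reactants = list(A = 1:4, X = 5:8),
    products = list(X = 5:8, B = 1:4))
  expect_warning(tab <- decomposeReaction(carrier), "self-pair")
  expect_false(any(tab$substrate_id == tab$product_id))
})

test_that("stoichiometric duplicates keep the maximal mapping per pair", {
  rxn <- atomMappedReaction("R6",
    reactants = list(A = 1:3, A = 4:5),
    products = list(B = c(1:3, 4L)))
  tab <- decomposeReaction(rxn)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_c, 3L)  # the 3-atom instance wins over the 1-atom one
})

test_that("atomMappedReaction enforces the atom-map invariants", {
  expect_error(
    atomMappedReaction("bad", reactants = list(A = c(1L, 2L), B = 2:4),
                       products = list(C = 1:4)),
    "more than once")
  expect_error(
    atomMappedReaction("bad", reactants = list(1:3),
                       products = list(C = 1:3)),
    "named list")
})

test_that("CoA contraction collapses the moiety only when shared by both sides", {
  cc <- makeCoaCase()
  carriers <- coaCarriers(cc$compounds)
  plain <- decomposeReactions(cc$reactions, carriers, contract = FALSE)
  contr <- decomposeReactions(cc$reactions, carriers, contract = TRUE)
  for (i in seq_len(nrow(cc$groundTruth))) {
    gt <- cc$groundTruth[i, ]
    sel <- function(tb) tb$car[tb$substrate_id == gt$substrate_id &
                               tb$product_id == gt$product_id]
    expect_equal(sel(plain), gt$car_uncontracted, tolerance = 1e-6,
                 label = paste("uncontracted", gt$substrate_id, gt$product_id))
    expect_equal(sel(contr), gt$car_contracted, tolerance = 1e-6,
                 label = paste("contracted", gt$substrate_id, gt$product_id))
  }
  # contraction strictly lowers the CAR whenever acyl parts share fewer
  # atoms than the moiety holds
  shared <- cc$groundTruth[cc$groundTruth$car_uncontracted >
                             cc$groundTruth$car_contracted, ]
  expect_gte(nrow(shared), 3L)
  # the non-CoA reaction is untouched by the flag
  plainSmall <- plain[plain$substrate_id == "C20041" &
                        plain$product_id == "C20043", ]
  contrSmall <- contr[contr$substrate_id == "C20041" &
                        contr$product_id == "C20043", ]
  expect_identical(plainSmall$car, contrSmall$car)
})

test_that("contractCoA is a no-op without CoA and warns on one-sided carriers", {
  rxn <- atomMappedReaction("R7", reactants = list(A = 1:4),
                            products = list(B = 1:4))
  expect_identical(contractCoA(rxn, c("C00010")), rxn)

  coaMol <- c(1:48, 49L, 50L)
  attr(coaMol, "coa") <- 1:48
  oneSided <- atomMappedReaction("R8",
    reactants = list(acylcoa = coaMol),
    products = list(acid = c(49L, 50L)))
  expect_warning(out <- contractCoA(oneSided, "acylcoa"), "one side only")
  expect_identical(out, oneSided)
})

test_that("a conserved CoA pseudo-atom counts toward n_c", {
  coa <- 1:48
  a <- c(coa, 100L, 101L); attr(a, "coa") <- coa
  b <- c(coa, 100L, 101L, 102L, 103L); attr(b, "coa") <- coa
  rxn <- atomMappedReaction("R9",
    reactants = list(A = a, D = 102:103), products = list(B = b))
  tab <- decomposeReaction(rxn, coaCarriers = c("A", "B"))
  ab <- tab[tab$substrate_id == "A", ]
  expect_equal(ab$n_r, 3L)  # 2 acyl + 1 pseudo-atom
  expect_equal(ab$n_p, 5L)
  expect_equal(ab$n_c, 3L)  # both acyl atoms plus the conserved pseudo-atom
})
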