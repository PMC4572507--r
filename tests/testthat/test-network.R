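## small fixed network fixture: 6 nodes in 2 categories, hand-picked weights
smallCDN <- function() {
  ids <- paste0("D", 1:6)
  cats <- setNames(rep(c("CA", "CB"), each = 3), ids)
  sim <- matrix(0, 6, 6, dimnames = list(ids, ids))
  put <- function(a, b, w) { sim[a, b] <<- w; sim[b, a] <<- w }
  put("D1", "D2", 2.5); put("D2", "D3", 3.0); put("D1", "D3", 2.2)
  put("D4", "D5", 2.8); put("D5", "D6", 2.6)
  put("D3", "D4", 2.1)   # one cross-category (gray) edge
  buildCDN(sim, cats, simcut = 2)
}

test_that("network construction thresholds strictly and drops isolates", {
  ids <- c("A", "B", "C")
  sim <- matrix(0, 3, 3, dimnames = list(ids, ids))
  sim["A", "B"] <- sim["B", "A"] <- 2.5
  sim["A", "C"] <- sim["C", "A"] <- 2.0   # exactly at the cutoff: no edge
  cats <- setNames(c("X", "X", "Y"), ids)
  cdn <- buildCDN(sim, cats, simcut = 2)
  expect_setequal(cdnNodes(cdn), c("A", "B"))     # C is isolated, dropped
  expect_equal(nrow(cdnEdges(cdn)), 1)
  expect_equal(cdnEdges(cdn)$weight, 2.5)

  # all similarities below the cutoff: an empty, valid network
  empty <- buildCDN(matrix(0, 3, 3, dimnames = list(ids, ids)), cats, 2)
  expect_length(cdnNodes(empty), 0)
  expect_equal(nrow(cdnEdges(empty)), 0)

  expect_error(buildCDN(sim, cats, simcut = -1), "non-negative")
  expect_error(buildCDN(sim, cats[1:2], simcut = 2), "missing")
})

test_that("gray edges are those whose endpoints share no category", {
  cdn <- smallCDN()
  gef <- grayEdgeFraction(cdn)
  expect_equal(gef$totalEdges, 6L)
  expect_equal(gef$grayEdges, 1L)
  expect_equal(gef$fraction, 1 / 6)

  # multi-category endpoints: sharing any one category makes the edge
  # non-gray
  ids <- c("P", "Q")
  sim <- matrix(c(0, 3, 3, 0), 2, dimnames = list(ids, ids))
  cdn2 <- buildCDN(sim, list(P = c("X", "Y"), Q = c("Y", "Z")), simcut = 2)
  expect_equal(grayEdgeFraction(cdn2)$grayEdges, 0L)
  cdn3 <- buildCDN(sim, list(P = c("X", "Y"), Q = c("Z", "W")), simcut = 2)
  expect_equal(grayEdgeFraction(cdn3)$grayEdges, 1L)

  ids3 <- c("A", "B", "C")
  edgeless <- buildCDN(matrix(0, 3, 3, dimnames = list(ids3, ids3)),
                       setNames(c("X", "X", "Y"), ids3), 2)
  expect_error(grayEdgeFraction(edgeless), "edgeless")
})

test_that("edge randomization preserves the exact degree sequence", {
  for (s in 1:5) {
    cdn <- syntheticModularCDN(nBlocks = 2, nodesPerBlock = 10,
                               pWithin = 0.5, seed = s)
    degBefore <- cdnDegrees(cdn)
    r <- edgeRandomize(cdn, seed = s + 100)
    # independent counting oracle over the edge table
    e <- cdnEdges(r)
    degAfter <- table(factor(c(e$a, e$b), levels = cdnNodes(cdn)))
    expect_equal(as.integer(degAfter), unname(degBefore))
    expect_equal(nrow(e), nrow(cdnEdges(cdn)))
    # no self-loops, no duplicated edges
    expect_true(all(e$a != e$b))
    expect_false(any(duplicated(paste(pmin(e$a, e$b), pmax(e$a, e$b)))))
  }

  cdn <- smallCDN()
  # zero swaps: the identical network
  r0 <- edgeRandomize(cdn, nSwaps = 0, seed = 1)
  expect_setequal(paste(cdnEdges(r0)$a, cdnEdges(r0)$b),
                  paste(cdnEdges(cdn)$a, cdnEdges(cdn)$b))
  # determinism given the seed
  expect_identical(cdnEdges(edgeRandomize(cdn, seed = 7)),
                   cdnEdges(edgeRandomize(cdn, seed = 7)))

  # 4-cycle: a swap either recreates an existing edge (skipped) or flips
  # to the diagonal pairing; the edge count never changes
  ids <- c("A", "B", "C", "D")
  sim <- matrix(0, 4, 4, dimnames = list(ids, ids))
  for (p in list(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "A"))) {
    sim[p[1], p[2]] <- 3; sim[p[2], p[1]] <- 3
  }
  cyc <- buildCDN(sim, setNames(rep("X", 4), ids), 2)
  for (s in 1:5) {
    r <- edgeRandomize(cyc, nSwaps = 1, seed = s)
    expect_equal(nrow(cdnEdges(r)), 4)
    deg <- table(c(cdnEdges(r)$a, cdnEdges(r)$b))
    expect_true(all(deg == 2))
  }
})

test_that("annotation randomization replaces the prescribed fraction", {
  ont <- toyPhenoOntology()
  sets <- list(D1 = c("HP:0009381", "HP:0001500", "HP:0002315", "HP:0001903"),
               D2 = c("HP:0000256", "HP:0005472"))

  expect_identical(annotationRandomize(sets, 0, ont, seed = 1)$D1, sets$D1)

  r <- annotationRandomize(sets, 0.5, ont, seed = 2)
  expect_length(r$D1, 4)
  expect_equal(sum(sets$D1 %in% r$D1), 2)    # exactly half survive
  expect_length(r$D2, 2)
  expect_equal(sum(sets$D2 %in% r$D2), 1)

  r1 <- annotationRandomize(sets, 1, ont, seed = 3)
  expect_equal(sum(sets$D1 %in% r1$D1), 0)
  expect_length(r1$D1, 4)
  # replacements come from the abnormality subtree
  pool <- termDescendants(ont, abnormalityRoot(ont))
  expect_true(all(unlist(r1) %in% pool))
  # deterministic given the seed
  expect_identical(annotationRandomize(sets, 0.5, ont, seed = 9),
                   annotationRandomize(sets, 0.5, ont, seed = 9))
  expect_error(annotationRandomize(sets, 1.5, ont, seed = 1), "fraction")
})

test_that("edge-randomization significance recovers planted modularity", {
  cdn <- syntheticModularCDN(seed = 5)
  expect_equal(grayEdgeFraction(cdn)$fraction, 0)
  rep <- gefSignificance(cdn, "er", replicates = 100, seed = 7)
  # every rewired null mixes the two blocks, so the observed GEF of 0 is
  # below all null values
  expect_true(all(rep@nulls > 0))
  expect_equal(rep@pValue, 1 / 101)
  expect_equal(rep@bound, "p < 0.01")
  # the observed GEF sits below the 1st percentile of the null
  expect_lt(rep@observed, quantile(rep@nulls, 0.01))
})

test_that("a rewire-invariant network yields p = 1", {
  # a triangle cannot be rewired without creating loops or duplicates
  ids <- c("A", "B", "C")
  sim <- matrix(3, 3, 3, dimnames = list(ids, ids)); diag(sim) <- 0
  tri <- buildCDN(sim, setNames(c("X", "X", "Y"), ids), 2)
  rep <- gefSignificance(tri, "er", replicates = 50, seed = 3)
  expect_true(all(rep@nulls == rep@observed))
  expect_equal(rep@pValue, 1)
  expect_true(is.na(rep@bound))
})

test_that("annotation-randomization significance rebuilds the network per replicate", {
  ont <- syntheticOntology(80, 4, seed = 2)
  gen <- generateSyntheticCorpus(ont, nDiseases = 12, termsPerDisease = 6,
                                 abstractsPerDisease = 8, seed = 3)
  sets <- gen$truth$planted
  icD <- termFrequencies(ont, sets)
  sim <- pairwiseSimilarity(ont, icD, sets)
  cut <- unname(quantile(sim[upper.tri(sim)], 0.7))
  cdn <- buildCDN(sim, gen$categories, simcut = cut)
  rep <- gefSignificance(cdn, "ar", replicates = 20, seed = 11,
                         arInputs = list(sets = sets, ic = icD,
                                         categories = gen$categories,
                                         ontology = ont))
  expect_length(rep@nulls, 20)
  expect_true(all(rep@nulls >= 0 & rep@nulls <= 1))
  expect_gt(rep@pValue, 0)
  expect_lte(rep@pValue, 1)
  # the ar replicate simcut can be lowered to keep replicate networks
  # comparable in size
  rep2 <- gefSignificance(cdn, "ar", replicates = 5, seed = 11,
                          arInputs = list(sets = sets, ic = icD,
                                          categories = gen$categories,
                                          ontology = ont,
                                          simcut = cut * 0.7))
  expect_length(rep2@nulls, 5)

  expect_error(gefSignificance(cdn, "ar", replicates = 2, seed = 1),
               "arInputs")
})

test_that("graph export round-trips and honors the public formats", {
  cdn <- smallCDN()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  exportGraph(cdn, tsv, format = "edge-tsv")
  back <- importCDN(tsv)
  expect_identical(cdnNodes(back), cdnNodes(cdn))
  expect_identical(cdnCategories(back), cdnCategories(cdn))
  expect_equal(cdnEdges(back), cdnEdges(cdn))
  expect_equal(back@simcut, cdn@simcut)

  # empty network: a valid (empty-bodied) document that round-trips
  ids <- c("A", "B")
  empty <- buildCDN(matrix(0, 2, 2, dimnames = list(ids, ids)),
                    setNames(c("X", "Y"), ids), 2)
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  exportGraph(empty, tsv2, format = "edge-tsv")
  back2 <- importCDN(tsv2)
  expect_length(cdnNodes(back2), 0)

  # a 3-node path gives 2 SIF lines
  ids <- c("A", "B", "C")
  sim <- matrix(0, 3, 3, dimnames = list(ids, ids))
  sim["A", "B"] <- sim["B", "A"] <- 3; sim["B", "C"] <- sim["C", "B"] <- 3
  path3 <- buildCDN(sim, setNames(rep("X", 3), ids), 2)
  sif <- withr::local_tempfile(fileext = ".sif")
  exportGraph(path3, sif, format = "sif")
  expect_length(readLines(sif), 2)

  gml <- withr::local_tempfile(fileext = ".graphml")
  exportGraph(cdn, gml, format = "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), length(cdnNodes(cdn)))
  expect_equal(igraph::ecount(g), nrow(cdnEdges(cdn)))
})
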