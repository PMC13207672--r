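makeGrid <- function(side) {
  coords <- expand.grid(x = seq_len(side), y = seq_len(side))
  counts <- matrix(rpois(20 * side^2, 5), nrow = 20,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   sprintf("s%03d", seq_len(side^2))))
  SpatialFerro(counts, coords)
}

test_that("spot scoring shares the single-cell code path bit for bit", {
  sim <- simulateSpatial(6, seed = 3)
  sp <- normalizeLogNorm(sim$sp)
  sets <- ferroptosisGeneSets()
  st <- spotScores(sp, sets, seed = 11)
  direct <- scoreCollection(
    SummarizedExperiment::assay(sp, "lognorm"), sets,
    method = "module", seed = 11)
  expect_identical(scoreMatrix(st), scoreMatrix(direct))
})

test_that("constant spot expression scores zero on every axis", {
  coords <- expand.grid(x = 1:4, y = 1:4)
  m <- matrix(2, 10, 16, dimnames = list(sprintf("g%02d", 1:10),
                                         sprintf("s%02d", 1:16)))
  sp <- SpatialFerro(m, coords)
  SummarizedExperiment::assay(sp, "lognorm") <- m
  sc <- spotScores(sp, GeneSetCollection(list(GeneSet("a", c("g01", "g02")))),
                   seed = 1)
  expect_equal(unname(scoreMatrix(sc)[, 1]), rep(0, 16))
})

test_that("kNN graph connects interior spots to axis neighbours at k = 4", {
  set.seed(2)
  sp <- makeGrid(5)
  sp <- buildKnnGraph(sp, k = 4)
  g <- spotGraph(sp)
  cd <- SummarizedExperiment::colData(sp)
  centre <- which(cd$x == 3 & cd$y == 3)
  nb <- igraph::neighbors(g, centre)$name
  nbCoords <- cd[nb, c("x", "y")]
  d <- abs(nbCoords$x - 3) + abs(nbCoords$y - 3)
  expect_true(all(d == 1))
  expect_gte(length(nb), 4)
})

test_that("default k = 6 graph has minimum degree 6 after symmetrization", {
  set.seed(4)
  sp <- buildKnnGraph(makeGrid(8), k = 6)
  expect_true(all(igraph::degree(spotGraph(sp)) >= 6))
})

test_that("graph is invariant under rigid translation of coordinates", {
  set.seed(6)
  sp <- makeGrid(6)
  spT <- sp
  SummarizedExperiment::colData(spT)$x <-
    SummarizedExperiment::colData(spT)$x + 100
  SummarizedExperiment::colData(spT)$y <-
    SummarizedExperiment::colData(spT)$y - 7
  g1 <- spotGraph(buildKnnGraph(sp, k = 6))
  g2 <- spotGraph(buildKnnGraph(spT, k = 6))
  e1 <- igraph::as_edgelist(g1); e2 <- igraph::as_edgelist(g2)
  expect_identical(e1[order(e1[, 1], e1[, 2]), ],
                   e2[order(e2[, 1], e2[, 2]), ])
})

test_that("duplicate spot coordinates are rejected", {
  coords <- data.frame(x = c(1, 1, 2), y = c(1, 1, 2))
  counts <- matrix(1, 4, 3, dimnames = list(paste0("g", 1:4),
                                            paste0("s", 1:3)))
  expect_error(SpatialFerro(counts, coords), "unique")
})

test_that("two separated blobs cluster into their planted partition", {
  coords <- rbind(expand.grid(x = 1:4, y = 1:4),
                  expand.grid(x = 101:104, y = 1:4))
  set.seed(8)
  counts <- matrix(rpois(10 * 32, 5), nrow = 10,
                   dimnames = list(paste0("g", 1:10),
                                   sprintf("s%02d", 1:32)))
  sp <- SpatialFerro(counts, coords)
  sp <- buildKnnGraph(sp, k = 6)
  sp <- clusterGraph(sp, seed = 1)
  lab <- SummarizedExperiment::colData(sp)$cluster
  expect_equal(length(unique(lab)), 2L)
  expect_equal(length(unique(lab[1:16])), 1L)
  expect_equal(length(unique(lab[17:32])), 1L)
  expect_true(lab[1] != lab[17])
  # determinism under a fixed seed
  lab2 <- SummarizedExperiment::colData(clusterGraph(sp, seed = 1))$cluster
  expect_identical(lab, lab2)
})

test_that("tiny fully-connected graph is one cluster; labels can be injected", {
  coords <- data.frame(x = c(0, 1, 0), y = c(0, 0, 1))
  counts <- matrix(1:12, 4, 3, dimnames = list(paste0("g", 1:4),
                                               paste0("s", 1:3)))
  sp <- SpatialFerro(counts, coords)
  sp <- buildKnnGraph(sp, k = 2)
  sp <- clusterGraph(sp, seed = 1)
  expect_equal(unique(SummarizedExperiment::colData(sp)$cluster), 1L)
  spInj <- clusterGraph(sp, labels = c("a", "b", "a"))
  expect_equal(SummarizedExperiment::colData(spInj)$cluster, c(1L, 2L, 1L))
})

test_that("cluster score test needs two labels and reports medians", {
  sc <- rnorm(20)
  expect_error(clusterScoreTest(sc, rep("a", 20)), "2 labels")
  res <- clusterScoreTest(sc, rep(c("a", "b"), each = 10))
  expect_named(res$medians, c("a", "b"))
})

test_that("margin spots outscore core spots under the planted 2x gradient", {
  fa <- ferroptosisGeneSets()[["ferroptosis_all"]]
  for (s in 1:5) {
    sim <- simulateSpatial(8, gradientHigh = 4, gradientLow = 2, seed = s)
    sp <- normalizeLogNorm(sim$sp)
    sc <- moduleScore(sp, fa, seed = 1)
    reg <- SummarizedExperiment::colData(sp)$region
    expect_gt(mean(sc[reg == "margin"]), mean(sc[reg == "core"]))
  }
})
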