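test_that("significance mask applies both thresholds strictly", {
  rho <- c(0.15, -0.05, 0.20)
  p <- c(1e-5, 0.3, 0.01)
  expect_equal(unname(significanceMask(rho, p)), c(TRUE, FALSE, TRUE))
  # boundary: |rho| = 0.1 exactly fails the strict inequality
  expect_false(significanceMask(0.10, 1e-6))
  expect_false(significanceMask(0.5, 0.05))
  expect_false(significanceMask(NA_real_, 0.001))
})

test_that("correlation weights exclude the regulator and flag degenerate genes", {
  m <- toyMatrix(25, 40)
  m["g05", ] <- 3                       # zero-variance gene
  w <- correlationWeights(m, "g01")
  expect_false("g01" %in% names(w@rho))
  expect_true(is.na(w@rho[["g05"]]))
  expect_false(w@mask[["g05"]])
  # mask consistent with reported rho/p under the strict rule
  expect_equal(w@mask, significanceMask(w@rho, w@p, 0.1, 0.05))
  expect_error(correlationWeights(m, "nope"), "not detected")
})

test_that("per-pair Spearman and the vectorized weights agree", {
  m <- toyMatrix(10, 60)
  w <- correlationWeights(m, "g01")
  st <- spearmanTest(m["g01", ], m["g07", ])
  expect_equal(w@rho[["g07"]], st$estimate, tolerance = 1e-12)
  expect_equal(w@p[["g07"]], st$p_value, tolerance = 1e-10)
})

test_that("planted targets are masked and null genes spared", {
  sens <- spec <- c()
  for (s in 1:3) {
    cfg <- simConfig(nCells = 2000, rhoPlanted = 0.5, seed = s)
    sim <- simulateSingleCell(cfg)
    se <- normalizeLogNorm(sim$se)
    w <- correlationWeights(se, cfg$regulator)
    truth <- sim$truth$trueRho[names(w@mask)]
    sens <- c(sens, mean(w@mask[truth == 0.5]))
    spec <- c(spec, mean(w@mask[truth == 0]))
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(spec), 0.05)
})

test_that("KO delta equals the negated masked dot product", {
  # one masked gene with weight 0.5; raw (non-z-scored) expression 1 -> -0.5
  rho <- c(g2 = 0.5, g3 = -0.02)
  p <- c(g2 = 1e-4, g3 = 0.8)
  w <- new("CorrelationWeights", regulator = "g1", rho = rho, p = p,
           pAdj = bhAdjust(p), mask = significanceMask(rho, p),
           rhoMin = 0.1, pMax = 0.05)
  m <- matrix(1, 3, 4, dimnames = list(c("g1", "g2", "g3"),
                                       paste0("c", 1:4)))
  m["g2", ] <- c(1, 2, 0, 1)
  sets <- GeneSetCollection(list(GeneSet("axis1", "g2")))
  res <- koDeltas(m, w, sets, zscore = FALSE)
  expect_equal(unname(koDelta(res)), -0.5 * c(1, 2, 0, 1))
  expect_equal(unname(koAxisDelta(res)[, "axis1"]), -0.5 * c(1, 2, 0, 1))
  # raising a positively-correlated masked gene strictly decreases delta
  m2 <- m; m2["g2", 1] <- m2["g2", 1] + 1
  res2 <- koDeltas(m2, w, sets, zscore = FALSE)
  expect_lt(koDelta(res2)[1], koDelta(res)[1])
})

test_that("KO delta is linear in the (standardized) expression", {
  m <- toyMatrix(20, 30)
  w <- correlationWeights(m, "g01", rhoMin = 0, pMax = 1)
  sets <- GeneSetCollection(list(GeneSet("a", rownames(m)[2:6])))
  res <- koDeltas(m, w, sets, zscore = FALSE)
  masked <- names(which(w@mask))
  wts <- w@rho[masked]
  hand <- -colSums(m[masked, , drop = FALSE] * wts) / length(masked)
  expect_equal(unname(koDelta(res)), unname(hand), tolerance = 1e-12)
})

test_that("widening thresholds grows the mask monotonically", {
  m <- toyMatrix(40, 50)
  w1 <- correlationWeights(m, "g01", rhoMin = 0, pMax = 1)
  w2 <- correlationWeights(m, "g01", rhoMin = 0.1, pMax = 0.05)
  w3 <- correlationWeights(m, "g01", rhoMin = 0.3, pMax = 0.05)
  expect_true(all(w2@mask <= w1@mask))
  expect_true(all(w3@mask <= w2@mask))
  expect_equal(sum(w1@mask), length(w1@mask))  # rhoMin=0, pMax=1 keeps all
})

test_that("empty mask is an error", {
  m <- toyMatrix(10, 20)
  w <- correlationWeights(m, "g01", rhoMin = 0.999, pMax = 1e-12)
  expect_error(koDeltas(m, w, GeneSetCollection(list())), "no masked")
})

test_that("cell-type aggregation enforces the 5-cell minimum inclusively", {
  delta <- setNames(seq_len(12) / 10, paste0("c", 1:12))
  res <- new("KOResult", delta = delta,
             axisDelta = matrix(numeric(0), 0, 0),
             responder = rep(NA_character_, 12))
  labels <- c(rep("A", 5), rep("B", 4), rep("C", 3))
  tab <- aggregateByCellType(res, labels, minCells = 5)
  expect_equal(tab$cell_type, "A")
  expect_setequal(attr(tab, "excluded"), c("B", "C"))
  # single type covering all cells reproduces the global mean
  tabAll <- aggregateByCellType(res, rep("all", 12))
  expect_equal(tabAll$mean_delta, mean(delta))
})

test_that("responder quartiles split 1..8 into the expected thirds", {
  delta <- setNames(as.numeric(1:8), paste0("c", 1:8))
  res <- new("KOResult", delta = delta,
             axisDelta = matrix(numeric(0), 0, 0),
             responder = rep(NA_character_, 8))
  lab <- responderLabels(classifyResponders(res))
  expect_equal(unname(lab[delta >= 7]), c("high", "high"))
  expect_equal(unname(lab[delta <= 2]), c("low", "low"))
  expect_equal(sum(lab == "mid") + sum(lab == "high") + sum(lab == "low"), 8L)
  # monotone transform leaves labels unchanged
  res2 <- new("KOResult", delta = exp(delta),
              axisDelta = matrix(numeric(0), 0, 0),
              responder = rep(NA_character_, 8))
  expect_equal(responderLabels(classifyResponders(res2)), lab)
  expect_error(classifyResponders(
    new("KOResult", delta = delta[1:5],
        axisDelta = matrix(numeric(0), 0, 0),
        responder = rep(NA_character_, 5))), "8 observations")
  expect_error(classifyResponders(
    new("KOResult", delta = rep(1, 10),
        axisDelta = matrix(numeric(0), 0, 0),
        responder = rep(NA_character_, 10))), "degenerate")
})

test_that("a gene exclusive to high responders tops the marker table", {
  m <- toyMatrix(30, 40)
  delta <- setNames(rnorm(40), colnames(m))
  res <- classifyResponders(new("KOResult", delta = delta,
                                axisDelta = matrix(numeric(0), 0, 0),
                                responder = rep(NA_character_, 40)))
  lab <- responderLabels(res)
  m["g09", ] <- 0
  m["g09", lab == "high"] <- 5
  markers <- responderMarkers(m, res)
  expect_equal(nrow(markers), nrow(m))
  expect_equal(markers$gene[1], "g09")
  expect_equal(markers$direction[1], 1)
})

test_that("the coupled cell type shows the most negative mean KO delta", {
  for (s in 1:2) {
    cfg <- simConfig(nCells = 1500, seed = s, coupledTypes = "epithelial")
    sim <- simulateSingleCell(cfg)
    se <- normalizeLogNorm(sim$se)
    ko <- suppressWarnings(virtualKO(se, "NFE2L2", markers = FALSE))
    tab <- ko$cellTypeTable
    dEpi <- tab$mean_delta[tab$cell_type == "epithelial"]
    expect_lt(dEpi, min(tab$mean_delta[tab$cell_type != "epithelial"]))
  }
})
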