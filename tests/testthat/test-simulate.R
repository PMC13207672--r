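test_that("single-cell generator is bit-identical under a fixed seed", {
  cfg <- simConfig(nGenes = 120, nCells = 60,
                   targetSet = c("HMOX1", "NQO1"), seed = 5)
  a <- simulateSingleCell(cfg)
  b <- simulateSingleCell(cfg)
  expect_identical(SummarizedExperiment::assay(a$se, "counts"),
                   SummarizedExperiment::assay(b$se, "counts"))
  expect_identical(a$truth$latentActivity, b$truth$latentActivity)
})

test_that("generator validates its configuration", {
  expect_error(simConfig(nCells = 5), "nCells")
  expect_error(simConfig(nGenes = 5), "exceed")
  expect_error(simConfig(rhoPlanted = 1), "rhoPlanted")
  expect_error(simConfig(regulator = "HMOX1"), "target set")
  expect_error(simConfig(cellTypes = data.frame(
    name = "a", proportion = 0.7, foldChange = 2)), "sum to 1")
})

test_that("cell-type counts follow the configured proportions", {
  cfg <- simConfig(nGenes = 120, nCells = 1000, targetSet = c("HMOX1"),
                   seed = 2)
  sim <- simulateSingleCell(cfg)
  counts <- table(sim$truth$cellType)
  for (i in 1:3) {
    p <- cfg$cellTypes$proportion[i]
    expected <- 1000 * p
    expect_lt(abs(counts[[cfg$cellTypes$name[i]]] - expected),
              3 * sqrt(1000 * p * (1 - p)) + 1)
  }
})

test_that("rho = 0 plants no correlation between regulator and targets", {
  rhos <- unlist(lapply(1:6, function(s) {
    cfg <- simConfig(nCells = 2000, rhoPlanted = 0, seed = s)
    sim <- simulateSingleCell(cfg)
    m <- SummarizedExperiment::assay(normalizeLogNorm(sim$se), "lognorm")
    reg <- rank(m[cfg$regulator, ])
    vapply(cfg$targetSet, function(g) cor(reg, rank(m[g, ])), numeric(1))
  }))
  expect_lt(mean(abs(rhos)), 0.05)
})

test_that("planted Spearman correlation is recovered within 0.1", {
  err <- unlist(lapply(1:10, function(s) {
    cfg <- simConfig(nCells = 2000, rhoPlanted = 0.5, seed = s)
    sim <- simulateSingleCell(cfg)
    m <- SummarizedExperiment::assay(normalizeLogNorm(sim$se), "lognorm")
    reg <- rank(m[cfg$regulator, ])
    abs(vapply(cfg$targetSet, function(g) cor(reg, rank(m[g, ])),
               numeric(1)) - 0.5)
  }))
  expect_lt(median(err), 0.1)
})

test_that("spatial grid partitions into core, margin and stroma", {
  sim <- simulateSpatial(8, seed = 1)
  cd <- SummarizedExperiment::colData(sim$sp)
  expect_equal(ncol(sim$sp), 64L)
  expect_setequal(unique(cd$region), c("core", "margin", "stroma"))
  expect_equal(sum(table(cd$region)), 64L)
  # determinism
  sim2 <- simulateSpatial(8, seed = 1)
  expect_identical(SummarizedExperiment::assay(sim$sp, "counts"),
                   SummarizedExperiment::assay(sim2$sp, "counts"))
  expect_error(simulateSpatial(3), "nSpotsSide")
  expect_error(simulateSpatial(8, gradientHigh = 1, gradientLow = 2),
               "contrast")
})

test_that("survival generator honours censoring and null concordance", {
  sig <- prognosticSignature()
  res <- simulateSurvivalCohort(300, sig, effectScale = 1,
                                censoringRate = 0, seed = 3)
  expect_true(all(res$cohort$event == 1))
  res2 <- simulateSurvivalCohort(300, sig, effectScale = 1,
                                 censoringRate = 0, seed = 3)
  expect_identical(res$cohort, res2$cohort)
  expect_error(simulateSurvivalCohort(100, sig, censoringRate = 1), "censoring")
  # null effect: concordance near 1/2
  null <- simulateSurvivalCohort(2000, sig, effectScale = 0,
                                 censoringRate = 0.3, seed = 4)$cohort
  cidx <- concordanceIndex(riskScore(null, sig))
  expect_gte(cidx, 0.45); expect_lte(cidx, 0.55)
})

test_that("expected concordance rises monotonically with effect scale", {
  sig <- prognosticSignature()
  cs <- vapply(c(0, 0.25, 0.5, 1), function(es) {
    mean(vapply(1:3, function(s) {
      coh <- simulateSurvivalCohort(600, sig, effectScale = es,
                                    censoringRate = 0.3, seed = s)$cohort
      concordanceIndex(riskScore(coh, sig))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(cs) > 0))
})

test_that("null shuffle preserves marginals and is seed-stable", {
  m <- toyMatrix(15, 12)
  s1 <- nullShuffle(m, seed = 6)
  s2 <- nullShuffle(m, seed = 6)
  expect_identical(s1, s2)
  expect_equal(rowSums(s1), rowSums(m))
  expect_equal(sort(unname(s1[3, ])), sort(unname(m[3, ])))
  expect_false(identical(s1, m))
})

test_that("expression round-trips through MTX + TSV output", {
  cfg <- simConfig(nGenes = 120, nCells = 25, targetSet = "HMOX1", seed = 8)
  sim <- simulateSingleCell(cfg)
  d <- file.path(tempdir(), "mtx_roundtrip")
  writeExpression(sim$se, d, truth = list(note = "test"))
  back <- readExpression(d)
  expect_equal(as.matrix(SummarizedExperiment::assay(back, "counts")),
               as.matrix(SummarizedExperiment::assay(sim$se, "counts")))
  expect_equal(SummarizedExperiment::colData(back)$cell_type,
               SummarizedExperiment::colData(sim$se)$cell_type)
  expect_true(file.exists(file.path(d, "truth.json")))
})
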