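test_that("risk score is the signed sum of beta times expression", {
  model <- SignatureModel(c(g1 = 0.5, g2 = -0.25))
  coh <- data.frame(subject_id = "s1", time = 1, event = 1, g1 = 2, g2 = 4)
  expect_equal(riskScore(coh, model)$risk_score, 0)
})

test_that("absent signature genes contribute zero and are reported", {
  model <- SignatureModel(c(g1 = 0.5, g2 = -0.25))
  coh <- data.frame(subject_id = "s1", time = 1, event = 1, g1 = 2)
  scored <- riskScore(coh, model)
  expect_equal(scored$risk_score, 1)
  expect_equal(attr(scored, "missing_genes"), "g2")
  expect_error(riskScore(coh, model, missingPolicy = "fail"), "g2")
  none <- data.frame(subject_id = "s1", time = 1, event = 1, other = 5)
  expect_error(riskScore(none, model), "no signature gene")
})

test_that("median split assigns ties low and balances tie-free scores", {
  coh <- data.frame(subject_id = paste0("s", 1:4), time = 1:4, event = 1,
                    risk_score = c(1, 2, 3, 4))
  g <- stratifyMedian(coh)
  expect_equal(g$risk_group, c("low", "low", "high", "high"))
  # permuting subjects leaves per-subject groups unchanged
  g2 <- stratifyMedian(coh[c(3, 1, 4, 2), ])
  expect_equal(g2$risk_group[g2$subject_id == "s1"], "low")
  expect_equal(g2$risk_group[g2$subject_id == "s4"], "high")
  # a score equal to the median goes low
  coh3 <- data.frame(risk_score = c(1, 2, 3), time = 1, event = 1)
  expect_equal(stratifyMedian(coh3)$risk_group, c("low", "low", "high"))
  expect_error(stratifyMedian(data.frame(risk_score = c(1, 1),
                                         time = 1:2, event = 1)),
               "degenerate")
})

test_that("KM estimate matches the censoring-free closed form", {
  km <- kmEstimate(data.frame(time = 1:3, event = 1))
  expect_equal(km$surv, c(1, 2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(km$time[1], 0)
  noEvents <- kmEstimate(data.frame(time = c(2, 5), event = 0))
  expect_true(all(noEvents$surv == 1))
  expect_error(kmEstimate(data.frame(time = -1, event = 1)), "negative")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(14)
  t <- rexp(200)
  km <- kmEstimate(data.frame(time = t, event = 1))
  for (i in 2:nrow(km))
    expect_equal(km$surv[i], mean(t > km$time[i]), tolerance = 1e-12)
  expect_true(all(diff(km$surv) <= 1e-15))
})

test_that("log-rank is null on duplicated groups and matches a hand tally", {
  g <- data.frame(time = c(1, 3, 4, 7), event = c(1, 1, 0, 1))
  same <- logrankTest(g, g)
  expect_equal(unname(same$statistic), 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  # hand O/E/V tally: A events at 1,2; B events at 3,4; no censoring
  a <- data.frame(time = c(1, 2), event = 1)
  b <- data.frame(time = c(3, 4), event = 1)
  # per event time: (atRiskA, atRiskB, events) -> E_A = d*nA/n, V = hypergeom
  tally <- rbind(c(2, 2, 1), c(1, 2, 1), c(0, 2, 1), c(0, 1, 1))
  oA <- c(1, 1, 0, 0)
  eA <- tally[, 3] * tally[, 1] / (tally[, 1] + tally[, 2])
  v <- apply(tally, 1, function(r) {
    n <- r[1] + r[2]
    if (n <= 1) 0 else r[3] * (r[1] / n) * (r[2] / n) * (n - r[3]) / (n - 1)
  })
  hand <- (sum(oA) - sum(eA))^2 / sum(v)
  res <- logrankTest(a, b)
  expect_equal(unname(res$statistic), hand, tolerance = 1e-10)
  # symmetric in group exchange
  expect_equal(logrankTest(b, a)$statistic, res$statistic, tolerance = 1e-12)
  expect_error(logrankTest(a, data.frame(time = 1, event = 0)), "event")
})

test_that("concordance handles closed-form pairs and ties", {
  one <- data.frame(time = c(1, 2), event = 1, risk_score = c(2, 1))
  expect_equal(concordanceIndex(one), 1)
  tied <- data.frame(time = c(1, 2, 3), event = 1, risk_score = 1:3 * 0 + 2)
  expect_equal(concordanceIndex(tied), 0.5)
  censored <- data.frame(time = c(1, 2), event = 0, risk_score = c(2, 1))
  expect_error(concordanceIndex(censored), "comparable")
})

test_that("concordance is transform-invariant and matches pair enumeration", {
  set.seed(31)
  coh <- data.frame(time = rexp(60), event = rbinom(60, 1, 0.7),
                    risk_score = rnorm(60))
  c1 <- concordanceIndex(coh)
  coh2 <- coh; coh2$risk_score <- exp(coh$risk_score)   # strictly increasing
  expect_equal(concordanceIndex(coh2), c1, tolerance = 1e-12)
  expect_equal(c1, bruteCIndex(coh$time, coh$event, coh$risk_score),
               tolerance = 1e-12)
})

test_that("stratification pipeline separates a strong simulated effect", {
  sig <- prognosticSignature()
  coh <- simulateSurvivalCohort(400, sig, effectScale = 1,
                                censoringRate = 0.3, seed = 9)$cohort
  res <- survivalStratification(coh, sig)
  expect_gt(res$cindex, 0.6)
  expect_lt(res$logrank$p_value, 0.01)
  expect_equal(sort(unique(res$cohort$risk_group)), c("high", "low"))
  expect_equal(res$missing_genes, character(0))
})
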