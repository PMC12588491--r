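test_that("simulation is reproducible and honors empty sources", {
  cfg <- smallMixedConfig()
  t1 <- simulatePopulation(cfg)
  t2 <- simulatePopulation(cfg)
  expect_identical(t1$A@values, t2$A@values) # same seed, bit-identical
  expect_identical(t1$B@mask, t2$B@mask)

  cfg0 <- smallMixedConfig(nA = 0, nB = 0)
  t0 <- simulatePopulation(cfg0)
  expect_equal(nRecords(t0$A), 0)
  expect_identical(attributeNames(t0$A), c("age", "sex", "x1", "cnt"))
})

test_that("zero loadings produce independent attributes; thresholds at 0 are symmetric", {
  cfg <- simulationConfig(
    nRecords = c(S = 20000), latentDim = 2,
    attrs = list(simAttr("u", "real", c(0, 0), noise = 1),
                 simAttr("v", "real", c(0, 0), noise = 1),
                 simAttr("b", "ordered_categorical", c(0, 0), noise = 1,
                         thresholds = 0, levels = c("neg", "pos"))),
    sourceBlocks = list(S = c("u", "v", "b")), common = "u", seed = 5)
  tab <- simulatePopulation(cfg)$S
  expect_lt(abs(cor(tab@values[, "u"], tab@values[, "v"],
                    method = "spearman")), 0.02)
  expect_lt(abs(mean(tab@values[, "b"] == 2) - 0.5), 0.02)
})

test_that("simulated values respect their declared domains", {
  tabs <- simulatePopulation(cohortConfig(nA = 300, nB = 300))
  sch <- simSchema(cohortConfig(nA = 300, nB = 300))
  dts <- attributeDtypes(sch)
  for (tb in tabs) {
    for (a in attributeNames(tb)) {
      x <- tb@values[tb@mask[, a], a]
      switch(dts[[a]],
             positive = expect_true(all(x > 0)),
             count = expect_true(all(x >= 0 & x == floor(x))),
             categorical = ,
             ordered_categorical = expect_true(all(
               x %in% seq_along(schemaLevels(sch, a)))),
             expect_true(all(is.finite(x))))
    }
  }
})

test_that("exact Gaussian conditionals follow the closed form E[Y|X=x] = rho x", {
  cfg <- bivariateConfig(rho = 0.8)
  oracle <- latentOracle(cfg)
  for (x in c(-1.5, 0, 0.7)) {
    tc <- trueConditional(oracle, "Y", list(X = x))
    expect_identical(tc$method, "exact")
    expect_equal(tc$mean, 0.8 * x, tolerance = 1e-10)
    expect_equal(tc$sd, sqrt(1 - 0.8^2), tolerance = 1e-10)
  }
})

test_that("importance-sampling conditionals agree with exact and empirical answers", {
  cfg <- bivariateConfig(rho = 0.8, n = 20000, seed = 3)
  oracle <- latentOracle(cfg)
  ex <- trueConditional(oracle, "Y", list(X = 1))
  mc <- trueConditional(oracle, "Y", list(X = 1), nMC = 40000, seed = 8,
                        method = "mc")
  expect_lt(abs(mc$mean - ex$mean), 3 * mc$se + 0.02)
  # conditioning on nothing reproduces the marginal of the simulator
  tab <- simulatePopulation(cfg)$S
  marg <- trueConditional(oracle, "Y", list(), method = "mc", nMC = 30000)
  expect_lt(abs(marg$mean - mean(tab@values[, "Y"])), 0.03)
  # an (essentially) impossible conditioning event errors with a diagnostic
  expect_error(trueConditional(oracle, "Y", list(X = 40), nMC = 2000,
                               method = "mc"), "probability")
})

test_that("the linkage design enforces Y independent of X given Z", {
  oracle <- latentOracle(linkageConfig())
  pz <- trueConditional(oracle, "Y", list(Z = 0.8), nMC = 60000, seed = 2,
                        method = "mc")
  pzx <- trueConditional(oracle, "Y", list(Z = 0.8, X = -1.2), nMC = 60000,
                         seed = 3, method = "mc")
  expect_lt(abs(pz$mean - pzx$mean), 3 * (pz$se + pzx$se) + 0.02)
})

test_that("discrete chain oracle marginalizes exactly and by simulation", {
  oracle <- discreteChainOracle(pX1 = 0.5, pZ1gX = c(0.3, 0.8),
                                pY1gZ = c(0.2, 0.9))
  # P(Y=1|X=1) = 0.8 * 0.9 + 0.2 * 0.2 = 0.76 by enumeration
  ex <- trueConditional(oracle, "Y", list(X = 1))
  expect_identical(ex$method, "exact")
  expect_equal(ex$mean, 0.76, tolerance = 1e-12)
  mc <- trueConditional(oracle, "Y", list(X = 1), nMC = 40000, seed = 4,
                        method = "mc")
  expect_lt(abs(mc$mean - 0.76), 3 * mc$se)
  # degenerate conditioning errors
  expect_error(trueConditional(discreteChainOracle(
    pX1 = 1, pZ1gX = c(0.3, 0.8), pY1gZ = c(0.2, 0.9)),
    "Y", list(X = 0)), "probability")
})

test_that("mixed-type conditional summaries come back in the right shape", {
  cfg <- smallMixedConfig(nA = 10, nB = 10)
  oracle <- latentOracle(cfg)
  lv <- trueConditional(oracle, "ord", list(x1 = 1), nMC = 20000, seed = 6)
  expect_named(lv$probs, c("lo", "mid", "hi"))
  expect_equal(sum(lv$probs), 1, tolerance = 1e-9)
  ct <- trueConditional(oracle, "cnt", list(x1 = 0.5), nMC = 20000, seed = 6)
  expect_true(ct$mean > 0 && ct$sd > 0)
})
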