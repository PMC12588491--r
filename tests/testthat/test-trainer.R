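test_that("mask selection targets only observed cells and honors the floor rule", {
  set.seed(8)
  mask <- matrix(runif(200) < 0.7, 20, 10)
  mask[3, ] <- FALSE # a record with nothing observed
  mk <- maskRecords(mask, 0.5, seed = 1)
  expect_true(all(mk$targetMask[!mask] == FALSE)) # never structural cells
  expect_true(all(!(mk$inputMask & mk$targetMask)))
  expect_true(all((mk$inputMask | mk$targetMask) == mask))
  expect_identical(mk$skipped, 3L)

  # maskRate = 1: every observed cell is a target, input empty
  mk1 <- maskRecords(mask, 1, seed = 2)
  expect_identical(mk1$targetMask, mask)
  expect_false(any(mk1$inputMask))

  # vanishing rate with the forced floor: exactly one target per record
  mk0 <- maskRecords(mask, 1e-9, seed = 3)
  nT <- rowSums(mk0$targetMask)
  expect_true(all(nT[rowSums(mask) > 0] == 1))
  expect_error(maskRecords(mask, 0), "maskRate")
})

test_that("the empirical masked fraction matches the binomial rate", {
  set.seed(11)
  mask <- matrix(TRUE, 2000, 50) # 1e5 observed cells
  rate <- 0.37
  mk <- maskRecords(mask, rate, seed = 5)
  n <- length(mask)
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(mean(mk$targetMask) - rate), 3 * se + 1 / nrow(mask))
  # a rate range draws a different rate per record
  mkr <- maskRecords(mask, c(0.1, 0.9), seed = 6)
  perRecord <- rowMeans(mkr$targetMask)
  expect_gt(sd(perRecord), sd(rowMeans(mk$targetMask)) * 2)
})

test_that("zero epochs returns the initialization; training reduces the loss", {
  cfg <- smallMixedConfig(nA = 400, nB = 400, seed = 9)
  corpus <- simCorpus(cfg)
  nc <- networkConfig(embedDim = 16, heads = 2, ffDim = 24, seed = 12)
  m0 <- trainModel(corpus, nc,
                   trainingConfig(epochsStage1 = 0, epochsStage2 = 0,
                                  seed = 1))
  expect_identical(HetTabGen:::flattenParams(m0@params),
                   HetTabGen:::flattenParams(
                     HetTabGen:::netInit(corpusSchema(corpus), nc)))
  expect_equal(nrow(m0@history), 0)
  expect_false(any(m0@trainedAttributes))

  l0 <- evaluateLoss(m0, corpus, seed = 42)
  m1 <- trainModel(corpus, nc,
                   trainingConfig(epochsStage1 = 2, epochsStage2 = 6,
                                  batchSize = 256, seed = 1))
  l1 <- evaluateLoss(m1, corpus, seed = 42)
  expect_lt(l1, l0)
  # history records per-epoch losses for both stages
  expect_setequal(unique(m1@history$stage), c(1, 2))
  expect_true(all(is.finite(m1@history$loss)))
  expect_true(all(m1@trainedAttributes))
})

test_that("the trainer refuses corpora containing holdout records", {
  cfg <- smallMixedConfig(nA = 100, nB = 100)
  corpus <- concatSources(simulatePopulation(cfg), simSchema(cfg))
  sp <- splitHoldout(corpus, 0.2, seed = 1)
  hold <- HetTabGen:::withStandardizers(
    sp$holdout, corpusStandardizers(fitStandardizers(sp$train)))
  expect_error(trainModel(hold, networkConfig(embedDim = 8, heads = 2)),
               "holdout")
})

test_that("training is reproducible under its seed", {
  corpus <- getSmallCorpus()
  nc <- networkConfig(embedDim = 8, heads = 2, ffDim = 12, seed = 4)
  tc <- trainingConfig(epochsStage1 = 1, epochsStage2 = 2, batchSize = 64,
                       seed = 77)
  mA <- trainModel(corpus, nc, tc)
  mB <- trainModel(corpus, nc, tc)
  expect_identical(HetTabGen:::flattenParams(mA@params),
                   HetTabGen:::flattenParams(mB@params))
  expect_identical(mA@history$loss, mB@history$loss)
})

test_that("the network learns a non-linear conditional dependence", {
  # y = x^2 + noise is invisible to a covariance summary but not to the model
  set.seed(14)
  n <- 2000
  x <- rnorm(n)
  df <- data.frame(x = x, y = x^2 + rnorm(n, sd = 0.3))
  sch <- modelSchema(list(list(name = "x", dtype = "real", sources = "S"),
                          list(name = "y", dtype = "real", sources = "S")))
  corpus <- fitStandardizers(concatSources(list(sourceTable("S", df, sch)),
                                           sch))
  model <- trainModel(corpus,
                      networkConfig(embedDim = 16, heads = 2, ffDim = 32,
                                    seed = 2),
                      trainingConfig(epochsStage1 = 0, epochsStage2 = 25,
                                     batchSize = 512, seed = 3))
  modes <- vapply(c(-2, -1, 0, 1, 2), function(v)
    impute(model, list(x = v), "y")$y$mode, 0)
  # monotone on each branch of the parabola, and curved
  expect_gt(modes[1], modes[2])
  expect_gt(modes[2], modes[3])
  expect_lt(modes[3], modes[4])
  expect_lt(modes[4], modes[5])
  expect_equal(modes[3], 0, tolerance = 0.35)
  expect_gt(modes[1], 2.5)
})
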