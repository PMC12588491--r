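test_that("histogram overlap hits its closed-form anchors", {
  x <- rnorm(500)
  expect_equal(univariateOverlap(x, x), 1)
  expect_equal(univariateOverlap(runif(300), runif(300) + 10), 0)
  # p = [0.5, 0.5] vs q = [1, 0] over two shared bins -> 0.5
  expect_equal(univariateOverlap(c(0, 1), c(0, 0.01), bins = 2), 0.5)
  # categorical samples use levels as bins
  expect_equal(univariateOverlap(c("a", "a", "b", "b"), c("a", "a", "a", "a")),
               0.5)
  expect_error(univariateOverlap(numeric(0), x), "empty")
})

test_that("histogram overlap is symmetric and order-invariant", {
  set.seed(3)
  for (i in 1:5) {
    a <- rnorm(200, sd = runif(1, 0.5, 2))
    b <- rnorm(300, mean = runif(1, -1, 1))
    o1 <- univariateOverlap(a, b, bins = 15)
    expect_equal(o1, univariateOverlap(b, a, bins = 15))
    expect_equal(o1, univariateOverlap(sample(a), sample(b), bins = 15))
    expect_true(o1 >= 0 && o1 <= 1)
  }
})

test_that("external concordance matches the z-score definition and normal-overlap closed form", {
  set.seed(6)
  x <- rnorm(4000, mean = 2, sd = 1.5)
  same <- externalCompare(x, mean(x), sd(x))
  expect_equal(same$z, 0)
  expect_equal(same$overlap, 1, tolerance = 1e-9)
  # a shift of exactly one external SD gives |z| = 1
  shift <- externalCompare(x, mean(x) - sd(x), sd(x))
  expect_equal(shift$z, 1, tolerance = 1e-9)
  expect_error(externalCompare(x, 0, 0), "SD")
  expect_error(externalCompare(rep(1, 5), 0, 1), "degenerate")

  # equal-SD densities 2 sigma apart overlap by 2 Phi(-1)
  expect_equal(normalOverlap(0, 1, 2, 1), 2 * pnorm(-1), tolerance = 1e-12)
  # general case against a numerical-integration oracle
  numOverlap <- function(m1, s1, m2, s2)
    integrate(function(t) pmin(dnorm(t, m1, s1), dnorm(t, m2, s2)),
              -Inf, Inf, rel.tol = 1e-10)$value
  cases <- list(c(0, 1, 2, 1), c(0, 1, 1, 2), c(-1, 0.5, 2, 1.7),
                c(0, 3, 0.2, 0.4))
  for (cs in cases)
    expect_equal(normalOverlap(cs[1], cs[2], cs[3], cs[4]),
                 numOverlap(cs[1], cs[2], cs[3], cs[4]), tolerance = 1e-3)
  # continuity: overlap approaches 1 as the summaries converge
  ovs <- vapply(c(1, 0.5, 0.1, 0.01), function(d)
    normalOverlap(0, 1, d, 1 + d), 0)
  expect_true(all(diff(ovs) > 0))
  expect_gt(ovs[4], 0.99)
})

test_that("mean/mode baselines read off the training statistics", {
  sch <- modelSchema(list(
    list(name = "r", dtype = "real", sources = "A"),
    list(name = "c", dtype = "categorical", levels = c("A", "B", "C"),
         sources = "A")))
  df <- data.frame(r = c(1, 2, 3), c = c("B", "B", "A"))
  corpus <- concatSources(list(sourceTable("A", df, sch)), sch)
  expect_equal(baselineImpute(corpus, "r"), 2)
  expect_equal(baselineImpute(corpus, "c"), 2) # index of majority level "B"
})

test_that("machine-learning efficiency is exact on identical data and collapses on shuffled targets", {
  fx <- getRegressionFixture()
  real <- fx$real
  testIdx <- HetTabGen:::withSeed(5, sample(nrow(real), round(0.25 * nrow(real))))
  trainReal <- real[-testIdx, ]
  # synthetic identical to the real training rows: identical fits
  r2same <- suppressWarnings(mlEfficiency(real, trainReal, "y", seed = 5))
  expect_equal(r2same[["r2_synthetic_only"]], r2same[["r2_real"]],
               tolerance = 1e-12)
  # permuting the target severs the signal
  shuf <- trainReal
  shuf$y <- HetTabGen:::withSeed(9, sample(shuf$y))
  r2shuf <- suppressWarnings(mlEfficiency(real, shuf, "y", seed = 5))
  expect_lte(r2shuf[["r2_synthetic_only"]], 0.05)
  expect_error(mlEfficiency(real, trainReal[, -1], "y"), "target")
})

test_that("imputation error report mirrors the per-dtype benchmark layout", {
  fx <- getCohortFixture()
  rep <- fixture("cohortReport", function()
    imputationErrorReport(fx$model, fx$holdout, fx$train, kPredictors = 10,
                          maxRecords = 250, seed = 7))
  per <- reportAttributes(rep)
  agg <- reportAggregate(rep)
  expect_true(all(is.finite(per$value)))
  acc <- per$value[grepl("accuracy", per$metric)]
  expect_true(all(acc >= 0 & acc <= 1))
  expect_true(all(c("abs_std_error", "baseline_abs_std_error",
                    "macro_accuracy", "baseline_macro_accuracy") %in%
                    agg$metric))
  # every dtype present in the schema is evaluated
  expect_setequal(unique(per$dtype),
                  unique(attributeDtypes(fx$model@schema)))
  # mean imputation of a Gaussian attribute has E|X - mu|/sigma = sqrt(2/pi)
  realBase <- agg$value[agg$dtype == "real" &
                          agg$metric == "baseline_abs_std_error"]
  expect_equal(realBase, sqrt(2 / pi), tolerance = 0.06)
  expect_error(imputationErrorReport(fx$model, fx$train, fx$train),
               "holdout")
})

test_that("bivariate conditional overlap detects training and non-linear structure", {
  bl <- getBivariateModel()
  repT <- bivariateReport(bl$model, bl$corpus, list(c("X", "Y")),
                          xBins = 4, nDraw = 400, seed = 11)
  ovT <- reportPairs(repT)$value
  expect_gt(ovT, 0.75)
  # an untrained network does distinctly worse on the same comparison
  m0 <- trainModel(bl$corpus, bl$model@netConfig,
                   trainingConfig(epochsStage1 = 0, epochsStage2 = 0,
                                  seed = 1))
  rep0 <- bivariateReport(m0, bl$corpus, list(c("X", "Y")),
                          xBins = 4, nDraw = 400, seed = 11)
  expect_gt(ovT, reportPairs(rep0)$value)
  # a pair never jointly observed cannot be evaluated
  lk <- getLinkageFixture()
  expect_error(bivariateReport(lk$model, lk$corpus, list(c("X", "Y"))),
               "jointly")
})

test_that("scenario checks report direction and magnitude between personas", {
  fx <- getCohortFixture()
  model <- fx$model
  base <- list(age = 45, sex = "M", bmi = 24)
  personas <- list(
    active = c(base, list(smoke = "never", exer = "high")),
    sedentary = c(base, list(smoke = "daily", exer = "low")))
  # the generator couples daily smoking (z3 high) with more steps (z3 high)
  exp1 <- data.frame(target = "steps", higher = "sedentary",
                     lower = "active")
  out <- scenarioCheck(model, personas, exp1)
  expect_true(out$pass[1])
  expect_gt(out$delta[1], 0)
  # identical personas: delta exactly 0, strict expectations fail
  same <- scenarioCheck(model, list(p1 = base, p2 = base),
                        data.frame(target = "steps", higher = "p1",
                                   lower = "p2"))
  expect_identical(same$delta, 0)
  expect_false(same$pass)
})
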