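twoSourceSchema <- function() {
  modelSchema(list(
    list(name = "age", dtype = "real", sources = c("A", "B")),
    list(name = "sex", dtype = "categorical", levels = c("M", "F"),
         sources = c("A", "B")),
    list(name = "X", dtype = "real", sources = "A"),
    list(name = "Y", dtype = "real", sources = "B")))
}

test_that("row-wise concatenation unions attributes and blanks out-of-block cells", {
  sch <- twoSourceSchema()
  ta <- sourceTable("A", data.frame(age = c(30, 41, 52), sex = c("M", "F", "M"),
                                    X = c(1, 2, 3)), sch)
  tb <- sourceTable("B", data.frame(age = c(25, 60), sex = c("F", "F"),
                                    Y = c(9, 8)), sch)
  corpus <- concatSources(list(ta, tb), sch)
  expect_equal(nRecords(corpus), 5)
  expect_identical(attributeNames(corpus), c("age", "sex", "X", "Y"))
  vals <- corpusValues(corpus)
  mask <- corpusMask(corpus)
  expect_true(all(is.na(vals[4:5, "X"])))
  expect_true(all(is.na(vals[1:3, "Y"])))
  expect_true(all(mask[1:3, c("age", "sex", "X")]))
  # observed cells preserved bit-exactly
  expect_identical(vals[1:3, "X"], c(1, 2, 3))
  expect_identical(vals[4:5, "Y"], c(9, 8))
  expect_identical(sourceLabels(corpus), c("A", "A", "A", "B", "B"))

  # single source: corpus is the source
  one <- concatSources(list(ta), sch)
  expect_equal(nRecords(one), 3)
  expect_identical(corpusValues(one)[, c("age", "sex", "X")],
                   unname(ta@values)[, ] |> `colnames<-`(c("age", "sex", "X")))
})

test_that("conflicting dtypes across sources are rejected", {
  sch <- twoSourceSchema()
  ta <- sourceTable("A", data.frame(age = c(30, 41), sex = c("M", "F"),
                                    X = c(1, 2)), sch)
  tbBad <- new("SourceTable", label = "B",
               values = matrix(c(1, 2), 2, 1, dimnames = list(NULL, "age")),
               mask = matrix(TRUE, 2, 1), dtypes = c(age = "categorical"))
  expect_error(concatSources(list(ta, tbBad), sch), "declared as")
  # and out-of-domain values are rejected at construction
  expect_error(sourceTable("A", data.frame(age = 1, sex = "Q", X = 0), sch),
               "not in levels")
})

test_that("stratified holdout is disjoint, exhaustive, seeded, and cell-accurate", {
  cfg <- cohortConfig(nA = 800, nB = 800, seed = 19)
  corpus <- concatSources(simulatePopulation(cfg), simSchema(cfg))
  sp <- splitHoldout(corpus, 0.10, strata = c("sex", "age"), seed = 1)
  expect_equal(nRecords(sp$train) + nRecords(sp$holdout), nRecords(corpus))
  expect_true(all(corpusRoles(sp$holdout) == "holdout"))
  expect_true(all(corpusRoles(sp$train) == "train"))
  # reproducible under the seed
  sp2 <- splitHoldout(corpus, 0.10, strata = c("sex", "age"), seed = 1)
  expect_identical(corpusValues(sp$holdout), corpusValues(sp2$holdout))

  # per sex x age-decade cell the holdout count is round(0.1 * cell size)
  vals <- corpusValues(corpus)
  cells <- paste(sourceLabels(corpus), vals[, "sex"],
                 floor(vals[, "age"] / 10) * 10)
  hvals <- corpusValues(sp$holdout)
  hcells <- paste(sourceLabels(sp$holdout), hvals[, "sex"],
                  floor(hvals[, "age"] / 10) * 10)
  for (cl in unique(cells)) {
    nCell <- sum(cells == cl)
    expect_lte(abs(sum(hcells == cl) - 0.10 * nCell), 1)
  }

  # fraction 0: empty holdout, train is the corpus
  sp0 <- splitHoldout(corpus, 0, seed = 1)
  expect_equal(nRecords(sp0$holdout), 0)
  expect_equal(nRecords(sp0$train), nRecords(corpus))
  expect_error(splitHoldout(corpus, 1.2), "fraction")
})

test_that("a source without the stratum attribute falls back with a warning", {
  corpus <- getSmallCorpus() # 'ord' exists only in source B
  expect_warning(splitHoldout(corpus, 0.2, strata = "ord", seed = 3),
                 "entirely missing")
})

test_that("record adjustment up-samples with replacement and never fabricates", {
  cfg <- bivariateConfig(n = 897, seed = 2)
  corpus <- concatSources(simulatePopulation(cfg), simSchema(cfg))
  up <- adjustRecords(corpus, c(S = 18000), seed = 4)
  expect_equal(nRecords(up), 18000)
  orig <- apply(corpusValues(corpus), 1, paste, collapse = "|")
  expect_true(all(apply(corpusValues(up), 1, paste, collapse = "|") %in% orig))

  down <- adjustRecords(corpus, c(S = 100), seed = 4)
  expect_equal(nRecords(down), 100)
  expect_false(any(duplicated(corpusValues(down))))

  same <- adjustRecords(corpus, c(S = 897), seed = 4)
  expect_equal(nRecords(same), 897)
  gone <- adjustRecords(corpus, c(S = 0), seed = 4)
  expect_equal(nRecords(gone), 0)
  expect_error(adjustRecords(corpus, c(Nope = 5)), "unknown source")
})

test_that("standardizers follow the typed closed forms and invert exactly", {
  sch <- modelSchema(list(
    list(name = "r", dtype = "real", sources = "A"),
    list(name = "p", dtype = "positive", sources = "A"),
    list(name = "k", dtype = "count", sources = "A")))
  df <- data.frame(r = c(1, 2, 3), p = c(exp(1), exp(2), exp(1.5)),
                   k = c(0, 3, 7))
  corpus <- fitStandardizers(concatSources(list(sourceTable("A", df, sch)),
                                           sch))
  std <- corpusStandardizers(corpus)
  expect_equal(std$r$mean, 2)
  expect_equal(std$r$sd, sd(c(1, 2, 3)))
  expect_equal(std$p$logMean, 1.5)
  # standardize-then-invert is the identity on observed values
  for (a in c("r", "p", "k")) {
    x <- df[[a]]
    expect_equal(unstandardizeValue(std[[a]], standardizeValue(std[[a]], x)),
                 x, tolerance = 1e-12)
  }
})

test_that("degenerate standardizer inputs are flagged", {
  sch <- modelSchema(list(list(name = "r", dtype = "real", sources = "A"),
                          list(name = "p", dtype = "positive",
                               sources = "A")))
  flat <- data.frame(r = c(5, 5, 5), p = c(1, 2, 3))
  corpus <- concatSources(list(sourceTable("A", flat, sch)), sch)
  expect_warning(fitStandardizers(corpus), "zero variance")
  # a non-positive value smuggled past construction is caught at fitting
  bad <- new("SourceTable", label = "A",
             values = matrix(c(1, 2, 3, 2, -1, 4), 3, 2,
                             dimnames = list(NULL, c("r", "p"))),
             mask = matrix(TRUE, 3, 2), dtypes = c(r = "real", p = "positive"))
  expect_error(fitStandardizers(concatSources(list(bad), sch)),
               "non-positive")
})
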