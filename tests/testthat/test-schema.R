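test_that("schema construction validates types, domains, and linkage", {
  sch <- modelSchema(list(
    list(name = "age", dtype = "positive", sources = c("A", "B")),
    list(name = "sex", dtype = "categorical", levels = c("M", "F"),
         sources = c("A", "B")),
    list(name = "sbp", dtype = "real", sources = "A",
         field_category = "Vital signs", units = "mmHg")))
  expect_s4_class(sch, "ModelSchema")
  expect_identical(attributeNames(sch), c("age", "sex", "sbp"))
  expect_identical(commonAttributes(sch), c("age", "sex"))
  expect_identical(schemaLevels(sch, "sex"), c("M", "F"))
  expect_null(schemaLevels(sch, "sbp"))

  expect_error(modelSchema(list(
    list(name = "a", dtype = "float", sources = "A"))), "unknown dtype")
  expect_error(modelSchema(list(
    list(name = "a", dtype = "real", sources = "A"),
    list(name = "a", dtype = "real", sources = "A"))), "duplicate")
  expect_error(modelSchema(list(
    list(name = "a", dtype = "ordered_categorical", sources = "A"))),
    "levels")
  # positive bounds must be > 0
  expect_error(modelSchema(list(
    list(name = "a", dtype = "positive", bounds = c(-1, 5),
         sources = "A"))), "positive")
  # two sources with no common attribute are not linked
  expect_error(modelSchema(list(
    list(name = "a", dtype = "real", sources = "A"),
    list(name = "b", dtype = "real", sources = "B"))), "linked")
})

test_that("schema round-trips losslessly through YAML and JSON", {
  sch <- simSchema(smallMixedConfig())
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    saveSchema(sch, path)
    back <- loadSchema(path)
    expect_identical(attributeNames(back), attributeNames(sch))
    expect_identical(attributeDtypes(back), attributeDtypes(sch))
    for (a in attributeNames(sch)) {
      expect_identical(schemaLevels(back, a), schemaLevels(sch, a))
      expect_identical(sort(schemaSources(back, a)),
                       sort(schemaSources(sch, a)))
    }
  }
  # minimal two-attribute file
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(attributes = list(
    list(name = "age", dtype = "positive", sources = list("A")),
    list(name = "sex", dtype = "categorical", levels = list("M", "F"),
         sources = list("A")))), path)
  mini <- loadSchema(path)
  expect_equal(length(attributeNames(mini)), 2)
})

test_that("attribute screening drops high-missingness and independent attributes but never common ones", {
  set.seed(4)
  n <- 400
  z <- rnorm(n)
  df <- data.frame(age = exp(0.2 * z + 4), link = z + rnorm(n, sd = 0.1),
                   twin = z + rnorm(n, sd = 0.3), noise = rnorm(n),
                   ghost = rep(NA_real_, n))
  sch <- modelSchema(list(
    list(name = "age", dtype = "positive", sources = c("A", "B")),
    list(name = "link", dtype = "real", sources = "A"),
    list(name = "twin", dtype = "real", sources = "A"),
    list(name = "noise", dtype = "real", sources = "A"),
    list(name = "ghost", dtype = "real", sources = "A")))
  ghostless <- df
  corpus <- concatSources(list(sourceTable("A", df, sch)), sch)

  expect_error(selectAttributes(sch, corpus, maxMissingRate = 2),
               "thresholds")
  # no-op thresholds keep everything
  all1 <- selectAttributes(sch, corpus, 1.0, 0.0)
  expect_identical(attributeNames(all1), attributeNames(sch))
  # fully missing attribute is dropped at any real threshold
  sel <- selectAttributes(sch, corpus, maxMissingRate = 0.2)
  expect_false("ghost" %in% attributeNames(sel))
  # the independent attribute is dropped, its correlated twin kept
  sel2 <- selectAttributes(sch, corpus, 1.0, minDependence = 0.1)
  expect_false("noise" %in% attributeNames(sel2))
  expect_true(all(c("link", "twin") %in% attributeNames(sel2)))
  # Spearman oracle agrees that the twin is dependent and noise is not
  expect_gt(abs(cor(df$twin, df$link, method = "spearman")), 0.1)
  expect_lt(abs(cor(df$noise, df$link, method = "spearman")), 0.1)
  # common attributes survive even when they would otherwise fail
  selC <- selectAttributes(sch, corpus, maxMissingRate = 0, minDependence = 1)
  expect_true("age" %in% attributeNames(selC))
})

test_that("screening is monotone in the missing-rate threshold", {
  corpus <- getSmallCorpus()
  sch <- corpusSchema(corpus)
  kept <- lapply(c(0.02, 0.08, 0.5, 1.0), function(r)
    attributeNames(selectAttributes(sch, corpus, maxMissingRate = r)))
  for (i in seq_len(length(kept) - 1))
    expect_true(all(kept[[i]] %in% kept[[i + 1]]))
})
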