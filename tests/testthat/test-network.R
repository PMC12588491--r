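test_that("typed negative log-likelihoods match their closed forms", {
  # categorical with all mass on the true level scores zero
  expect_equal(typedNLL(list(probs = c(a = 1, b = 0)), "a", "categorical"), 0)
  expect_equal(typedNLL(list(probs = c(0.25, 0.75)), 2, "ordered_categorical"),
               -log(0.75))
  # Gaussian evaluated at its own mean: 0.5 log(2 pi sigma^2)
  for (s in c(0.5, 1, 2.3))
    expect_equal(typedNLL(list(mean = 1.7, sd = s), 1.7, "real"),
                 0.5 * log(2 * pi * s^2), tolerance = 1e-12)
  # positive works on the log of the value
  expect_equal(typedNLL(list(mean = 0, sd = 1), exp(0), "positive"),
               0.5 * log(2 * pi), tolerance = 1e-12)
  # Poisson lambda = 1, k = 0 -> NLL exactly 1
  expect_equal(typedNLL(list(rate = 1), 0, "count"), 1)
  expect_error(typedNLL(list(mean = 0, sd = 0), 0, "real"), "SD")
  expect_error(typedNLL(list(rate = -2), 1, "count"), "rate")
  expect_error(typedNLL(list(probs = c(0.5, 0.4)), 1, "categorical"), "sum")
})

test_that("distribution modes follow the typed closed forms bit-exactly", {
  expect_identical(modeOf(list(mean = 5.2, sd = 1.1), "real"), 5.2)
  # log-normal mode exp(mu - sigma^2)
  expect_identical(modeOf(list(mean = 0, sd = 1), "positive"), exp(-1))
  # Poisson mode floor(lambda); integer rate stays put
  expect_identical(modeOf(list(rate = 3.7), "count"), 3)
  expect_identical(modeOf(list(rate = 4), "count"), 4)
  # argmax level, ties resolved to the lowest index
  expect_identical(modeOf(list(probs = c(x = 0.4, y = 0.4, z = 0.2)),
                          "categorical"), "x")
  # de-standardization applies the stored transform
  std <- list(dtype = "real", mean = 10, sd = 2)
  expect_identical(modeOf(list(mean = 1.5, sd = 1), "real", std), 13)
  stdP <- list(dtype = "positive", logMean = 1, logSd = 0.5)
  expect_equal(modeOf(list(mean = 0, sd = 1), "positive", stdP),
               exp(1 - 0.25), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences for both decoding modes", {
  corpus <- getSmallCorpus()
  schema <- corpusSchema(corpus)
  std <- corpusStandardizers(corpus)
  dm <- HetTabGen:::designMatrices(corpus)
  idx <- 1:7
  set.seed(1)
  mk <- maskRecords(dm$OBS[idx, ], 0.5)
  for (passes in c(1L, 2L)) {
    nc <- networkConfig(embedDim = 8, encLayers = 1, decLayers = 1,
                        heads = 2, ffDim = 12, passes = passes, seed = 3)
    par <- HetTabGen:::netInit(schema, nc)
    f <- function(vec) {
      p <- HetTabGen:::unflattenParams(vec, par)
      HetTabGen:::netLossGrad(p, dm$XEMB[idx, ], dm$YTGT[idx, ],
                              mk$inputMask, mk$targetMask, nc, dm$dts,
                              std = std, wantGrad = FALSE)$loss
    }
    res <- HetTabGen:::netLossGrad(par, dm$XEMB[idx, ], dm$YTGT[idx, ],
                                   mk$inputMask, mk$targetMask, nc, dm$dts,
                                   std = std)
    v0 <- HetTabGen:::flattenParams(par)
    g <- HetTabGen:::flattenParams(res$grads)
    expect_length(g, length(v0))
    set.seed(5)
    sel <- sample(length(v0), 80)
    eps <- 1e-5
    num <- vapply(sel, function(i) {
      vp <- v0; vp[i] <- vp[i] + eps
      vm <- v0; vm[i] <- vm[i] - eps
      (f(vp) - f(vm)) / (2 * eps)
    }, 0)
    relErr <- abs(num - g[sel]) / pmax(abs(num), abs(g[sel]), 1e-4)
    expect_lt(max(relErr), 1e-4)
  }
})

test_that("tokenization emits one token per observed attribute, none for missing", {
  model <- getBivariateModel()$model
  toks <- embedRecord(model, list(X = 0.4))
  expect_length(toks, 1)
  expect_identical(toks[[1]]$name, "X")
  expect_length(embedRecord(model, list()), 0) # fully missing is valid
  # identical observed values give identical token sequences
  t2 <- embedRecord(model, list(X = 0.4))
  expect_identical(toks, t2)
  expect_error(embedRecord(model, list(nope = 1)), "unknown attribute")
})

test_that("decoding is invariant to token order and always full-width", {
  fx <- getCohortFixture()
  model <- fx$model
  obs <- list(age = 45, sex = "F", bmi = 23, sbp = 0.4)
  toks <- embedRecord(model, obs)
  out1 <- encodeDecode(model, toks)
  set.seed(2)
  out2 <- encodeDecode(model, sample(toks))
  expect_identical(out1, out2) # exact, not approximate
  expect_identical(names(out1), attributeNames(model@schema))
  # empty token sequence decodes every attribute from default tokens
  out0 <- encodeDecode(model, list())
  expect_identical(names(out0), attributeNames(model@schema))
  expect_true(all(vapply(out0, function(p)
    all(vapply(p, function(v) all(is.finite(v)), TRUE)), TRUE)))
})

test_that("probability heads are normalized within 1e-6 under random weights", {
  corpus <- getSmallCorpus()
  schema <- corpusSchema(corpus)
  nc <- networkConfig(embedDim = 16, heads = 4, ffDim = 24, seed = 99)
  par <- HetTabGen:::netInit(schema, nc)
  dm <- HetTabGen:::designMatrices(corpus)
  fwd <- HetTabGen:::nnForward(par, dm$XEMB[1:20, ], dm$OBS[1:20, ], nc,
                               dm$dts)
  dts <- attributeDtypes(schema)
  for (j in seq_along(dts)) {
    if (dts[[j]] %in% c("categorical", "ordered_categorical")) {
      p <- exp(fwd$heads[[j]]$logp)
      expect_true(all(abs(rowSums(p) - 1) < 1e-6))
      expect_true(all(p >= 0))
    }
  }
})

test_that("an untrained attribute added to the schema leaves original outputs unchanged", {
  base <- getBivariateModel()$model
  sch <- base@schema
  ext <- modelSchema(c(
    lapply(attributeNames(sch), function(a) list(
      name = a, dtype = attributeDtypes(sch)[[a]],
      levels = schemaLevels(sch, a), sources = schemaSources(sch, a))),
    list(list(name = "ghost", dtype = "real", sources = "S"))))
  parExt <- HetTabGen:::netInit(ext, base@netConfig)
  m <- length(attributeNames(sch))
  # copy every shared weight; the new attribute keeps fresh (untrained) rows
  parExt$A[1:m, ] <- base@params$A
  parExt$Wval[1:m, ] <- base@params$Wval
  parExt$Dtok[1:m, ] <- base@params$Dtok
  parExt$Elev[1:m] <- base@params$Elev
  parExt$heads[1:m] <- base@params$heads
  parExt$enc <- base@params$enc
  parExt$dec <- base@params$dec
  parExt$gF <- base@params$gF
  parExt$bF <- base@params$bF
  stdExt <- c(base@standardizers,
              list(ghost = list(dtype = "real", mean = 0, sd = 1)))
  extModel <- new("GenerativeModel", params = parExt, netConfig = base@netConfig,
                  schema = ext, standardizers = stdExt,
                  history = base@history,
                  trainedAttributes = c(base@trainedAttributes,
                                        ghost = FALSE),
                  versionName = base@versionName)
  for (obs in list(list(X = 0.8), list(X = -1.2), list())) {
    a1 <- impute(base, obs, "Y")$Y
    a2 <- impute(extModel, obs, "Y")$Y
    expect_identical(a1$params, a2$params)
    expect_identical(a1$mode, a2$mode)
  }
})
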