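# Shared simulation configurations and lazily trained model fixtures.
# Heavy fixtures are built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# -- configurations ---------------------------------------------------------

# small mixed-type two-source cohort exercising all five dtypes
smallMixedConfig <- function(nA = 60, nB = 50, seed = 7, missingRate = 0.1) {
  simulationConfig(
    nRecords = c(A = nA, B = nB), latentDim = 2,
    attrs = list(
      simAttr("age", "positive", c(0.3, 0), noise = 0.2, intercept = 3.8),
      simAttr("sex", "categorical", matrix(c(0.5, -0.5, 0, 0), 2, 2),
              levels = c("M", "F")),
      simAttr("x1", "real", c(0.9, 0.2), noise = 0.4),
      simAttr("cnt", "count", c(0.4, 0.1), noise = 0.1, intercept = 1.0),
      simAttr("ord", "ordered_categorical", c(0.6, -0.3), noise = 0.5,
              thresholds = c(-0.5, 0.5), levels = c("lo", "mid", "hi")),
      simAttr("y1", "real", c(0.1, 0.8), noise = 0.4)),
    sourceBlocks = list(A = c("age", "sex", "x1", "cnt"),
                        B = c("age", "sex", "ord", "y1")),
    common = c("age", "sex"), missingRate = missingRate, seed = seed)
}

# bivariate Gaussian with corr(X, Y) = rho
bivariateConfig <- function(rho = 0.8, n = 4000, seed = 11) {
  l <- sqrt(rho)
  simulationConfig(
    nRecords = c(S = n), latentDim = 1,
    attrs = list(simAttr("X", "real", l, noise = sqrt(1 - rho)),
                 simAttr("Y", "real", l, noise = sqrt(1 - rho))),
    sourceBlocks = list(S = c("X", "Y")), common = c("X", "Y"), seed = seed)
}

# statistical-linkage setting: sources {X, Z} and {Z, Y}, Y independent of
# X given Z (Z pins the single latent factor up to small noise)
linkageConfig <- function(a = 0.85, b = 0.85, n = 2500, seed = 21) {
  simulationConfig(
    nRecords = c(S1 = n, S2 = n), latentDim = 1,
    attrs = list(simAttr("X", "real", a, noise = sqrt(1 - a^2)),
                 simAttr("Z", "real", 1.0, noise = 0.05),
                 simAttr("Y", "real", b, noise = sqrt(1 - b^2))),
    sourceBlocks = list(S1 = c("X", "Z"), S2 = c("Z", "Y")),
    common = "Z", seed = seed)
}

# 12-attribute two-source mixed cohort (imputation benchmark conditions)
cohortConfig <- function(nA = 2000, nB = 2000, seed = 33) {
  simulationConfig(
    nRecords = c(A = nA, B = nB), latentDim = 3,
    attrs = list(
      simAttr("age",  "positive", c(0.25, 0, 0), noise = 0.12,
              intercept = 3.75),
      simAttr("sex",  "categorical", matrix(c(0.8, -0.8, 0, 0, 0, 0), 2, 3),
              levels = c("M", "F")),
      simAttr("bmi",  "positive", c(0.1, 0.15, 0), noise = 0.08,
              intercept = 3.1),
      simAttr("sbp",  "real", c(0.5, 0.6, 0), noise = 0.45),
      simAttr("gluc", "positive", c(0.3, 0.5, 0.2), noise = 0.3,
              intercept = 4.6),
      simAttr("chol", "real", c(0.2, 0.7, 0.2), noise = 0.5),
      simAttr("visits", "count", c(0, 0.5, 0.4), noise = 0.15,
              intercept = 0.9),
      simAttr("smoke", "ordered_categorical", c(0, 0, 0.9), noise = 0.45,
              thresholds = c(-0.4, 0.8), levels = c("never", "past", "daily")),
      simAttr("exer", "ordered_categorical", c(0, 0.4, -0.7), noise = 0.5,
              thresholds = c(-0.7, 0.5), levels = c("low", "mid", "high")),
      simAttr("alc",  "categorical",
              matrix(c(0.6, -0.2, 0, 0.3, 0.5, -0.6), 2, 3),
              levels = c("no", "yes")),
      simAttr("steps", "real", c(0, -0.3, 0.8), noise = 0.5),
      simAttr("hdl",  "real", c(-0.2, -0.6, 0.3), noise = 0.55)),
    sourceBlocks = list(
      A = c("age", "sex", "bmi", "sbp", "gluc", "chol", "visits"),
      B = c("age", "sex", "bmi", "smoke", "exer", "alc", "steps", "hdl")),
    common = c("age", "sex", "bmi"), missingRate = 0.05, seed = seed)
}

# single-source regression cohort for machine-learning efficiency
regressionConfig <- function(n = 3000, seed = 77) {
  simulationConfig(
    nRecords = c(S = n), latentDim = 3,
    attrs = c(list(simAttr("y", "real", c(0.9, 0.6, 0.4), noise = 0.35)),
              lapply(1:9, function(i) {
                set.seed(100 + i)
                simAttr(paste0("x", i), "real", rnorm(3, sd = 0.5),
                        noise = 0.4)
              })),
    sourceBlocks = list(S = c("y", paste0("x", 1:9))),
    common = "y", seed = seed)
}

simCorpus <- function(cfg) {
  fitStandardizers(concatSources(simulatePopulation(cfg), simSchema(cfg)))
}

# -- cached heavy fixtures --------------------------------------------------

getSmallCorpus <- function() fixture("smallCorpus", function() {
  simCorpus(smallMixedConfig())
})

getBivariateModel <- function() fixture("bivariateModel", function() {
  corpus <- simCorpus(bivariateConfig())
  model <- trainModel(
    corpus,
    networkConfig(embedDim = 16, encLayers = 1, decLayers = 1, heads = 2,
                  ffDim = 32, seed = 2),
    trainingConfig(maskRate = 0.5, epochsStage1 = 0, epochsStage2 = 30,
                   batchSize = 512, learningRate = 5e-3, seed = 3),
    versionName = "vega")
  list(corpus = corpus, model = model, rho = 0.8)
})

getLinkageFixture <- function() fixture("linkage", function() {
  cfg <- linkageConfig()
  corpus <- simCorpus(cfg)
  model <- trainModel(
    corpus,
    networkConfig(embedDim = 16, encLayers = 1, decLayers = 1, heads = 2,
                  ffDim = 32, seed = 2),
    trainingConfig(maskRate = 0.5, epochsStage1 = 10, epochsStage2 = 40,
                   batchSize = 256, learningRate = 5e-3, seed = 3),
    versionName = "altair")
  list(cfg = cfg, corpus = corpus, model = model,
       oracle = latentOracle(cfg))
})

getCohortFixture <- function() fixture("cohort", function() {
  cfg <- cohortConfig()
  tabs <- simulatePopulation(cfg)
  corpus <- concatSources(tabs, simSchema(cfg))
  sp <- splitHoldout(corpus, 0.10, strata = c("sex", "age"), seed = 5)
  train <- fitStandardizers(sp$train)
  model <- trainModel(
    train,
    networkConfig(embedDim = 32, encLayers = 1, decLayers = 1, heads = 4,
                  ffDim = 64, seed = 2),
    trainingConfig(maskRate = 0.5, epochsStage1 = 5, epochsStage2 = 15,
                   batchSize = 512, learningRate = 5e-3, seed = 3),
    versionName = "deneb")
  list(cfg = cfg, corpus = corpus, train = train, holdout = sp$holdout,
       model = model)
})

getRegressionFixture <- function() fixture("regression", function() {
  cfg <- regressionConfig()
  corpus <- simCorpus(cfg)
  model <- trainModel(
    corpus,
    networkConfig(embedDim = 32, heads = 4, seed = 2),
    trainingConfig(maskRate = 0.5, epochsStage1 = 0, epochsStage2 = 80,
                   batchSize = 256, learningRate = 5e-3, seed = 3),
    versionName = "spica")
  synth <- generateRecords(model, 3000, sampling = "sequential", seed = 9)
  list(corpus = corpus, model = model, synth = synth,
       real = as.data.frame(corpusValues(corpus)))
})
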