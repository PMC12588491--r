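#' @include corpus.R
NULL

#' Declare one simulated attribute
#'
#' Each attribute is driven by a linear score \code{loading \%*\% z +
#' intercept} on the shared latent normal vector \code{z}, plus independent
#' Gaussian noise of scale \code{noise} where the type uses a noisy score:
#' \itemize{
#'   \item \code{real}: identity link, value = score + noise.
#'   \item \code{positive}: exponential link, value = exp(score + noise).
#'   \item \code{count}: Poisson with log link, rate = exp(score); noise is
#'     added to the log-rate before exponentiation.
#'   \item \code{ordered_categorical}: level = interval of (score + noise)
#'     among strictly increasing \code{thresholds}.
#'   \item \code{categorical}: softmax over per-level scores
#'     \code{loading[l, ] \%*\% z + intercept[l]} (loading is a levels x
#'     latent matrix, noise unused -- level probabilities given z are exact).
#' }
#'
#' @param name attribute name
#' @param dtype one of the five supported types
#' @param loading numeric vector (length latentDim) or, for categorical, a
#'   levels x latentDim matrix
#' @param noise Gaussian noise SD on the score scale
#' @param intercept scalar (or per-level vector for categorical)
#' @param levels character level names for level types
#' @param thresholds strictly increasing cutpoints (ordered_categorical;
#'   length = nlevels - 1)
#' @export
simAttr <- function(name, dtype, loading, noise = 0.5, intercept = 0,
                    levels = NULL, thresholds = NULL) {
  dtype <- match.arg(dtype, ATTRIBUTE_DTYPES)
  if (dtype == "categorical") {
    loading <- as.matrix(loading)
    if (is.null(levels)) levels <- paste0("L", seq_len(nrow(loading)))
    if (length(intercept) == 1) intercept <- rep(intercept, nrow(loading))
    if (nrow(loading) != length(levels) ||
        length(intercept) != length(levels))
      stopf("attribute '%s': categorical loading/intercept shape mismatch",
            name)
  } else if (dtype == "ordered_categorical") {
    if (is.null(thresholds)) stopf("attribute '%s': thresholds required", name)
    if (is.null(levels)) levels <- paste0("L", seq_len(length(thresholds) + 1))
    if (length(levels) != length(thresholds) + 1)
      stopf("attribute '%s': need one more level than thresholds", name)
  }
  list(name = name, dtype = dtype, loading = loading, noise = noise,
       intercept = intercept, levels = levels, thresholds = thresholds)
}

#' Assemble a simulation configuration
#'
#' @param nRecords named numeric vector, records per source
#' @param latentDim latent factor dimension
#' @param attrs list of \code{\link{simAttr}} entries
#' @param sourceBlocks named list, source label -> attribute names in that
#'   block; each block must contain all \code{common} attributes
#' @param common character vector of designated common (linking) attributes
#' @param missingRate per-attribute MCAR rate inside a block (scalar or
#'   named vector; default 0)
#' @param seed integer
#' @return a validated \code{\linkS4class{SimulationConfig}}
#' @export
simulationConfig <- function(nRecords, latentDim, attrs, sourceBlocks,
                             common = character(0), missingRate = 0,
                             seed = 1L) {
  names(attrs) <- vapply(attrs, `[[`, "", "name")
  if (length(missingRate) == 1)
    missingRate <- setNames(rep(missingRate, length(attrs)), names(attrs))
  mr <- setNames(rep(0, length(attrs)), names(attrs))
  mr[names(missingRate)] <- missingRate
  new("SimulationConfig", nRecords = nRecords,
      latentDim = as.integer(latentDim), attrs = attrs,
      sourceBlocks = sourceBlocks, commonAttributes = common,
      missingRate = mr, seed = as.integer(seed))
}

#' Derive the ModelSchema implied by a simulation configuration
#' @param config a SimulationConfig
#' @export
simSchema <- function(config) {
  srcOf <- function(nm) names(Filter(function(b) nm %in% b,
                                     config@sourceBlocks))
  modelSchema(lapply(config@attrs, function(a) {
    list(name = a$name, dtype = a$dtype, levels = a$levels,
         sources = srcOf(a$name))
  }))
}

# latent scores for one attribute given latent matrix z (n x k)
simScore <- function(a, z) {
  if (a$dtype == "categorical") z %*% t(a$loading) else
    drop(z %*% a$loading) + a$intercept
}

#' Simulate a multi-source mixed-type cohort
#'
#' Draws one latent standard-normal vector per subject, maps it through the
#' per-attribute links of the configuration, then applies the structural
#' source blocks and the MCAR missingness.  Fully reproducible under the
#' configuration seed.
#'
#' @param config a \code{SimulationConfig}
#' @return named list of \code{SourceTable}, one per source block
#' @export
simulatePopulation <- function(config) {
  schema <- simSchema(config)
  withSeed(config@seed, {
    lapply(setNames(nm = names(config@sourceBlocks)), function(src) {
      n <- as.integer(config@nRecords[[src]] %||% 0)
      blk <- config@sourceBlocks[[src]]
      vals <- matrix(NA_real_, n, length(blk), dimnames = list(NULL, blk))
      if (n > 0) {
        z <- matrix(rnorm(n * config@latentDim), n, config@latentDim)
        for (a in config@attrs[blk]) {
          vals[, a$name] <- simDrawAttr(a, z)
          mr <- config@missingRate[[a$name]]
          if (mr > 0) vals[runif(n) < mr, a$name] <- NA
        }
      }
      new("SourceTable", label = src, values = vals, mask = !is.na(vals),
          dtypes = setNames(vapply(config@attrs[blk], `[[`, "", "dtype"),
                            blk))
    })
  })
}

simDrawAttr <- function(a, z) {
  n <- nrow(z)
  switch(a$dtype,
    real = simScore(a, z) + rnorm(n, sd = a$noise),
    positive = exp(simScore(a, z) + rnorm(n, sd = a$noise)),
    count = rpois(n, exp(pmin(simScore(a, z) +
                                rnorm(n, sd = a$noise), 30))),
    ordered_categorical = {
      lat <- simScore(a, z) + rnorm(n, sd = a$noise)
      as.numeric(findInterval(lat, a$thresholds) + 1)
    },
    categorical = {
      sc <- simScore(a, z)
      sc <- sweep(sc, 2, a$intercept, "+")
      p <- exp(sc - apply(sc, 1, max))
      p <- p / rowSums(p)
      vapply(seq_len(n), function(i)
        sample.int(ncol(p), 1L, prob = p[i, ]), 1L)
    })
}

#' Ground-truth oracle sharing parameters with the simulator
#' @param config a SimulationConfig
#' @return a \code{LatentFactorOracle}
#' @export
latentOracle <- function(config) new("LatentFactorOracle", config = config)

#' Discrete X -> Z -> Y chain oracle
#'
#' A three-variable binary chain used to exercise the marginalization
#' identity P(Y|X) = sum_z P(Y|z) P(z|X) exactly (enumeration over the 8
#' outcomes) and by Monte-Carlo simulation.
#'
#' @param pX1 P(X = 1)
#' @param pZ1gX c(P(Z=1|X=0), P(Z=1|X=1))
#' @param pY1gZ c(P(Y=1|Z=0), P(Y=1|Z=1))
#' @export
discreteChainOracle <- function(pX1 = 0.5, pZ1gX, pY1gZ) {
  new("DiscreteChainOracle", pX1 = pX1, pZ1gX = pZ1gX, pY1gZ = pY1gZ)
}
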