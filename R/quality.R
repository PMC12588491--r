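#' @include inference.R
NULL

#' Mean/mode baseline imputation value for one attribute
#'
#' real and positive attributes: the training mean; count, categorical and
#' ordered categorical attributes: the training mode (most frequent value,
#' ties to the smallest).
#'
#' @param corpus training TabularCorpus
#' @param attribute attribute name
#' @return constant baseline value on the natural scale (level index for
#'   level types)
#' @export
baselineImpute <- function(corpus, attribute) {
  dt <- attributeDtypes(corpus)[[attribute]]
  x <- corpusValues(corpus)[, attribute]
  x <- x[!is.na(x)]
  if (!length(x)) stopf("attribute '%s' has no observed values", attribute)
  if (dt %in% c("real", "positive")) {
    mean(x)
  } else {
    tab <- table(x)
    as.numeric(names(tab)[which.max(tab)])
  }
}

# natural-scale training SD per attribute (denominator of the standardized
# imputation error)
naturalSD <- function(corpus) {
  vals <- corpusValues(corpus)
  vapply(colnames(vals), function(a) sd(vals[, a], na.rm = TRUE), 0)
}

#' Holdout imputation-error benchmark against mean/mode baselines
#'
#' For each target attribute, every holdout record with the target observed
#' is imputed from the top-k model-ranked predictors that are observed in
#' that record; the mode of the estimated distribution is the point
#' estimate.  Numeric targets report the absolute error divided by the
#' training-set SD on the natural scale; level targets report accuracy
#' macro-averaged over the levels present.  The same records are scored
#' under the mean/mode baseline.
#'
#' @param model a GenerativeModel
#' @param holdout holdout TabularCorpus (disjoint from training)
#' @param train training TabularCorpus (predictor ranking, baselines, SDs)
#' @param kPredictors number of predictors conditioned on (default 10)
#' @param maxRecords per-target cap on evaluated holdout records
#' @param seed integer (probe/record subsampling)
#' @return an \code{\linkS4class{EvaluationReport}}; aggregates give the
#'   mean and SD of the per-attribute metric by dtype, for the model and
#'   the baseline
#' @export
imputationErrorReport <- function(model, holdout, train, kPredictors = 10L,
                                  maxRecords = 500L, seed = 1L) {
  if (any(corpusRoles(train) == "holdout") ||
      !all(corpusRoles(holdout) == "holdout"))
    stopf("pass the training split as 'train' and the holdout split as 'holdout'")
  attrs <- attributeNames(model@schema)
  dts <- attributeDtypes(model@schema)
  sdTrain <- naturalSD(train)
  hvals <- corpusValues(holdout)
  hmask <- corpusMask(holdout)
  dmH <- designMatrices(withStandardizers(holdout, model@standardizers))
  rows <- list()
  for (a in intersect(attrs, colnames(hvals))) {
    tj <- match(a, attrs)
    rec <- which(hmask[, a])
    if (length(rec) == 0) {
      jlog("imputationError.skip", attribute = a)
      next
    }
    rec <- withSeed(seed, if (length(rec) > maxRecords)
      sample(rec, maxRecords) else rec)
    preds <- rankPredictors(model, train, a, k = kPredictors, seed = seed)
    B <- length(rec)
    XEMB <- matrix(0, B, length(attrs))
    OBS <- matrix(FALSE, B, length(attrs))
    for (p in preds) {
      pj <- match(p, attrs)
      ok <- dmH$OBS[rec, pj]
      XEMB[ok, pj] <- dmH$XEMB[rec[ok], pj]
      OBS[ok, pj] <- TRUE
    }
    heads <- modelForwardChunked(model, XEMB, OBS, targets = a)
    sp <- headParams(model, heads, a)
    std <- model@standardizers[[a]]
    truth <- hvals[rec, a]
    if (dts[[a]] %in% NUMERIC_DTYPES) {
      modes <- switch(dts[[a]],
        real = sp$mean * std$sd + std$mean,
        positive = exp((sp$mean * std$logSd + std$logMean) -
                         (sp$sd * std$logSd)^2),
        count = floor(sp$rate))
      err <- mean(abs(modes - truth)) / sdTrain[[a]]
      base <- baselineImpute(train, a)
      berr <- mean(abs(base - truth)) / sdTrain[[a]]
      rows[[length(rows) + 1L]] <- data.frame(
        attribute = a, dtype = dts[[a]],
        metric = c("abs_std_error", "baseline_abs_std_error"),
        value = c(err, berr), n = B)
    } else {
      modes <- max.col(sp$probs, ties.method = "first")
      acc <- macroAccuracy(truth, modes)
      base <- baselineImpute(train, a)
      bacc <- macroAccuracy(truth, rep(base, B))
      rows[[length(rows) + 1L]] <- data.frame(
        attribute = a, dtype = dts[[a]],
        metric = c("macro_accuracy", "baseline_macro_accuracy"),
        value = c(acc, bacc), n = B)
    }
  }
  perAttr <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(perAttr, perAttr[c("dtype", "metric")],
                                     drop = TRUE), function(g)
    data.frame(dtype = g$dtype[1], metric = g$metric[1],
               value = mean(g$value), sdAcross = sd(g$value),
               nAttributes = nrow(g))))
  rownames(agg) <- NULL
  agg$sdAcross[!is.finite(agg$sdAcross)] <- 0
  new("EvaluationReport", perAttribute = perAttr,
      perPair = data.frame(), aggregate = agg,
      info = list(version = model@versionName, kPredictors = kPredictors))
}

# accuracy macro-averaged over the true levels present
macroAccuracy <- function(truth, pred) {
  mean(vapply(unique(truth), function(l)
    mean(pred[truth == l] == l), 0))
}

#' Overlap area of two sample histograms
#'
#' Normalized histograms over shared bin edges spanning the pooled range
#' (levels serve as bins for character/factor input); the overlap is the
#' sum of bin-wise minima, a similarity in [0, 1].
#'
#' @param a,b samples (numeric, or character/factor for level data)
#' @param bins number of bins (numeric input); default Freedman-Diaconis
#'   on the pooled sample
#' @export
univariateOverlap <- function(a, b, bins = NULL) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stopf("empty sample")
  if (is.character(a) || is.factor(a) || is.character(b) || is.factor(b)) {
    lev <- union(unique(as.character(a)), unique(as.character(b)))
    p <- table(factor(as.character(a), lev)) / length(a)
    q <- table(factor(as.character(b), lev)) / length(b)
    return(sum(pmin(p, q)))
  }
  pooled <- c(a, b)
  nb <- bins %||% fdBinCount(pooled)
  rng <- range(pooled)
  if (rng[1] == rng[2]) return(1)
  brk <- seq(rng[1], rng[2], length.out = nb + 1)
  cut_ <- function(x) {
    i <- findInterval(x, brk, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(i, nbins = nb) / length(x)
  }
  sum(pmin(cut_(a), cut_(b)))
}

fdBinCount <- function(x) {
  h <- 2 * stats::IQR(x) * length(x)^(-1 / 3)
  if (!is.finite(h) || h <= 0) return(10L)
  max(1L, min(100L, ceiling(diff(range(x)) / h)))
}

#' Bivariate conditional-distribution fidelity
#'
#' For each attribute pair (X, Y), X is discretized into equal-frequency
#' bins; within each sufficiently occupied bin the corpus Y values are
#' compared with model draws of Y conditioned on the bin's X midpoint via
#' \code{\link{univariateOverlap}}.  The per-pair metric is the bin-weighted
#' mean overlap, which is sensitive to non-linear structure a covariance
#' summary would miss.
#'
#' @param model a GenerativeModel
#' @param corpus a TabularCorpus of reference records
#' @param pairs list of c(X, Y) attribute-name pairs
#' @param xBins number of X bins
#' @param nDraw model draws per bin
#' @param minCount smallest usable bin; smaller bins are excluded
#' @param bins histogram bins for the overlap
#' @param seed integer
#' @return an \code{EvaluationReport} with per-pair overlaps
#' @export
bivariateReport <- function(model, corpus, pairs, xBins = 5L, nDraw = 400L,
                            minCount = 20L, bins = 12L, seed = 1L) {
  vals <- corpusValues(corpus)
  dts <- attributeDtypes(model@schema)
  rows <- list()
  for (pr in pairs) {
    xa <- pr[1]; ya <- pr[2]
    ok <- !is.na(vals[, xa]) & !is.na(vals[, ya])
    if (!any(ok)) stopf("pair (%s, %s) never jointly observed", xa, ya)
    xv <- vals[ok, xa]; yv <- vals[ok, ya]
    brk <- unique(quantile(xv, probs = seq(0, 1, length.out = xBins + 1)))
    bin <- findInterval(xv, brk, rightmost.closed = TRUE, all.inside = TRUE)
    wsum <- 0; osum <- 0; used <- 0L
    for (bI in unique(bin)) {
      inB <- bin == bI
      if (sum(inB) < minCount) {
        jlog("bivariate.binExcluded", pair = paste(xa, ya), bin = bI,
             n = sum(inB))
        next
      }
      mid <- median(xv[inB])
      if (dts[[xa]] == "count") mid <- round(mid)
      draws <- drawConditional(model, ya, setNames(list(mid), xa), nDraw,
                               seed = seed + bI)
      ref <- yv[inB]
      ov <- if (dts[[ya]] %in% LEVEL_DTYPES) {
        univariateOverlap(as.character(ref), as.character(draws))
      } else {
        univariateOverlap(ref, draws, bins = bins)
      }
      wsum <- wsum + sum(inB); osum <- osum + ov * sum(inB)
      used <- used + 1L
    }
    if (wsum == 0) stopf("pair (%s, %s): all bins below minCount", xa, ya)
    rows[[length(rows) + 1L]] <- data.frame(
      x = xa, y = ya, metric = "conditional_overlap",
      value = osum / wsum, n = used)
  }
  perPair <- do.call(rbind, rows)
  agg <- data.frame(dtype = "all", metric = "mean_conditional_overlap",
                    value = mean(perPair$value), sdAcross = sd(perPair$value),
                    nAttributes = nrow(perPair))
  agg$sdAcross[!is.finite(agg$sdAcross)] <- 0
  new("EvaluationReport", perAttribute = data.frame(), perPair = perPair,
      aggregate = agg, info = list(version = model@versionName))
}

# draw nDraw values of `target` from the model conditional on `given`
drawConditional <- function(model, target, given, nDraw, seed = 1L) {
  est <- impute(model, given, target)[[target]]
  std <- model@standardizers[[target]]
  withSeed(seed, switch(est$dtype,
    real = rnorm(nDraw, est$params$mean, est$params$sd),
    positive = exp(rnorm(nDraw, est$params$mean, est$params$sd)),
    count = rpois(nDraw, est$params$rate),
    sample(length(est$params$probs), nDraw, replace = TRUE,
           prob = est$params$probs)))
}

#' Scenario-based directional checks on persona inputs
#'
#' Imputes each target for every persona and verifies the expected
#' inequalities between modes, reporting direction and magnitude.
#'
#' @param model a GenerativeModel
#' @param personas named list of observed-value maps
#' @param expectations data.frame with columns \code{target},
#'   \code{higher}, \code{lower}: the target's mode under persona
#'   \code{higher} is expected to exceed its mode under persona
#'   \code{lower} (level targets compare level indices)
#' @return data.frame with modes, magnitude (delta) and pass/fail per
#'   expectation
#' @export
scenarioCheck <- function(model, personas, expectations) {
  modes <- lapply(personas, function(p) {
    est <- impute(model, p)
    vapply(names(est), function(a) {
      e <- est[[a]]
      if (is.character(e$mode))
        as.numeric(match(e$mode, schemaLevels(model@schema, a)))
      else as.numeric(e$mode)
    }, 0)
  })
  out <- expectations
  out$modeHigher <- NA_real_
  out$modeLower <- NA_real_
  for (i in seq_len(nrow(out))) {
    tg <- out$target[i]
    out$modeHigher[i] <- modes[[out$higher[i]]][[tg]]
    out$modeLower[i] <- modes[[out$lower[i]]][[tg]]
  }
  out$delta <- out$modeHigher - out$modeLower
  out$pass <- out$delta > 0
  out
}

#' Concordance of a model sample with an external summary
#'
#' Treats the model-sample mean as a sample mean and reports its z-score
#' relative to the external distribution, \eqn{z = (\bar{x} - \mu_{ext}) /
#' \sigma_{ext}}, together with the overlapping area of the two normal
#' densities fitted to the model sample and the external summary.
#'
#' @param modelSample numeric model draws
#' @param externalMean,externalSD external summary statistics (SD > 0)
#' @param externalN external sample size (recorded, not used)
#' @return list(z, overlap, modelMean, modelSD)
#' @export
externalCompare <- function(modelSample, externalMean, externalSD,
                            externalN = NULL) {
  if (externalSD <= 0) stopf("external SD must be > 0")
  if (length(modelSample) < 2 || sd(modelSample) <= 0)
    stopf("degenerate model sample")
  m1 <- mean(modelSample)
  s1 <- sd(modelSample)
  list(z = (m1 - externalMean) / externalSD,
       overlap = normalOverlap(m1, s1, externalMean, externalSD),
       modelMean = m1, modelSD = s1)
}

#' Overlapping area of two normal densities (closed form)
#' @param m1,s1,m2,s2 means and SDs
#' @export
normalOverlap <- function(m1, s1, m2, s2) {
  if (abs(s1 - s2) < 1e-12) {
    if (abs(m1 - m2) < 1e-300) return(1)
    return(2 * pnorm(-abs(m1 - m2) / (2 * s1)))
  }
  A <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  Bc <- m1 / s1^2 - m2 / s2^2
  Cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) - log(s1 / s2)
  disc <- Bc^2 - 4 * A * Cc
  if (disc <= 0) {
    # one density dominates everywhere: the overlap is the mass of the
    # narrower density... which cannot happen for distinct normals with
    # unequal SDs; fall back to the smaller total mass bound
    r <- numeric(0)
  } else {
    r <- sort(c((-Bc - sqrt(disc)) / (2 * A), (-Bc + sqrt(disc)) / (2 * A)))
  }
  pts <- c(-Inf, r, Inf)
  tot <- 0
  for (i in seq_len(length(pts) - 1)) {
    lo <- pts[i]; hi <- pts[i + 1]
    mid <- if (is.infinite(lo) && is.infinite(hi)) m1
           else if (is.infinite(lo)) hi - 1
           else if (is.infinite(hi)) lo + 1
           else (lo + hi) / 2
    use1 <- dnorm(mid, m1, s1) <= dnorm(mid, m2, s2)
    mu <- if (use1) m1 else m2
    sg <- if (use1) s1 else s2
    tot <- tot + (pnorm(hi, mu, sg) - pnorm(lo, mu, sg))
  }
  min(max(tot, 0), 1)
}

#' Machine-learning efficiency of synthetic data
#'
#' Fits the same regressor (gradient-boosted trees) on (i) the real
#' training rows, (ii) synthetic rows only, and (iii) synthetic plus real
#' training rows, and reports the R-squared of each fit on a held-out real
#' test split.  Synthetic data of high utility yields performance close to
#' the real-data fit, and augmentation should not degrade it.
#'
#' @param real data.frame/matrix of real records (features + target)
#' @param synthetic data.frame/matrix of synthetic records, same columns
#' @param target numeric target column name (regression)
#' @param testFraction fraction of real rows held out for testing
#' @param seed integer
#' @param nrounds boosting rounds
#' @param maxDepth,eta tree depth and learning rate
#' @return named numeric: r2_real, r2_synthetic_only,
#'   r2_synthetic_plus_real
#' @export
mlEfficiency <- function(real, synthetic, target, testFraction = 0.25,
                         seed = 1L, nrounds = 150L, maxDepth = 4L,
                         eta = 0.1) {
  real <- as.data.frame(real)
  synthetic <- as.data.frame(synthetic)
  if (!target %in% colnames(real) || !target %in% colnames(synthetic))
    stopf("target '%s' must be present in both tables", target)
  feats <- setdiff(colnames(real), target)
  real <- real[!is.na(real[[target]]), , drop = FALSE]
  synthetic <- synthetic[!is.na(synthetic[[target]]), , drop = FALSE]
  testIdx <- withSeed(seed,
    sample(nrow(real), max(1L, round(testFraction * nrow(real)))))
  test <- real[testIdx, , drop = FALSE]
  trainReal <- real[-testIdx, , drop = FALSE]

  fitScore <- function(dat) {
    X <- as.matrix(dat[, feats, drop = FALSE])
    bst <- xgboost::xgboost(
      data = X, label = dat[[target]], nrounds = nrounds,
      params = list(objective = "reg:squarederror", max_depth = maxDepth,
                    eta = eta, nthread = 1, seed = seed),
      verbose = 0)
    pred <- predict(bst, as.matrix(test[, feats, drop = FALSE]))
    y <- test[[target]]
    1 - sum((pred - y)^2) / sum((y - mean(y))^2)
  }
  c(r2_real = fitScore(trainReal),
    r2_synthetic_only = fitScore(synthetic),
    r2_synthetic_plus_real = fitScore(rbind(synthetic, trainReal)))
}

#' Turn a SourceTable into a data.frame (level types stay level indices)
#' @param table a SourceTable
#' @export
sourceTableData <- function(table) {
  v <- table@values
  v[!table@mask] <- NA
  as.data.frame(v)
}
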