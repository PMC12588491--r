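#' @include trainer.R
NULL

WHATIF_DISCLAIMER <- paste(
  "Associative estimate only: the counterfactual distribution reflects",
  "statistical association in the training data and must not be",
  "interpreted as a causal effect.")

# validate and standardize a named list of observed values against the
# model's schema; returns list(x = standardized values, codes kept raw for
# level types)
encodeObserved <- function(model, observed, context = "observed") {
  schema <- model@schema
  dts <- attributeDtypes(schema)
  std <- model@standardizers
  unknown <- setdiff(names(observed), names(dts))
  if (length(unknown))
    stopf("unknown attribute '%s' in %s values", unknown[1], context)
  out <- list()
  for (a in names(observed)) {
    v <- observed[[a]]
    dt <- dts[[a]]
    if (dt %in% LEVEL_DTYPES) {
      lev <- schemaLevels(schema, a)
      if (is.character(v) || is.factor(v)) {
        idx <- match(as.character(v), lev)
        if (is.na(idx))
          stopf("attribute '%s': value '%s' is not a declared level", a, v)
        v <- idx
      }
      if (v < 1 || v > length(lev) || v != floor(v))
        stopf("attribute '%s': level index out of range", a)
      out[[a]] <- v
    } else {
      v <- suppressWarnings(as.numeric(v))
      if (!is.finite(v)) stopf("attribute '%s': non-finite value", a)
      if (dt == "positive" && v <= 0)
        stopf("attribute '%s': positive attribute requires a value > 0", a)
      if (dt == "count" && (v < 0 || v != floor(v)))
        stopf("attribute '%s': count must be a nonnegative integer", a)
      out[[a]] <- v
    }
  }
  out
}

# build 1 x m design row from validated observed values
designRow <- function(model, observed) {
  attrs <- attributeNames(model@schema)
  m <- length(attrs)
  XEMB <- matrix(0, 1, m, dimnames = list(NULL, attrs))
  OBS <- matrix(FALSE, 1, m, dimnames = list(NULL, attrs))
  for (a in names(observed)) {
    j <- match(a, attrs)
    dt <- attributeDtypes(model@schema)[[a]]
    XEMB[1, j] <- if (dt %in% LEVEL_DTYPES) observed[[a]]
                  else standardizeValue(model@standardizers[[a]],
                                        observed[[a]])
    OBS[1, j] <- TRUE
  }
  list(XEMB = XEMB, OBS = OBS)
}

# forward pass of a fitted model; when `targets` is given, imputed value
# tokens of the remaining missing attributes are fed back in a second pass
# (leave-target-out), which composes the trained conditionals across
# sources
modelForward <- function(model, XEMB, OBS, targets = NULL) {
  feedMask <- NULL
  if (!is.null(targets) && model@netConfig@passes > 1L) {
    feedMask <- !OBS
    tj <- match(targets, attributeNames(model@schema))
    feedMask[, tj] <- FALSE
    untrained <- which(!model@trainedAttributes[
      attributeNames(model@schema)])
    if (length(untrained)) feedMask[, untrained] <- FALSE
  }
  fullForward(model@params, XEMB, OBS, model@netConfig,
              attributeDtypes(model@schema), model@standardizers,
              feedMask = feedMask)
}

# forward in chunks to bound attention-array memory; merges head outputs
modelForwardChunked <- function(model, XEMB, OBS, targets = NULL,
                                chunk = 2048L) {
  B <- nrow(XEMB)
  if (B <= chunk) return(modelForward(model, XEMB, OBS, targets)$heads)
  splits <- split(seq_len(B), ceiling(seq_len(B) / chunk))
  parts <- lapply(splits, function(idx)
    modelForward(model, XEMB[idx, , drop = FALSE],
                 OBS[idx, , drop = FALSE], targets)$heads)
  m <- length(parts[[1]])
  out <- vector("list", m)
  names(out) <- names(parts[[1]])
  for (j in seq_len(m)) {
    fields <- names(parts[[1]][[j]])
    out[[j]] <- setNames(lapply(fields, function(f) {
      pieces <- lapply(parts, function(p) p[[j]][[f]])
      if (is.matrix(pieces[[1]])) do.call(rbind, pieces)
      else do.call(c, pieces)
    }), fields)
  }
  out
}

# standardized-scale distribution parameters of attribute j for all records
headParams <- function(model, heads, a) {
  dt <- attributeDtypes(model@schema)[[a]]
  o <- heads[[match(a, attributeNames(model@schema))]]
  if (dt %in% c("real", "positive")) {
    list(mean = o$mu, sd = exp(o$logsd))
  } else if (dt == "count") {
    list(rate = exp(o$loglam))
  } else {
    p <- exp(o$logp)
    colnames(p) <- schemaLevels(model@schema, a)
    list(probs = p)
  }
}

# natural-scale view of standardized params for one record index b
naturalParams <- function(model, a, sp, b = 1L) {
  dt <- attributeDtypes(model@schema)[[a]]
  std <- model@standardizers[[a]]
  if (dt == "real") {
    list(mean = sp$mean[b] * std$sd + std$mean, sd = sp$sd[b] * std$sd)
  } else if (dt == "positive") {
    # parameters of the log value on its natural (log) scale
    list(mean = sp$mean[b] * std$logSd + std$logMean,
         sd = sp$sd[b] * std$logSd)
  } else if (dt == "count") {
    list(rate = sp$rate[b])
  } else {
    list(probs = sp$probs[b, ])
  }
}

#' Tokenize one record's observed attributes
#'
#' One token per observed attribute (none for missing): the attribute
#' identity embedding plus the learned value embedding.  Token order
#' carries no meaning.
#'
#' @param model a GenerativeModel
#' @param observed named list of observed attribute values
#' @return list of tokens, each \code{list(attr, name, vector)}
#' @export
embedRecord <- function(model, observed) {
  observed <- encodeObserved(model, observed)
  dr <- designRow(model, observed)
  emb <- embedForward(model@params, dr$XEMB, dr$OBS,
                      attributeDtypes(model@schema))
  attrs <- attributeNames(model@schema)
  toks <- list()
  for (a in names(observed)) {
    j <- match(a, attrs)
    toks[[length(toks) + 1L]] <- list(attr = j, name = a,
                                      vector = emb$T[j, ])
  }
  toks
}

#' Decode distribution parameters for every attribute from a token sequence
#'
#' The encoder attends only over the supplied (observed) tokens; the
#' full-width latent sequence is then assembled from the transformed
#' observed latents plus each missing attribute's learnable default token,
#' and the typed heads emit parameters for every schema attribute.  The
#' output is invariant to token order.
#'
#' @param model a GenerativeModel
#' @param tokens list of tokens from \code{\link{embedRecord}} (may be
#'   empty: all attributes are then decoded from default tokens alone)
#' @return named list of standardized-scale distribution parameters per
#'   attribute
#' @export
encodeDecode <- function(model, tokens) {
  attrs <- attributeNames(model@schema)
  m <- length(attrs)
  d <- ncol(model@params$A)
  T <- matrix(0, m, d)
  OBS <- matrix(FALSE, 1, m)
  for (tk in tokens) {
    T[tk$attr, ] <- tk$vector
    OBS[1, tk$attr] <- TRUE
  }
  fwd <- fullForward(model@params, matrix(0, 1, m), OBS, model@netConfig,
                     attributeDtypes(model@schema), model@standardizers,
                     Temb = T)
  setNames(lapply(attrs, function(a) headParams(model, fwd$heads, a)),
           attrs)
}

#' Conditional imputation: estimated distributions for target attributes
#'
#' One encoder-decoder pass conditioned on the observed values returns, for
#' every target attribute, the full estimated distribution together with
#' its mode as a point estimate on the natural scale.
#'
#' @param model a GenerativeModel
#' @param observed named list of observed attribute values (may be empty
#'   for the model's unconditional estimate)
#' @param targets character vector of target attributes (default: all
#'   attributes not observed)
#' @return named list per target: \code{dtype}, \code{params}
#'   (natural-scale distribution parameters; for positive attributes the
#'   parameters of the log value), \code{mode}
#' @export
impute <- function(model, observed = list(), targets = NULL) {
  observed <- encodeObserved(model, observed)
  attrs <- attributeNames(model@schema)
  if (is.null(targets)) targets <- setdiff(attrs, names(observed))
  unknown <- setdiff(targets, attrs)
  if (length(unknown)) stopf("unknown target attribute '%s'", unknown[1])
  clash <- intersect(targets, names(observed))
  if (length(clash))
    stopf("attribute '%s' supplied both as observed and as target", clash[1])
  dr <- designRow(model, observed)
  fwd <- modelForward(model, dr$XEMB, dr$OBS, targets = targets)
  dts <- attributeDtypes(model@schema)
  setNames(lapply(targets, function(a) {
    sp <- headParams(model, fwd$heads, a)
    np <- naturalParams(model, a, sp)
    mode <- modeOf(list(mean = sp$mean[1], sd = sp$sd[1],
                        rate = sp$rate[1],
                        probs = if (!is.null(sp$probs)) sp$probs[1, ]),
                   dts[[a]], model@standardizers[[a]])
    list(dtype = dts[[a]], params = np, mode = mode)
  }), targets)
}

# vectorized per-record NLL of true values y (likelihood scale) for attr a
targetNLLs <- function(model, heads, a, y) {
  dt <- attributeDtypes(model@schema)[[a]]
  o <- heads[[match(a, attributeNames(model@schema))]]
  if (dt %in% c("real", "positive")) {
    r <- y - o$mu
    0.5 * log(2 * pi) + o$logsd + r^2 / (2 * exp(2 * o$logsd))
  } else if (dt == "count") {
    exp(o$loglam) - y * o$loglam + lgamma(y + 1)
  } else {
    -o$logp[cbind(seq_along(y), as.integer(y))]
  }
}

#' Generate synthetic records
#'
#' Conditioning values are copied verbatim into every record.  In
#' \code{"sequential"} mode (default) the unconditioned attributes are
#' sampled one at a time in a seeded random order, each draw fed back as
#' observed, which captures dependencies between attributes.  In
#' \code{"independent"} mode every attribute is sampled from the one-pass
#' conditional given only the conditioning values -- faster, but draws are
#' independent across attributes given the conditioning.
#'
#' @param model a GenerativeModel
#' @param n number of records
#' @param conditioning named list of fixed attribute values
#' @param sampling \code{"sequential"} or \code{"independent"}
#' @param seed integer
#' @return a \code{SourceTable} of synthetic records (level types as level
#'   indices), labelled with the model version
#' @export
generateRecords <- function(model, n, conditioning = list(),
                            sampling = c("sequential", "independent"),
                            seed = 1L) {
  sampling <- match.arg(sampling)
  conditioning <- encodeObserved(model, conditioning, "conditioning")
  schema <- model@schema
  attrs <- attributeNames(schema)
  dts <- attributeDtypes(schema)
  m <- length(attrs)
  vals <- matrix(NA_real_, n, m, dimnames = list(NULL, attrs))
  tbl <- function() new("SourceTable",
                        label = paste0("synthetic-", model@versionName),
                        values = vals, mask = !is.na(vals),
                        dtypes = setNames(as.character(dts), attrs))
  if (n == 0) return(tbl())

  XEMB <- matrix(0, n, m, dimnames = list(NULL, attrs))
  OBS <- matrix(FALSE, n, m, dimnames = list(NULL, attrs))
  for (a in names(conditioning)) {
    v <- conditioning[[a]]
    vals[, a] <- v
    XEMB[, a] <- if (dts[[a]] %in% LEVEL_DTYPES) v
                 else standardizeValue(model@standardizers[[a]], v)
    OBS[, a] <- TRUE
  }
  free <- setdiff(attrs, names(conditioning))

  drawAttr <- function(a, heads) {
    sp <- headParams(model, heads, a)
    std <- model@standardizers[[a]]
    switch(dts[[a]],
      real = {
        z <- rnorm(n, mean = rep_len(sp$mean, n), sd = rep_len(sp$sd, n))
        list(nat = z * std$sd + std$mean, emb = z)
      },
      positive = {
        z <- rnorm(n, mean = rep_len(sp$mean, n), sd = rep_len(sp$sd, n))
        list(nat = exp(z * std$logSd + std$logMean), emb = z)
      },
      count = {
        kdraw <- rpois(n, rep_len(sp$rate, n))
        list(nat = kdraw, emb = standardizeValue(std, kdraw))
      },
      {
        p <- sp$probs
        if (nrow(p) == 1L) p <- p[rep(1L, n), , drop = FALSE]
        lev <- vapply(seq_len(n), function(i)
          sample.int(ncol(p), 1L, prob = p[i, ]), 1L)
        list(nat = as.numeric(lev), emb = as.numeric(lev))
      })
  }

  withSeed(seed, {
    if (sampling == "independent") {
      dr <- designRow(model, conditioning)
      heads <- modelForward(model, dr$XEMB, dr$OBS)$heads
      for (a in free) {
        dw <- drawAttr(a, heads)
        vals[, a] <- dw$nat
      }
    } else {
      order <- if (length(free)) sample(free) else character(0)
      for (a in order) {
        heads <- modelForwardChunked(model, XEMB, OBS)
        dw <- drawAttr(a, heads)
        vals[, a] <- dw$nat
        XEMB[, a] <- dw$emb
        OBS[, a] <- TRUE
      }
    }
  })
  tbl()
}

#' What-if (counterfactual) query
#'
#' Imputes the target under a baseline and under an intervention and
#' reports both distributions and the difference of their modes.  The
#' output is associative, not causal, and always carries the disclaimer.
#'
#' @param model a GenerativeModel
#' @param baseline named list of observed values
#' @param intervention named list of values overriding the baseline
#' @param target target attribute (must not appear in either map)
#' @return list: \code{baseline}, \code{counterfactual} (impute outputs),
#'   \code{delta} (mode difference; level targets: character change),
#'   \code{disclaimer}
#' @export
whatIf <- function(model, baseline, intervention, target) {
  if (target %in% c(names(baseline), names(intervention)))
    stopf("target '%s' must not be observed in either scenario", target)
  cf <- modifyList(baseline, intervention)
  b <- impute(model, baseline, target)[[target]]
  c2 <- impute(model, cf, target)[[target]]
  delta <- if (is.numeric(b$mode)) c2$mode - b$mode
           else paste(b$mode, "->", c2$mode)
  list(baseline = b, counterfactual = c2, delta = delta,
       disclaimer = WHATIF_DISCLAIMER)
}

#' Rank candidate predictors of a target attribute with the model
#'
#' Scores each candidate by the mean reduction in the target's negative
#' log-likelihood over a probe sample when that candidate alone is
#' observed, relative to observing nothing, and returns the top k.  This
#' is the model-driven screen used to pick the attributes conditioned on
#' during imputation benchmarking.
#'
#' @param model a GenerativeModel
#' @param corpus a TabularCorpus providing the probe sample
#' @param target target attribute
#' @param k number of predictors to return (default 10)
#' @param probeSize maximum probe records
#' @param seed probe subsampling seed
#' @return character vector of the top-k attribute names, best first
#' @export
rankPredictors <- function(model, corpus, target, k = 10L,
                           probeSize = 256L, seed = 1L) {
  if (k < 1) stopf("k must be >= 1")
  attrs <- attributeNames(model@schema)
  if (!target %in% attrs) stopf("unknown target attribute '%s'", target)
  dm <- designMatrices(withStandardizers(corpus, model@standardizers))
  tj <- match(target, attrs)
  rows <- which(dm$OBS[, tj])
  if (length(rows) == 0) stopf("target '%s' never observed in probe corpus",
                               target)
  rows <- withSeed(seed, {
    if (length(rows) > probeSize) sample(rows, probeSize) else rows
  })
  y <- dm$YTGT[rows, tj]
  B <- length(rows)
  m <- length(attrs)

  # unconditional params are identical for every record; evaluate per-y
  emptyHeads <- modelForward(model, matrix(0, 1, m),
                             matrix(FALSE, 1, m), targets = target)$heads
  o0 <- emptyHeads[[tj]]
  nll0 <- if (attributeDtypes(model@schema)[[tj]] %in% LEVEL_DTYPES) {
    -o0$logp[1, as.integer(y)]
  } else if (attributeDtypes(model@schema)[[tj]] == "count") {
    exp(o0$loglam[1]) - y * o0$loglam[1] + lgamma(y + 1)
  } else {
    0.5 * log(2 * pi) + o0$logsd[1] +
      (y - o0$mu[1])^2 / (2 * exp(2 * o0$logsd[1]))
  }

  candidates <- setdiff(attrs, target)
  scores <- setNames(rep(-Inf, length(candidates)), candidates)
  for (a in candidates) {
    cj <- match(a, attrs)
    use <- which(dm$OBS[rows, cj])
    if (length(use) < 3) next
    XEMB <- matrix(0, length(use), m)
    XEMB[, cj] <- dm$XEMB[rows[use], cj]
    OBS <- matrix(FALSE, length(use), m)
    OBS[, cj] <- TRUE
    heads <- modelForwardChunked(model, XEMB, OBS, targets = target)
    nllc <- targetNLLs(model, heads, target, y[use])
    scores[a] <- mean(nll0[use] - nllc)
  }
  if (k > length(candidates)) {
    jlog("rankPredictors.kTooLarge", k = k, candidates = length(candidates))
    k <- length(candidates)
  }
  names(sort(scores, decreasing = TRUE))[seq_len(k)]
}

# attach externally fitted standardizers to a corpus (e.g. evaluate a
# holdout corpus under the training-split transforms)
withStandardizers <- function(corpus, std) {
  S4Vectors::metadata(corpus)$standardizers <- std
  corpus
}
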