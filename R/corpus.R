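#' @include schema.R
NULL

#' Build a typed source table from a data.frame
#'
#' Character/factor columns of level-typed attributes are encoded as 1-based
#' level indices against the schema domain; numeric columns are checked
#' against their domain (positive values > 0, counts in the nonnegative
#' integers).  \code{NA} cells become missing.
#'
#' @param label source identifier
#' @param data data.frame, records x attributes
#' @param schema the ModelSchema declaring the column types
#' @return a \code{\linkS4class{SourceTable}}
#' @export
sourceTable <- function(label, data, schema) {
  attrs <- colnames(data)
  unknown <- setdiff(attrs, attributeNames(schema))
  if (length(unknown))
    stopf("source '%s' has attributes absent from the schema: %s",
          label, paste(unknown, collapse = ", "))
  dts <- attributeDtypes(schema)[attrs]
  vals <- matrix(NA_real_, nrow(data), length(attrs),
                 dimnames = list(NULL, attrs))
  for (a in attrs) {
    x <- data[[a]]
    if (dts[[a]] %in% LEVEL_DTYPES) {
      lev <- schemaLevels(schema, a)
      if (is.numeric(x)) {
        bad <- !is.na(x) & (x < 1 | x > length(lev) | x != floor(x))
        if (any(bad))
          stopf("source '%s', attribute '%s': level index out of range",
                label, a)
        vals[, a] <- as.numeric(x)
      } else {
        idx <- match(as.character(x), lev)
        bad <- !is.na(x) & is.na(idx)
        if (any(bad))
          stopf("source '%s', attribute '%s': value '%s' not in levels [%s]",
                label, a, as.character(x)[bad][1], paste(lev, collapse = ", "))
        vals[, a] <- as.numeric(idx)
      }
    } else {
      x <- as.numeric(x)
      if (dts[[a]] == "positive" && any(!is.na(x) & x <= 0))
        stopf("source '%s', attribute '%s': positive attribute has values <= 0",
              label, a)
      if (dts[[a]] == "count" && any(!is.na(x) & (x < 0 | x != floor(x))))
        stopf("source '%s', attribute '%s': counts must be nonnegative integers",
              label, a)
      bounds <- schema@domains[[a]]
      if (!is.null(bounds) && any(!is.na(x) & (x < bounds[1] | x > bounds[2])))
        stopf("source '%s', attribute '%s': value outside declared bounds",
              label, a)
      vals[, a] <- x
    }
  }
  new("SourceTable", label = label, values = vals, mask = !is.na(vals),
      dtypes = setNames(unname(dts), attrs))
}

#' Row-wise concatenation of source tables into one training corpus
#'
#' Each source record becomes one corpus record over the union attribute
#' set (schema order); attributes not measured in a record's source are
#' missing.  Common attributes stay observed wherever measured and act as
#' the implicit links between sources.
#'
#' @param tables list of \code{SourceTable}
#' @param schema the ModelSchema
#' @return a \code{\linkS4class{TabularCorpus}}
#' @export
concatSources <- function(tables, schema) {
  if (length(tables) == 0) stopf("no source tables given")
  dts <- attributeDtypes(schema)
  seen <- list()
  for (tb in tables) {
    for (a in attributeNames(tb)) {
      if (!a %in% names(dts))
        stopf("source '%s' has attribute '%s' absent from the schema",
              tb@label, a)
      declared <- tb@dtypes[[a]]
      if (!identical(declared, dts[[a]]))
        stopf("attribute '%s' declared as '%s' in source '%s' but '%s' in the schema",
              a, declared, tb@label, dts[[a]])
      if (!is.null(seen[[a]]) && !identical(seen[[a]], declared))
        stopf("attribute '%s' has conflicting dtypes across sources", a)
      seen[[a]] <- declared
    }
  }
  union_attrs <- intersect(attributeNames(schema),
                           unique(unlist(lapply(tables, attributeNames))))
  n <- sum(vapply(tables, nRecords, 0L))
  vals <- matrix(NA_real_, n, length(union_attrs),
                 dimnames = list(NULL, union_attrs))
  src <- character(n)
  at <- 0L
  for (tb in tables) {
    k <- nRecords(tb)
    if (k > 0) {
      rows <- (at + 1L):(at + k)
      cols <- attributeNames(tb)
      v <- tb@values
      v[!tb@mask] <- NA
      vals[rows, cols] <- v
      src[rows] <- tb@label
      at <- at + k
    }
  }
  newCorpus(vals, src, schema)
}

# Internal corpus constructor from a records x attributes matrix.
newCorpus <- function(vals, src, schema, roles = NULL, standardizers = NULL) {
  mask <- !is.na(vals)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = t(vals), mask = t(mask)),
    colData = S4Vectors::DataFrame(
      source = src,
      role = roles %||% rep("train", nrow(vals))),
    metadata = list(schema = schema, standardizers = standardizers))
  new("TabularCorpus", se)
}

# Subset a corpus by record index, keeping metadata.
corpusRecords <- function(corpus, idx, role = NULL) {
  vals <- corpusValues(corpus)[idx, , drop = FALSE]
  roles <- corpusRoles(corpus)[idx]
  if (!is.null(role)) roles <- rep(role, length(idx))
  newCorpus(vals, sourceLabels(corpus)[idx], corpusSchema(corpus),
            roles = roles, standardizers = corpusStandardizers(corpus))
}

#' Stratified holdout split
#'
#' Randomly selects a fraction of the records of each source as a holdout
#' set while maintaining the distributions of the stratification attributes
#' (sex and age by default; numeric strata are grouped into decades).  The
#' holdout is marked with role \code{"holdout"} and is refused by
#' \code{\link{trainModel}}.
#'
#' @param corpus a TabularCorpus
#' @param fraction holdout proportion in [0, 1); per stratum cell the
#'   holdout size is \code{round(fraction * cell size)}
#' @param strata attribute names to stratify on (those absent from the
#'   schema are ignored); a source in which a stratum attribute is entirely
#'   missing falls back to an unstratified split with a warning
#' @param seed integer
#' @return list with elements \code{train} and \code{holdout}
#' @export
splitHoldout <- function(corpus, fraction = 0.10,
                         strata = c("sex", "age"), seed = 1L) {
  if (fraction < 0 || fraction >= 1) stopf("fraction must lie in [0, 1)")
  strata <- intersect(strata, attributeNames(corpus))
  vals <- corpusValues(corpus)
  src <- sourceLabels(corpus)
  dts <- attributeDtypes(corpus)
  n <- nrow(vals)

  cellOf <- function(rows, useStrata) {
    if (length(useStrata) == 0) return(rep("all", length(rows)))
    parts <- lapply(useStrata, function(s) {
      v <- vals[rows, s]
      if (dts[[s]] %in% NUMERIC_DTYPES) {
        out <- ifelse(is.na(v), "NA", as.character(floor(v / 10) * 10))
      } else {
        out <- ifelse(is.na(v), "NA", as.character(v))
      }
      out
    })
    do.call(paste, c(parts, sep = "|"))
  }

  holdIdx <- integer(0)
  withSeed(seed, {
    for (s in unique(src)) {
      rows <- which(src == s)
      useStrata <- strata[vapply(strata, function(st)
        any(!is.na(vals[rows, st])), TRUE)]
      if (length(useStrata) < length(strata))
        warnf("source '%s': stratum attribute(s) %s entirely missing; %s",
              s, paste(setdiff(strata, useStrata), collapse = ", "),
              if (length(useStrata)) "stratifying on the rest"
              else "falling back to an unstratified split")
      cells <- cellOf(rows, useStrata)
      for (cl in unique(cells)) {
        cellRows <- rows[cells == cl]
        k <- round(fraction * length(cellRows))
        if (k > 0)
          holdIdx <- c(holdIdx, sample(cellRows, k))
      }
    }
  })
  holdIdx <- sort(holdIdx)
  trainIdx <- setdiff(seq_len(n), holdIdx)
  list(train = corpusRecords(corpus, trainIdx, role = "train"),
       holdout = corpusRecords(corpus, holdIdx, role = "holdout"))
}

#' Rebalance record counts per source
#'
#' Sources with fewer records than their target are up-sampled with
#' replacement; sources with more are down-sampled without replacement; a
#' target of zero removes the source.  Every adjusted record is a copy of
#' an original record -- no values are fabricated.
#'
#' @param corpus a TabularCorpus
#' @param targets named numeric vector or list, source label -> target count
#' @param seed integer
#' @export
adjustRecords <- function(corpus, targets, seed = 1L) {
  targets <- unlist(targets)
  src <- sourceLabels(corpus)
  unknown <- setdiff(names(targets), unique(src))
  if (length(unknown))
    stopf("unknown source label(s): %s", paste(unknown, collapse = ", "))
  if (any(targets < 0)) stopf("targets must be >= 0")
  keep <- integer(0)
  withSeed(seed, {
    for (s in unique(src)) {
      rows <- which(src == s)
      tgt <- if (s %in% names(targets)) targets[[s]] else length(rows)
      if (tgt == length(rows)) {
        keep <- c(keep, rows)
      } else if (tgt > length(rows)) {
        keep <- c(keep, rows, sample(rows, tgt - length(rows),
                                     replace = TRUE))
      } else if (tgt > 0) {
        keep <- c(keep, sample(rows, tgt))
      }
    }
  })
  corpusRecords(corpus, keep)
}

#' Fit per-attribute standardizers on the observed values of a corpus
#'
#' real: mean and unbiased SD on the raw scale; positive: mean and SD of the
#' log values; count: modeled on the raw scale (an auxiliary log1p location/
#' scale is kept for input embedding only); categorical and ordered
#' categorical: the schema level map.  The fitted transforms are stored in
#' the corpus metadata and reused verbatim at inference time.
#'
#' @param corpus a TabularCorpus (training split)
#' @param sdFloor smallest admissible SD; zero-variance attributes are
#'   floored here with a warning
#' @return the corpus with standardizers attached
#' @export
fitStandardizers <- function(corpus, sdFloor = 1e-6) {
  schema <- corpusSchema(corpus)
  vals <- corpusValues(corpus)
  dts <- attributeDtypes(schema)
  std <- list()
  for (a in attributeNames(corpus)) {
    x <- vals[, a]
    x <- x[!is.na(x)]
    dt <- dts[[a]]
    if (dt %in% c("real", "positive") && length(x) < 2)
      stopf("attribute '%s': need >= 2 observed values to standardize", a)
    std[[a]] <- switch(
      dt,
      real = {
        s <- sd(x)
        if (s < sdFloor) {
          warnf("attribute '%s': zero variance; SD floored at %g", a, sdFloor)
          s <- sdFloor
        }
        list(dtype = "real", mean = mean(x), sd = s)
      },
      positive = {
        if (any(x <= 0))
          stopf("attribute '%s': non-positive value in a positive attribute", a)
        lx <- log(x)
        s <- sd(lx)
        if (s < sdFloor) {
          warnf("attribute '%s': zero log-variance; SD floored at %g",
                a, sdFloor)
          s <- sdFloor
        }
        list(dtype = "positive", logMean = mean(lx), logSd = s)
      },
      count = {
        lx <- log1p(x)
        s <- max(sd(lx), sdFloor)
        list(dtype = "count", embMean = mean(lx), embSd = s)
      },
      list(dtype = dt, levels = schemaLevels(schema, a)))
  }
  S4Vectors::metadata(corpus)$standardizers <- std
  corpus
}

#' Standardize a natural-scale value for one attribute
#'
#' real -> (x - mean)/sd; positive -> (log x - logMean)/logSd; count ->
#' centered log1p (embedding scale); level types -> the level index itself.
#' @param std one attribute's standardizer entry
#' @param x numeric values (level indices for level types)
#' @export
standardizeValue <- function(std, x) {
  switch(std$dtype,
         real = (x - std$mean) / std$sd,
         positive = (log(x) - std$logMean) / std$logSd,
         count = (log1p(x) - std$embMean) / std$embSd,
         x)
}

#' Invert \code{standardizeValue}
#' @param std one attribute's standardizer entry
#' @param z standardized values
#' @export
unstandardizeValue <- function(std, z) {
  switch(std$dtype,
         real = z * std$sd + std$mean,
         positive = exp(z * std$logSd + std$logMean),
         count = expm1(z * std$embSd + std$embMean),
         z)
}
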