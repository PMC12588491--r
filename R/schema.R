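#' @include AllGenerics.R
NULL

#' Construct a model schema
#'
#' @param attributes list of per-attribute entries; each entry is a list with
#'   \code{name}, \code{dtype} (one of real, positive, count, categorical,
#'   ordered_categorical), \code{sources} (character), and optionally
#'   \code{levels} (required for level types; order carries meaning for
#'   ordered_categorical), \code{bounds} (numeric length 2),
#'   \code{field_category}, \code{units}.
#' @return a validated \code{\linkS4class{ModelSchema}}; attribute order
#'   equals input order.
#' @export
modelSchema <- function(attributes) {
  if (length(attributes) == 0) stopf("schema needs at least one attribute")
  nm <- vapply(attributes, function(a) as.character(a$name %||% NA), "")
  dt <- vapply(attributes, function(a) as.character(a$dtype %||% NA), "")
  if (anyNA(nm)) stopf("every schema attribute needs a name")
  bad <- which(!dt %in% ATTRIBUTE_DTYPES)
  if (length(bad))
    stopf("attribute '%s' has unknown dtype '%s' (allowed: %s)",
          nm[bad[1]], dt[bad[1]], paste(ATTRIBUTE_DTYPES, collapse = ", "))
  specs <- data.frame(
    name = nm, dtype = dt,
    field_category = vapply(attributes, function(a)
      as.character(a$field_category %||% ""), ""),
    units = vapply(attributes, function(a) as.character(a$units %||% ""), ""),
    stringsAsFactors = FALSE)
  domains <- setNames(lapply(attributes, function(a) {
    if (a$dtype %in% LEVEL_DTYPES) {
      lev <- a$levels
      if (is.null(lev))
        stopf("attribute '%s' (%s) must declare its levels%s", a$name,
              a$dtype,
              if (a$dtype == "ordered_categorical") " in order" else "")
      as.character(lev)
    } else if (!is.null(a$bounds)) as.numeric(a$bounds) else NULL
  }), nm)
  srcMap <- setNames(lapply(attributes, function(a)
    as.character(a$sources %||% "default")), nm)
  new("ModelSchema", specs = specs, domains = domains, srcMap = srcMap)
}

#' Load a model schema from YAML or JSON
#'
#' The file holds a top-level \code{attributes} list in the
#' \code{\link{modelSchema}} layout.  Attribute order in the file is
#' preserved.
#'
#' @param path file path ending in .yaml/.yml or .json
#' @return a \code{ModelSchema}
#' @export
loadSchema <- function(path) {
  if (!file.exists(path)) stopf("schema file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                       simplifyVector = TRUE)
  } else stopf("schema file must be YAML or JSON: %s", path)
  attrs <- raw$attributes %||% raw
  modelSchema(attrs)
}

#' Write a model schema to YAML or JSON
#' @param schema a ModelSchema
#' @param path destination (.yaml/.yml or .json)
#' @export
saveSchema <- function(schema, path) {
  entries <- lapply(seq_len(nrow(schema@specs)), function(i) {
    sp <- schema@specs[i, ]
    e <- list(name = sp$name, dtype = sp$dtype,
              sources = as.list(schema@srcMap[[sp$name]]))
    dom <- schema@domains[[sp$name]]
    if (sp$dtype %in% LEVEL_DTYPES) e$levels <- as.list(dom)
    else if (!is.null(dom)) e$bounds <- as.list(dom)
    if (nzchar(sp$field_category)) e$field_category <- sp$field_category
    if (nzchar(sp$units)) e$units <- sp$units
    e
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(attributes = entries), path,
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(list(attributes = entries), path)
  }
  invisible(path)
}

#' Restrict a schema to a subset of attributes (order preserved)
#' @param schema a ModelSchema
#' @param keep character vector of attribute names
#' @export
subsetSchema <- function(schema, keep) {
  keep <- intersect(schema@specs$name, keep)
  new("ModelSchema",
      specs = schema@specs[schema@specs$name %in% keep, , drop = FALSE],
      domains = schema@domains[keep],
      srcMap = schema@srcMap[keep])
}

#' Screen schema attributes by missingness and dependence
#'
#' Applies the attribute-selection criteria: attributes with a high
#' within-source missing rate are excluded, and attributes showing minimal
#' association with every other attribute contribute little to joint
#' estimation and are excluded.  The association screen uses the absolute
#' Spearman rank correlation for pairs of numeric, ordinal, and binary
#' attributes, and a Cramer's V contingency association when a nominal
#' attribute with more than two levels is involved (numeric partners are
#' discretized into quartiles).  Common (linking) attributes are never
#' dropped.  Both screens are computed on the full input schema, so raising
#' \code{maxMissingRate} can only enlarge the kept set.
#'
#' @param schema a ModelSchema
#' @param corpus a TabularCorpus whose columns are a subset of the schema
#' @param maxMissingRate highest tolerated within-source missing rate
#' @param minDependence smallest tolerated maximum absolute pairwise
#'   association
#' @return the filtered sub-schema
#' @export
selectAttributes <- function(schema, corpus, maxMissingRate = 1.0,
                             minDependence = 0.0) {
  if (maxMissingRate < 0 || maxMissingRate > 1 ||
      minDependence < 0 || minDependence > 1)
    stopf("thresholds must lie in [0, 1]")
  attrs <- attributeNames(schema)
  if (!all(attributeNames(corpus) %in% attrs))
    stopf("corpus contains attributes absent from the schema")
  attrs <- intersect(attrs, attributeNames(corpus))
  mask <- corpusMask(corpus)
  src <- sourceLabels(corpus)

  missRate <- vapply(attrs, function(a) {
    rows <- src %in% schemaSources(schema, a)
    if (!any(rows)) return(1)
    1 - mean(mask[rows, a])
  }, 0)

  assoc <- pairwiseAssociation(corpus, attrs, schema)
  maxAssoc <- apply(assoc, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r)) max(r) else 0
  })

  common <- commonAttributes(schema)
  keep <- attrs[(missRate <= maxMissingRate & maxAssoc >= minDependence) |
                  attrs %in% common]
  subsetSchema(schema, union(keep, setdiff(attributeNames(schema),
                                           attributeNames(corpus))))
}

#' Pairwise association matrix used by the attribute screen
#'
#' Spearman for numeric/ordinal/binary pairs; Cramer's V otherwise.  The
#' diagonal is NA.
#' @noRd
pairwiseAssociation <- function(corpus, attrs, schema) {
  vals <- corpusValues(corpus)[, attrs, drop = FALSE]
  dts <- attributeDtypes(schema)[attrs]
  nominal <- vapply(attrs, function(a)
    dts[[a]] == "categorical" && length(schemaLevels(schema, a)) > 2,
    TRUE)
  m <- length(attrs)
  out <- matrix(NA_real_, m, m, dimnames = list(attrs, attrs))
  if (m < 2) return(out)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    ok <- !is.na(vals[, i]) & !is.na(vals[, j])
    if (sum(ok) < 10) next
    x <- vals[ok, i]; y <- vals[ok, j]
    a <- if (nominal[i] || nominal[j]) {
      cramersV(discretize4(x, nominal[i]), discretize4(y, nominal[j]))
    } else {
      suppressWarnings(abs(stats::cor(x, y, method = "spearman")))
    }
    out[i, j] <- out[j, i] <- a
  }
  out
}

discretize4 <- function(x, isNominal) {
  if (isNominal || length(unique(x)) <= 4) return(factor(x))
  q <- unique(quantile(x, probs = c(0.25, 0.5, 0.75)))
  factor(findInterval(x, q))
}

cramersV <- function(f1, f2) {
  tab <- table(f1, f2)
  if (min(dim(tab)) < 2) return(0)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  n <- sum(tab)
  sqrt(as.numeric(chi2) / (n * (min(dim(tab)) - 1)))
}
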