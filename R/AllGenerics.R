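#' @include AllClasses.R
NULL

#' Attribute names, in schema order
#' @param x a ModelSchema, TabularCorpus, or SourceTable
#' @export
setGeneric("attributeNames", function(x) standardGeneric("attributeNames"))

#' Declared dtypes, as a named character vector
#' @param x a ModelSchema or TabularCorpus
#' @export
setGeneric("attributeDtypes", function(x) standardGeneric("attributeDtypes"))

#' Attributes measured in two or more sources
#' @param x a ModelSchema
#' @export
setGeneric("commonAttributes", function(x) standardGeneric("commonAttributes"))

#' Number of records
#' @param x a TabularCorpus or SourceTable
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' Per-record source labels
#' @param x a TabularCorpus or SourceTable
#' @export
setGeneric("sourceLabels", function(x) standardGeneric("sourceLabels"))

#' True conditional distribution under a ground-truth oracle
#'
#' Evaluates the conditional distribution of \code{target} given observed
#' attribute values under the known generating process: exactly where a
#' closed form exists (jointly Gaussian sub-case; discrete chain
#' enumeration), otherwise by self-normalized importance sampling over the
#' latent factors, with a Monte-Carlo standard error.
#'
#' @param oracle a \code{GroundTruthOracle}
#' @param target attribute name
#' @param given named list of conditioning attribute values (may be empty)
#' @param nMC Monte-Carlo sample size (ignored where exact evaluation is
#'   available and \code{method = "exact"})
#' @param seed integer RNG seed for the Monte-Carlo path
#' @param method \code{"auto"} (exact where possible), \code{"exact"}, or
#'   \code{"mc"}
#' @return list with elements \code{mean}, \code{sd} (numeric targets) or
#'   \code{probs} (level targets), \code{se} (Monte-Carlo standard error; 0
#'   for exact answers) and \code{method}
#' @export
setGeneric("trueConditional",
           function(oracle, target, given = list(), nMC = 20000L,
                    seed = 1L, method = c("auto", "exact", "mc"))
             standardGeneric("trueConditional"))

## ---- ModelSchema accessors ----

#' @rdname attributeNames
#' @export
setMethod("attributeNames", "ModelSchema", function(x) x@specs$name)

#' @rdname attributeDtypes
#' @export
setMethod("attributeDtypes", "ModelSchema",
          function(x) setNames(x@specs$dtype, x@specs$name))

#' @rdname commonAttributes
#' @export
setMethod("commonAttributes", "ModelSchema", function(x) {
  x@specs$name[vapply(x@srcMap[x@specs$name], length, 1L) >= 2]
})

#' Levels of a categorical or ordered categorical attribute
#' @param schema a ModelSchema
#' @param attribute attribute name
#' @export
schemaLevels <- function(schema, attribute) {
  dt <- attributeDtypes(schema)[[attribute]]
  if (!dt %in% LEVEL_DTYPES) return(NULL)
  schema@domains[[attribute]]
}

#' Sources in which an attribute is measured
#' @inheritParams schemaLevels
#' @export
schemaSources <- function(schema, attribute) schema@srcMap[[attribute]]

setMethod("show", "ModelSchema", function(object) {
  cat(sprintf("ModelSchema: %d attributes over %d source(s)\n",
              nrow(object@specs), length(unique(unlist(object@srcMap)))))
  tab <- table(factor(object@specs$dtype, levels = ATTRIBUTE_DTYPES))
  cat("  types:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat("  common attributes:",
      paste(commonAttributes(object), collapse = ", "), "\n")
})

## ---- SourceTable / TabularCorpus accessors ----

#' @rdname attributeNames
#' @export
setMethod("attributeNames", "SourceTable", function(x) colnames(x@values))

#' @rdname nRecords
#' @export
setMethod("nRecords", "SourceTable", function(x) nrow(x@values))

#' @rdname sourceLabels
#' @export
setMethod("sourceLabels", "SourceTable",
          function(x) rep(x@label, nrow(x@values)))

setMethod("show", "SourceTable", function(object) {
  cat(sprintf("SourceTable '%s': %d records x %d attributes (%.1f%% observed)\n",
              object@label, nrow(object@values), ncol(object@values),
              100 * mean(object@mask)))
})

#' @rdname attributeNames
#' @export
setMethod("attributeNames", "TabularCorpus", function(x) rownames(x))

#' @rdname attributeDtypes
#' @export
setMethod("attributeDtypes", "TabularCorpus",
          function(x) attributeDtypes(corpusSchema(x)))

#' @rdname nRecords
#' @export
setMethod("nRecords", "TabularCorpus", function(x) ncol(x))

#' @rdname sourceLabels
#' @export
setMethod("sourceLabels", "TabularCorpus",
          function(x) SummarizedExperiment::colData(x)$source)

#' Corpus values as a records x attributes matrix (natural scale, NA missing)
#' @param x a TabularCorpus
#' @export
corpusValues <- function(x) t(SummarizedExperiment::assay(x, "values"))

#' Corpus observation mask as a records x attributes logical matrix
#' @param x a TabularCorpus
#' @export
corpusMask <- function(x) {
  m <- t(SummarizedExperiment::assay(x, "mask"))
  storage.mode(m) <- "logical"
  m
}

#' The schema a corpus was built under
#' @param x a TabularCorpus
#' @export
corpusSchema <- function(x) S4Vectors::metadata(x)$schema

#' Fitted per-attribute standardizers (NULL before fitStandardizers)
#' @param x a TabularCorpus
#' @export
corpusStandardizers <- function(x) S4Vectors::metadata(x)$standardizers

#' Per-record role labels ("train" or "holdout")
#' @param x a TabularCorpus
#' @export
corpusRoles <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("role" %in% colnames(cd)) cd$role else rep("train", ncol(x))
}

setMethod("show", "TabularCorpus", function(object) {
  cat(sprintf("TabularCorpus: %d records x %d attributes\n",
              ncol(object), nrow(object)))
  src <- table(sourceLabels(object))
  cat("  sources:", paste(sprintf("%s (n=%d)", names(src), src),
                          collapse = ", "), "\n")
  cat(sprintf("  observed cells: %.1f%%; standardizers %s\n",
              100 * mean(SummarizedExperiment::assay(object, "mask")),
              if (is.null(corpusStandardizers(object))) "not fitted"
              else "fitted"))
})

setMethod("show", "GenerativeModel", function(object) {
  np <- sumLeaves(object@params, length)
  cat(sprintf("GenerativeModel '%s': %d attributes, %s parameters\n",
              object@versionName, nrow(object@schema@specs),
              format(np, big.mark = ",")))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs; final loss %.4f\n",
                nrow(object@history),
                object@history$loss[nrow(object@history)]))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  if (nrow(object@aggregate)) {
    cat("  aggregate:\n")
    print(object@aggregate, row.names = FALSE)
  } else if (nrow(object@perAttribute)) {
    cat(sprintf("  %d per-attribute records\n", nrow(object@perAttribute)))
  }
})

#' Per-attribute rows of an evaluation report
#' @param x an EvaluationReport
#' @export
reportAttributes <- function(x) x@perAttribute

#' Per-pair rows of an evaluation report
#' @param x an EvaluationReport
#' @export
reportPairs <- function(x) x@perPair

#' Aggregate rows of an evaluation report
#' @param x an EvaluationReport
#' @export
reportAggregate <- function(x) x@aggregate
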