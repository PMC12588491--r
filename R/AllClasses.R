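#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Typed attribute catalogue for the generative model
#'
#' A \code{ModelSchema} maps every attribute to one of the five supported
#' types (\code{real}, \code{positive}, \code{count}, \code{categorical},
#' \code{ordered_categorical}), its domain, and the source tables in which
#' it is measured.  It drives tokenization, the typed likelihood heads, and
#' decoding throughout the package.
#'
#' @slot specs data.frame with columns \code{name}, \code{dtype},
#'   \code{field_category}, \code{units}, in schema (file) order.
#' @slot domains named list; per attribute either a character vector of
#'   levels (order meaningful for \code{ordered_categorical}) or a numeric
#'   length-2 bounds vector (or \code{NULL}) for numeric types.
#' @slot srcMap named list mapping each attribute to the character vector of
#'   source labels in which it is measured.
#' @export
setClass("ModelSchema",
         representation(specs = "data.frame", domains = "list",
                        srcMap = "list"))

validModelSchema <- function(object) {
  sp <- object@specs
  msgs <- character(0)
  if (nrow(sp) == 0) msgs <- c(msgs, "schema has no attributes")
  if (anyDuplicated(sp$name))
    msgs <- c(msgs, sprintf("duplicate attribute name(s): %s",
                            paste(unique(sp$name[duplicated(sp$name)]),
                                  collapse = ", ")))
  bad <- !sp$dtype %in% ATTRIBUTE_DTYPES
  if (any(bad))
    msgs <- c(msgs, sprintf(
      "attribute '%s' has unknown dtype '%s' (allowed: %s)",
      sp$name[bad][1], sp$dtype[bad][1],
      paste(ATTRIBUTE_DTYPES, collapse = ", ")))
  for (i in seq_len(nrow(sp))) {
    nm <- sp$name[i]; dt <- sp$dtype[i]; dom <- object@domains[[nm]]
    if (dt %in% LEVEL_DTYPES) {
      if (length(dom) < 2)
        msgs <- c(msgs, sprintf("attribute '%s' (%s) needs >= 2 levels",
                                nm, dt))
    } else if (!is.null(dom)) {
      if (length(dom) != 2 || dom[1] >= dom[2])
        msgs <- c(msgs, sprintf("attribute '%s': bounds must be (lo, hi)", nm))
      if (dt == "positive" && dom[1] <= 0)
        msgs <- c(msgs, sprintf(
          "attribute '%s': positive-type bounds must be > 0", nm))
    }
    srcs <- object@srcMap[[nm]]
    if (length(srcs) < 1)
      msgs <- c(msgs, sprintf("attribute '%s' belongs to no source", nm))
  }
  # every pair of sources must be linked, directly or transitively, by a
  # common attribute
  allSrc <- unique(unlist(object@srcMap))
  if (length(allSrc) > 1 && length(msgs) == 0) {
    comp <- seq_along(allSrc)
    names(comp) <- allSrc
    for (srcs in object@srcMap) {
      if (length(srcs) > 1) {
        cs <- comp[srcs]
        comp[comp %in% cs] <- min(cs)
      }
    }
    if (length(unique(comp)) > 1)
      msgs <- c(msgs,
                "sources are not linked by common attributes (disconnected)")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("ModelSchema", validModelSchema)

#' One source table: typed values plus an observation mask
#'
#' Values are stored on the natural scale; categorical and ordered
#' categorical cells hold 1-based level indices.  \code{mask} is TRUE where
#' the cell was observed.
#'
#' @slot label character source identifier.
#' @slot values numeric matrix, records x attributes.
#' @slot mask logical matrix congruent with \code{values}.
#' @slot dtypes named character vector of declared column dtypes.
#' @export
setClass("SourceTable",
         representation(label = "character", values = "matrix",
                        mask = "matrix", dtypes = "character"))

setValidity("SourceTable", function(object) {
  msgs <- character(0)
  if (!identical(dim(object@values), dim(object@mask)))
    msgs <- c(msgs, "values and mask dimensions differ")
  if (is.null(colnames(object@values)))
    msgs <- c(msgs, "values must have attribute column names")
  if (any(is.na(object@values) & object@mask))
    msgs <- c(msgs, "mask marks NA cells as observed")
  if (length(msgs)) msgs else TRUE
})

#' Concatenated multi-source training corpus
#'
#' Extends \code{SummarizedExperiment}: rows are attributes (schema order),
#' columns are records.  Assays \code{values} (numeric, NA = missing) and
#' \code{mask} (logical).  \code{colData} carries the per-record
#' \code{source} label and a \code{role} column (\code{"train"} or
#' \code{"holdout"}).  Metadata holds the \code{ModelSchema} and, once
#' fitted, the per-attribute standardizers.
#' @export
setClass("TabularCorpus", contains = "SummarizedExperiment")

setValidity("TabularCorpus", function(object) {
  msgs <- character(0)
  an <- names(SummarizedExperiment::assays(object))
  if (!all(c("values", "mask") %in% an))
    msgs <- c(msgs, "assays 'values' and 'mask' are required")
  if (!"source" %in% colnames(SummarizedExperiment::colData(object)))
    msgs <- c(msgs, "colData must contain a 'source' column")
  if (is.null(S4Vectors::metadata(object)$schema))
    msgs <- c(msgs, "metadata must contain the ModelSchema")
  if (length(msgs) == 0) {
    v <- SummarizedExperiment::assay(object, "values")
    m <- SummarizedExperiment::assay(object, "mask")
    if (any(m & is.na(v)))
      msgs <- c(msgs, "observed cells (mask TRUE) must not be NA")
    if (any(!m & !is.na(v)))
      msgs <- c(msgs, "missing cells (mask FALSE) must be NA")
  }
  if (length(msgs)) msgs else TRUE
})

#' Latent-factor cohort simulation configuration
#'
#' Records are generated from a shared multivariate standard-normal latent
#' vector: each attribute applies a link to a linear score
#' \code{loading %*% z + intercept + noise}.  Source blocks and per-attribute
#' MCAR missingness are applied afterwards.
#'
#' @slot nRecords named numeric, records per source.
#' @slot latentDim integer latent dimension.
#' @slot attrs named list of per-attribute generator specs (see
#'   \code{\link{simAttr}}).
#' @slot sourceBlocks named list mapping source label to its attribute set.
#' @slot commonAttributes character, attributes present in every block.
#' @slot missingRate named numeric, per-attribute MCAR rate within blocks.
#' @slot seed integer.
#' @export
setClass("SimulationConfig",
         representation(nRecords = "numeric", latentDim = "integer",
                        attrs = "list", sourceBlocks = "list",
                        commonAttributes = "character",
                        missingRate = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  for (src in names(object@sourceBlocks)) {
    blk <- object@sourceBlocks[[src]]
    if (!all(object@commonAttributes %in% blk))
      msgs <- c(msgs, sprintf(
        "source '%s' lacks designated common attribute(s)", src))
    if (!all(blk %in% names(object@attrs)))
      msgs <- c(msgs, sprintf("source '%s' references unknown attributes", src))
  }
  for (nm in names(object@attrs)) {
    a <- object@attrs[[nm]]
    if (a$dtype == "ordered_categorical" &&
        is.unsorted(a$thresholds, strictly = TRUE))
      msgs <- c(msgs, sprintf(
        "attribute '%s': ordinal thresholds must be strictly increasing", nm))
    if (a$dtype == "count") {
      peak <- a$intercept + sum(abs(a$loading)) * 6 # ~6 SD latent excursion
      if (!is.finite(exp(peak)))
        msgs <- c(msgs, sprintf(
          "attribute '%s': log-link Poisson rate overflows", nm))
    }
  }
  if (any(object@missingRate < 0 | object@missingRate > 1))
    msgs <- c(msgs, "missing rates must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Ground-truth oracle over a known generating process
#'
#' Virtual parent of \code{LatentFactorOracle} (shares parameters with
#' \code{\link{simulatePopulation}}) and \code{DiscreteChainOracle}
#' (a small discrete X -> Z -> Y chain, exact by enumeration).  Both answer
#' \code{\link{trueConditional}} queries, realizing the marginalization
#' identity P(Y|X) = integral P(Y|Z) P(Z|X) dz that justifies statistical
#' linkage through common attributes.
#' @export
setClass("GroundTruthOracle", representation("VIRTUAL"))

#' @rdname GroundTruthOracle-class
#' @slot config the \code{SimulationConfig} shared with the simulator.
#' @export
setClass("LatentFactorOracle", contains = "GroundTruthOracle",
         representation(config = "SimulationConfig"))

#' @rdname GroundTruthOracle-class
#' @slot pX1 P(X = 1).
#' @slot pZ1gX length-2 vector: P(Z=1 | X=0), P(Z=1 | X=1).
#' @slot pY1gZ length-2 vector: P(Y=1 | Z=0), P(Y=1 | Z=1).
#' @export
setClass("DiscreteChainOracle", contains = "GroundTruthOracle",
         representation(pX1 = "numeric", pZ1gX = "numeric",
                        pY1gZ = "numeric"))

setValidity("DiscreteChainOracle", function(object) {
  p <- c(object@pX1, object@pZ1gX, object@pY1gZ)
  if (length(object@pZ1gX) != 2 || length(object@pY1gZ) != 2)
    return("conditional tables must have two entries (given 0, given 1)")
  if (any(p < 0 | p > 1)) return("probabilities must lie in [0, 1]")
  TRUE
})

#' Attention-network architecture configuration
#'
#' @slot embedDim token embedding dimension.
#' @slot encLayers number of encoder attention blocks.
#' @slot decLayers number of decoder attention blocks.
#' @slot heads attention heads (must divide \code{embedDim}).
#' @slot ffDim feed-forward hidden dimension.
#' @slot dropout dropout rate applied during training only.
#' @slot passes decoding passes: 1 = single pass; 2 = iterative decoding
#'   with gated feedback of imputed value tokens (the default; required for
#'   cross-source linkage).
#' @slot seed weight-initialization seed.
#' @export
setClass("NetworkConfig",
         representation(embedDim = "integer", encLayers = "integer",
                        decLayers = "integer", heads = "integer",
                        ffDim = "integer", dropout = "numeric",
                        passes = "integer", seed = "integer"))

setValidity("NetworkConfig", function(object) {
  msgs <- character(0)
  dims <- c(object@embedDim, object@encLayers, object@decLayers,
            object@heads, object@ffDim)
  if (any(dims < 1)) msgs <- c(msgs, "all dimensions must be positive")
  if (object@embedDim %% object@heads != 0)
    msgs <- c(msgs, "heads must divide embedDim")
  if (object@dropout < 0 || object@dropout >= 1)
    msgs <- c(msgs, "dropout must lie in [0, 1)")
  if (!object@passes %in% c(1L, 2L))
    msgs <- c(msgs, "passes must be 1 or 2")
  if (length(msgs)) msgs else TRUE
})

#' Masked-modeling training configuration
#'
#' @slot maskRate fraction of observed cells hidden per record (each record
#'   keeps at least one reconstruction target).
#' @slot epochsStage1 epochs per source in the per-source stage.
#' @slot epochsStage2 epochs on the combined corpus.
#' @slot batchSize records per gradient step.
#' @slot learningRate Adam peak learning rate (cosine-decayed).
#' @slot stageOrder source labels for stage 1, then \code{"combined"}.
#' @slot clipNorm global gradient-norm clip.
#' @slot weightDecay decoupled weight decay on weight matrices and
#'   embeddings (keeps the per-attribute encoder and head scales balanced,
#'   which the cross-source linkage behavior relies on).
#' @slot seed training seed (shuffling, masking, dropout).
#' @export
setClass("TrainingConfig",
         representation(maskRate = "numeric", epochsStage1 = "integer",
                        epochsStage2 = "integer", batchSize = "integer",
                        learningRate = "numeric", stageOrder = "character",
                        clipNorm = "numeric", weightDecay = "numeric",
                        seed = "integer"))

setValidity("TrainingConfig", function(object) {
  msgs <- character(0)
  if (!length(object@maskRate) %in% c(1L, 2L) ||
      any(object@maskRate <= 0 | object@maskRate > 1))
    msgs <- c(msgs, "maskRate must lie in (0, 1] (scalar or length-2 range)")
  if (object@epochsStage1 < 0 || object@epochsStage2 < 0)
    msgs <- c(msgs, "epochs must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Trained generative model (checkpoint)
#'
#' Bundles the network weights with everything needed to reuse them:
#' architecture, schema (hash-stamped), standardizers fitted on the training
#' split, the per-epoch loss history, and a version name (model releases are
#' named after stars).
#' @slot params nested list of weight arrays.
#' @slot netConfig \code{NetworkConfig}.
#' @slot schema \code{ModelSchema}.
#' @slot standardizers named list of per-attribute transform parameters.
#' @slot history data.frame of per-epoch losses per stage.
#' @slot trainedAttributes named logical; TRUE for attributes the model saw
#'   observed values of during training.  Only these may feed imputed value
#'   tokens back in the second decoding pass; an attribute added to the
#'   schema but never trained contributes nothing at inference.
#' @slot versionName character.
#' @export
setClass("GenerativeModel",
         representation(params = "list", netConfig = "NetworkConfig",
                        schema = "ModelSchema", standardizers = "list",
                        history = "data.frame",
                        trainedAttributes = "logical",
                        versionName = "character"))

#' Quality-suite evaluation report
#'
#' @slot perAttribute data.frame of per-attribute metric records.
#' @slot perPair data.frame of per-pair bivariate records.
#' @slot aggregate data.frame of per-dtype (or overall) summaries.
#' @slot info list of free-form provenance (model version, settings).
#' @export
setClass("EvaluationReport",
         representation(perAttribute = "data.frame", perPair = "data.frame",
                        aggregate = "data.frame", info = "list"))

setValidity("EvaluationReport", function(object) {
  num <- c(object@perAttribute$value, object@perPair$value,
           object@aggregate$value)
  if (length(num) && any(!is.finite(num)))
    return("metric values must be finite")
  TRUE
})
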