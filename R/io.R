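#' @include quality.R
NULL

#' Read a source table from CSV/TSV
#'
#' Missing cells are empty strings or \code{NA}; level-typed columns may
#' hold level names or 1-based indices.
#'
#' @param path file (.csv or .tsv)
#' @param schema a ModelSchema
#' @param label source label (default: file base name)
#' @export
readSourceTable <- function(path, schema, label = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  sourceTable(label %||% sub("\\.[^.]*$", "", basename(path)), df, schema)
}

#' Write a source table to CSV (level types as level names)
#' @param table a SourceTable
#' @param schema a ModelSchema (level decoding)
#' @param path destination
#' @export
writeSourceTable <- function(table, schema, path) {
  v <- table@values
  v[!table@mask] <- NA
  df <- as.data.frame(v)
  for (a in colnames(df)) {
    if (a %in% attributeNames(schema) &&
        attributeDtypes(schema)[[a]] %in% LEVEL_DTYPES)
      df[[a]] <- schemaLevels(schema, a)[df[[a]]]
  }
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize a corpus to a directory (values.csv + meta.json sidecar)
#' @param corpus a TabularCorpus
#' @param dir destination directory (created)
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vals <- corpusValues(corpus)
  write.csv(as.data.frame(vals), file.path(dir, "values.csv"),
            row.names = FALSE, na = "")
  schema <- corpusSchema(corpus)
  tmp <- tempfile(fileext = ".json")
  saveSchema(schema, tmp)
  meta <- list(source = sourceLabels(corpus), role = corpusRoles(corpus),
               schema = jsonlite::fromJSON(tmp, simplifyVector = FALSE),
               standardizers = corpusStandardizers(corpus),
               schema_hash = shortHash(schema@specs),
               producer = paste0("HetTabGen ",
                                 as.character(utils::packageVersion("HetTabGen"))))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a corpus directory written by \code{\link{writeCorpus}}
#' @param dir corpus directory
#' @export
readCorpus <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"),
                             simplifyVector = FALSE)
  schema <- modelSchema(meta$schema$attributes)
  df <- read.csv(file.path(dir, "values.csv"), stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  vals <- as.matrix(df)
  storage.mode(vals) <- "double"
  colnames(vals) <- colnames(df)
  std <- meta$standardizers
  if (!is.null(std))
    std <- lapply(std, function(s) {
      s[c("mean", "sd", "logMean", "logSd", "embMean", "embSd")] <-
        lapply(s[c("mean", "sd", "logMean", "logSd", "embMean", "embSd")],
               function(v) if (is.null(v)) NULL else as.numeric(v))
      s$levels <- if (is.null(s$levels)) NULL else as.character(s$levels)
      s
    })
  newCorpus(vals, unlist(meta$source), schema,
            roles = unlist(meta$role), standardizers = std)
}

#' Save a trained model checkpoint
#' @param model a GenerativeModel
#' @param path destination (.rds)
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  jlog("saveModel", path = path, version = model@versionName,
       schema_hash = shortHash(model@schema@specs))
  invisible(path)
}

#' Load a model checkpoint
#' @param path .rds path from \code{\link{saveModel}}
#' @export
readModel <- function(path) {
  m <- readRDS(path)
  if (!is(m, "GenerativeModel")) stopf("not a GenerativeModel checkpoint")
  m
}

#' Register a model checkpoint in a local registry directory
#'
#' The registry is a directory of named checkpoints plus a
#' \code{manifest.json} recording version name, schema hash, parameter
#' count, and registration time.
#'
#' @param model a GenerativeModel
#' @param dir registry directory (created if needed)
#' @return the checkpoint path, invisibly
#' @export
registerModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(model@versionName, ".rds"))
  saveModel(model, path)
  manifestPath <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifestPath))
    jsonlite::fromJSON(manifestPath, simplifyVector = FALSE) else list()
  manifest[[model@versionName]] <- list(
    version = model@versionName,
    file = basename(path),
    schema_hash = shortHash(model@schema@specs),
    attributes = nrow(model@schema@specs),
    parameters = sumLeaves(model@params, length),
    registered = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' List the models registered in a registry directory
#' @param dir registry directory
#' @return data.frame with one row per registered version
#' @export
listModels <- function(dir) {
  manifestPath <- file.path(dir, "manifest.json")
  if (!file.exists(manifestPath))
    return(data.frame(version = character(0), file = character(0),
                      schema_hash = character(0), attributes = integer(0),
                      parameters = integer(0), registered = character(0)))
  manifest <- jsonlite::fromJSON(manifestPath, simplifyVector = FALSE)
  do.call(rbind, lapply(manifest, function(e)
    data.frame(version = e$version, file = e$file,
               schema_hash = e$schema_hash,
               attributes = as.integer(e$attributes),
               parameters = as.integer(e$parameters),
               registered = e$registered)))
}

#' Read a simulation configuration from YAML
#'
#' Layout: top-level \code{nRecords} (map), \code{latentDim}, \code{seed},
#' \code{missingRate}, \code{common}, \code{sourceBlocks} (map), and
#' \code{attributes}: a list of \code{\link{simAttr}} fields (categorical
#' loadings as a list of per-level rows).
#' @param path YAML file
#' @export
readSimulationConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  attrs <- lapply(raw$attributes, function(a) {
    loading <- if (a$dtype == "categorical")
      do.call(rbind, lapply(a$loading, as.numeric))
    else as.numeric(a$loading)
    simAttr(a$name, a$dtype, loading, noise = a$noise %||% 0.5,
            intercept = as.numeric(a$intercept %||% 0),
            levels = if (!is.null(a$levels)) as.character(a$levels),
            thresholds = if (!is.null(a$thresholds))
              as.numeric(a$thresholds))
  })
  simulationConfig(
    nRecords = unlist(raw$nRecords), latentDim = raw$latentDim,
    attrs = attrs,
    sourceBlocks = lapply(raw$sourceBlocks, as.character),
    common = as.character(raw$common %||% character(0)),
    missingRate = if (is.null(raw$missingRate)) 0 else unlist(raw$missingRate),
    seed = raw$seed %||% 1L)
}
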