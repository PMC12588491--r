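#' @include backprop.R
NULL

#' Masked-modeling training configuration
#'
#' @param maskRate probability that each observed cell of a record becomes
#'   a reconstruction target (at least one target per record is enforced)
#' @param epochsStage1 epochs per source during the per-source stage
#' @param epochsStage2 epochs on the combined corpus
#' @param batchSize records per gradient step
#' @param learningRate Adam peak learning rate, cosine-decayed over all steps
#' @param stageOrder source labels visited in stage 1, then
#'   \code{"combined"}; defaults to corpus order at fit time
#' @param clipNorm global gradient-norm clip
#' @param weightDecay decoupled (AdamW-style) weight decay applied to
#'   weight matrices and embeddings only
#' @param seed training RNG seed
#' @export
trainingConfig <- function(maskRate = 0.5, epochsStage1 = 10L,
                           epochsStage2 = 20L, batchSize = 256L,
                           learningRate = 5e-3,
                           stageOrder = character(0), clipNorm = 5,
                           weightDecay = 1e-3, seed = 1L) {
  new("TrainingConfig", maskRate = maskRate,
      epochsStage1 = as.integer(epochsStage1),
      epochsStage2 = as.integer(epochsStage2),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      stageOrder = stageOrder, clipNorm = clipNorm,
      weightDecay = weightDecay, seed = as.integer(seed))
}

#' Select masked-modeling targets among the observed cells of a batch
#'
#' Each observed cell is independently hidden with probability
#' \code{maskRate}; records that would end up with no target keep one
#' randomly chosen observed cell as target.  Structurally missing cells can
#' never become targets.  Records with no observed cell at all are reported
#' in \code{skipped}.
#'
#' @param mask logical records x attributes observation matrix
#' @param maskRate per-cell masking probability in (0, 1]; a length-2
#'   vector draws one rate per record uniformly from that range, so the
#'   model sees conditioning sets of every size
#' @param seed optional integer; if given the draw is made under a local
#'   seed, otherwise the ambient RNG stream is used
#' @return list with \code{inputMask} (observed cells still visible),
#'   \code{targetMask} (cells to reconstruct), \code{skipped} (row indices
#'   without any observed cell)
#' @export
maskRecords <- function(mask, maskRate = 0.5, seed = NULL) {
  if (any(maskRate <= 0 | maskRate > 1))
    stopf("maskRate must lie in (0, 1]")
  draw <- function() {
    rate <- if (length(maskRate) == 2L)
      runif(nrow(mask), maskRate[1], maskRate[2]) else maskRate
    tgt <- mask & matrix(runif(length(mask)) < rate,
                         nrow(mask), ncol(mask))
    nObs <- rowSums(mask)
    fix <- which(nObs > 0 & rowSums(tgt) == 0)
    for (r in fix) {
      obsCells <- which(mask[r, ])
      pick <- if (length(obsCells) == 1) obsCells
              else obsCells[sample.int(length(obsCells), 1L)]
      tgt[r, pick] <- TRUE
    }
    skipped <- which(nObs == 0)
    if (length(skipped))
      jlog("maskRecords.skip", n = length(skipped),
           level = "warning")
    list(inputMask = mask & !tgt, targetMask = tgt, skipped = skipped)
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

# design matrices for the network: XEMB (standardized embedding values /
# level codes), YTGT (likelihood-scale targets; raw counts), OBS.
designMatrices <- function(corpus) {
  std <- corpusStandardizers(corpus)
  if (is.null(std))
    stopf("standardizers not fitted; call fitStandardizers() on the training corpus")
  vals <- corpusValues(corpus)
  dts <- attributeDtypes(corpus)
  XEMB <- vals
  YTGT <- vals
  for (a in colnames(vals)) {
    XEMB[, a] <- standardizeValue(std[[a]], vals[, a])
    if (std[[a]]$dtype %in% c("real", "positive"))
      YTGT[, a] <- XEMB[, a]
  }
  list(XEMB = XEMB, YTGT = YTGT, OBS = corpusMask(corpus),
       dts = dts, attrs = colnames(vals))
}

adamStep <- function(theta, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  state$theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  state
}

#' Train the generative network with masked modeling
#'
#' Two-stage schedule: the model is first trained on each source
#' separately (one shared network, sequential passes), then fine-tuned on
#' the combined corpus.  The loss is the mean per-target typed negative
#' log-likelihood.  Corpora carrying holdout records are refused.
#'
#' @param corpus a TabularCorpus with fitted standardizers (training split
#'   only)
#' @param netCfg a \code{\link{networkConfig}}
#' @param trainCfg a \code{\link{trainingConfig}}
#' @param versionName model version label stamped into every artifact
#'   (releases are conventionally named after stars)
#' @return a \code{\linkS4class{GenerativeModel}} with per-epoch loss
#'   history
#' @export
trainModel <- function(corpus, netCfg = networkConfig(),
                       trainCfg = trainingConfig(),
                       versionName = "altair") {
  if (any(corpusRoles(corpus) == "holdout"))
    stopf("corpus contains holdout records; the trainer refuses holdout data")
  schema <- corpusSchema(corpus)
  dm <- designMatrices(corpus)
  par <- netInit(schema, netCfg)
  std <- corpusStandardizers(corpus)

  usable <- which(rowSums(dm$OBS) > 0)
  if (length(usable) < nrow(dm$OBS))
    jlog("train.skipEmptyRecords", n = nrow(dm$OBS) - length(usable))

  src <- sourceLabels(corpus)
  stageOrder <- trainCfg@stageOrder
  if (length(stageOrder) == 0)
    stageOrder <- c(unique(src), "combined")
  if (!"combined" %in% stageOrder) stageOrder <- c(stageOrder, "combined")

  nb <- function(n) max(1L, ceiling(n / trainCfg@batchSize))
  totalSteps <- 0L
  for (s in setdiff(stageOrder, "combined"))
    totalSteps <- totalSteps + trainCfg@epochsStage1 *
      nb(sum(src[usable] == s))
  totalSteps <- totalSteps + trainCfg@epochsStage2 * nb(length(usable))

  theta <- flattenParams(par)
  state <- list(m = theta * 0, v = theta * 0, theta = theta)
  dmask <- decayMask(par)
  step <- 0L
  hist <- list()

  runEpochs <- function(rows, epochs, stage, label) {
    if (length(rows) == 0 || epochs == 0) return(invisible(NULL))
    for (ep in seq_len(epochs)) {
      ord <- sample(rows)
      nBatch <- nb(length(ord))
      lossSum <- 0
      nTgt <- 0
      for (b in seq_len(nBatch)) {
        idx <- ord[(((b - 1L) * trainCfg@batchSize) + 1L):
                     min(b * trainCfg@batchSize, length(ord))]
        mk <- maskRecords(dm$OBS[idx, , drop = FALSE], trainCfg@maskRate)
        res <- netLossGrad(par, dm$XEMB[idx, , drop = FALSE],
                           dm$YTGT[idx, , drop = FALSE],
                           mk$inputMask, mk$targetMask,
                           netCfg, dm$dts, std = std, training = TRUE)
        if (res$n == 0) next
        if (!is.finite(res$loss))
          stopf("training diverged (non-finite loss) at stage '%s' epoch %d",
                label, ep)
        g <- flattenParams(res$grads)
        gn <- sqrt(sum(g^2))
        if (gn > trainCfg@clipNorm) g <- g * (trainCfg@clipNorm / gn)
        step <<- step + 1L
        lr <- trainCfg@learningRate *
          (0.05 + 0.95 * 0.5 * (1 + cos(pi * (step - 1) /
                                          max(totalSteps - 1, 1))))
        state <<- adamStep(state$theta, g, state, lr, step)
        if (trainCfg@weightDecay > 0)
          state$theta <<- state$theta -
            lr * trainCfg@weightDecay * dmask * state$theta
        par <<- unflattenParams(state$theta, par)
        lossSum <- lossSum + res$loss * res$n
        nTgt <- nTgt + res$n
      }
      hist[[length(hist) + 1L]] <<- data.frame(
        stage = stage, source = label, epoch = ep,
        loss = lossSum / max(nTgt, 1))
    }
    invisible(NULL)
  }

  withSeed(trainCfg@seed, {
    for (s in setdiff(stageOrder, "combined"))
      runEpochs(usable[src[usable] == s], trainCfg@epochsStage1, 1L, s)
    runEpochs(usable, trainCfg@epochsStage2, 2L, "combined")
  })

  history <- if (length(hist)) do.call(rbind, hist)
             else data.frame(stage = integer(0), source = character(0),
                             epoch = integer(0), loss = numeric(0))
  jlog("train.done", version = versionName,
       schema_hash = shortHash(schema@specs),
       steps = step,
       final_loss = if (nrow(history)) history$loss[nrow(history)] else NA)
  trained <- colSums(dm$OBS[usable, , drop = FALSE]) > 0 & step > 0
  names(trained) <- dm$attrs
  new("GenerativeModel", params = par, netConfig = netCfg, schema = schema,
      standardizers = std, history = history,
      trainedAttributes = trained, versionName = versionName)
}

#' Evaluate the masked-modeling loss of a model on a corpus (no training)
#'
#' @param model a GenerativeModel
#' @param corpus a TabularCorpus with fitted standardizers
#' @param maskRate per-cell masking probability
#' @param seed mask seed
#' @export
evaluateLoss <- function(model, corpus, maskRate = 0.5, seed = 1L) {
  dm <- designMatrices(corpus)
  withSeed(seed, {
    mk <- maskRecords(dm$OBS, maskRate)
    res <- netLossGrad(model@params, dm$XEMB, dm$YTGT, mk$inputMask,
                       mk$targetMask, model@netConfig, dm$dts,
                       std = corpusStandardizers(corpus),
                       wantGrad = FALSE)
    res$loss
  })
}
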