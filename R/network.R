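#' @include oracle.R
NULL

#' Network architecture configuration
#'
#' @param embedDim token embedding dimension
#' @param encLayers encoder attention blocks (attend over observed tokens)
#' @param decLayers decoder attention blocks (read observed latents into
#'   the full-width sequence)
#' @param heads attention heads; must divide \code{embedDim}
#' @param ffDim feed-forward hidden width
#' @param dropout dropout rate during training
#' @param passes decoding passes (2 = iterative decoding with gated
#'   feedback of imputed value tokens, the default; 1 = single pass)
#' @param seed weight-initialization seed
#' @export
networkConfig <- function(embedDim = 32L, encLayers = 1L, decLayers = 1L,
                          heads = 4L, ffDim = 64L, dropout = 0,
                          passes = 2L, seed = 1L) {
  new("NetworkConfig", embedDim = as.integer(embedDim),
      encLayers = as.integer(encLayers), decLayers = as.integer(decLayers),
      heads = as.integer(heads), ffDim = as.integer(ffDim),
      dropout = as.numeric(dropout), passes = as.integer(passes),
      seed = as.integer(seed))
}

rowsOf <- function(j, B) ((j - 1L) * B + 1L):(j * B)

glorot <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

initBlock <- function(d, dff) {
  list(g1 = rep(1, d), b1 = rep(0, d),
       Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
       Wo = glorot(d, d), bo = rep(0, d),
       g2 = rep(1, d), b2 = rep(0, d),
       W1 = glorot(d, dff), b1f = rep(0, dff),
       W2 = glorot(dff, d), b2f = rep(0, d))
}

# Initialize all weights for a schema under a NetworkConfig.
netInit <- function(schema, cfg) {
  dts <- attributeDtypes(schema)
  m <- length(dts)
  d <- cfg@embedDim
  withSeed(cfg@seed, {
    par <- list(
      A = matrix(rnorm(m * d, sd = 0.02), m, d),
      Wval = matrix(rnorm(m * d, sd = 0.2), m, d),
      Dtok = matrix(rnorm(m * d, sd = 0.02), m, d),
      Elev = lapply(seq_len(m), function(j) {
        if (dts[[j]] %in% LEVEL_DTYPES) {
          L <- length(schemaLevels(schema, names(dts)[j]))
          matrix(rnorm(L * d, sd = 0.2), L, d)
        } else NULL
      }),
      enc = lapply(seq_len(cfg@encLayers), function(i) initBlock(d, cfg@ffDim)),
      dec = lapply(seq_len(cfg@decLayers), function(i) initBlock(d, cfg@ffDim)),
      gF = rep(1, d), bF = rep(0, d),
      heads = lapply(seq_len(m), function(j) {
        if (dts[[j]] %in% c("real", "positive")) {
          list(Wm = rnorm(d, sd = 0.1), bm = 0,
               Ws = rnorm(d, sd = 0.1), bs = 0)
        } else if (dts[[j]] == "count") {
          list(Wl = rnorm(d, sd = 0.1), bl = 0)
        } else {
          L <- length(schemaLevels(schema, names(dts)[j]))
          list(Wc = matrix(rnorm(L * d, sd = 0.1), L, d), bc = rep(0, L))
        }
      }))
    names(par$Elev) <- names(dts)
    names(par$heads) <- names(dts)
    par
  })
}

addRowVec <- function(X, v) X + matrix(v, nrow(X), ncol(X), byrow = TRUE)
mulRowVec <- function(X, v) X * matrix(v, nrow(X), ncol(X), byrow = TRUE)

lnForward <- function(X, g, b, eps = 1e-5) {
  n <- nrow(X)
  d <- ncol(X)
  mu <- .rowMeans(X, n, d)
  xc <- X - mu
  istd <- 1 / sqrt(.rowMeans(xc * xc, n, d) + eps)
  xhat <- xc * istd
  Y <- addRowVec(mulRowVec(xhat, g), b)
  list(Y = Y, xhat = xhat, istd = istd)
}

lnBackward <- function(dY, cache, g) {
  n <- nrow(dY)
  d <- ncol(dY)
  dxhat <- mulRowVec(dY, g)
  m1 <- .rowMeans(dxhat, n, d)
  m2 <- .rowMeans(dxhat * cache$xhat, n, d)
  list(dX = cache$istd * (dxhat - m1 - cache$xhat * m2),
       dg = .colSums(dY * cache$xhat, n, d), db = .colSums(dY, n, d))
}

# Multi-head attention over a flat (B*m) x d matrix, position-major rows.
# keyMask is B x m; masked keys receive exactly zero weight and rows whose
# key set is empty produce a zero attention output.  The projections run
# through BLAS; the score/softmax/apply core is compiled (src/).
attnForward <- function(N1, blk, B, m, heads, keyMask) {
  tN1 <- t(N1)
  Qt <- crossprod(blk$Wq, tN1) # d x N, token feature vectors contiguous
  Kt <- crossprod(blk$Wk, tN1)
  Vt <- crossprod(blk$Wv, tN1)
  core <- attn_fwd_cpp(Qt, Kt, Vt, keyMask, B, m, heads)
  O <- addRowVec(crossprod(core$At, blk$Wo), blk$bo)
  list(O = O, Qt = Qt, Kt = Kt, Vt = Vt, At = core$At, P = core$P)
}

attnBackward <- function(dO, cache, blk, N1, B, m, heads) {
  dWo <- cache$At %*% dO
  dbo <- .colSums(dO, nrow(dO), ncol(dO))
  dAt <- tcrossprod(blk$Wo, dO)
  core <- attn_bwd_cpp(dAt, cache$Qt, cache$Kt, cache$Vt, cache$P,
                       B, m, heads)
  dN1t <- blk$Wq %*% core$dQt + blk$Wk %*% core$dKt + blk$Wv %*% core$dVt
  list(dN1 = t(dN1t),
       dWq = t(core$dQt %*% N1), dWk = t(core$dKt %*% N1),
       dWv = t(core$dVt %*% N1), dWo = dWo, dbo = dbo)
}

blockForward <- function(H, blk, B, m, heads, keyMask, dropout = 0) {
  ln1 <- lnForward(H, blk$g1, blk$b1)
  att <- attnForward(ln1$Y, blk, B, m, heads, keyMask)
  dm1 <- NULL
  O <- att$O
  if (dropout > 0) {
    dm1 <- matrix(rbinom(length(O), 1, 1 - dropout) / (1 - dropout),
                  nrow(O), ncol(O))
    O <- O * dm1
  }
  H1 <- H + O
  ln2 <- lnForward(H1, blk$g2, blk$b2)
  pre <- addRowVec(ln2$Y %*% blk$W1, blk$b1f)
  F1 <- pmax(pre, 0)
  F2 <- addRowVec(F1 %*% blk$W2, blk$b2f)
  dm2 <- NULL
  if (dropout > 0) {
    dm2 <- matrix(rbinom(length(F2), 1, 1 - dropout) / (1 - dropout),
                  nrow(F2), ncol(F2))
    F2 <- F2 * dm2
  }
  list(H = H1 + F2, ln1 = ln1, att = att, H1 = H1, ln2 = ln2, F1 = F1,
       dm1 = dm1, dm2 = dm2)
}

blockBackward <- function(dH2, cache, blk, B, m, heads) {
  dF2 <- dH2
  if (!is.null(cache$dm2)) dF2 <- dF2 * cache$dm2
  dW2 <- crossprod(cache$F1, dF2)
  db2f <- colSums(dF2)
  dPre <- (dF2 %*% t(blk$W2)) * (cache$F1 > 0)
  dW1 <- crossprod(cache$ln2$Y, dPre)
  db1f <- colSums(dPre)
  l2 <- lnBackward(dPre %*% t(blk$W1), cache$ln2, blk$g2)
  dH1 <- dH2 + l2$dX
  dO <- dH1
  if (!is.null(cache$dm1)) dO <- dO * cache$dm1
  ab <- attnBackward(dO, cache$att, blk, cache$ln1$Y, B, m, heads)
  l1 <- lnBackward(ab$dN1, cache$ln1, blk$g1)
  list(dH = dH1 + l1$dX,
       grads = list(g1 = l1$dg, b1 = l1$db,
                    Wq = ab$dWq, Wk = ab$dWk, Wv = ab$dWv,
                    Wo = ab$dWo, bo = ab$dbo,
                    g2 = l2$dg, b2 = l2$db,
                    W1 = dW1, b1f = db1f, W2 = dW2, b2f = db2f))
}

# Embedding forward: XEMB n x m standardized values / level codes, OBS n x m.
embedForward <- function(par, XEMB, OBS, dts) {
  B <- nrow(XEMB)
  m <- ncol(XEMB)
  d <- ncol(par$A)
  T <- matrix(0, B * m, d)
  codes <- vector("list", m)
  for (j in seq_len(m)) {
    rows <- rowsOf(j, B)
    if (dts[j] %in% LEVEL_DTYPES) {
      cj <- XEMB[, j]
      cj[!OBS[, j] | is.na(cj)] <- 1
      codes[[j]] <- as.integer(cj)
      Tj <- par$Elev[[j]][codes[[j]], , drop = FALSE]
    } else {
      xj <- XEMB[, j]
      xj[!OBS[, j] | is.na(xj)] <- 0
      Tj <- outer(xj, par$Wval[j, ])
    }
    Tj <- sweep(Tj, 2, par$A[j, ], "+")
    Tj[!OBS[, j], ] <- 0
    T[rows, ] <- Tj
  }
  list(T = T, codes = codes)
}

# Full network forward pass.  Returns final latents Hf (flat), per-attribute
# head outputs, and caches for the backward pass.  A precomputed flat token
# matrix Temb may be supplied (token-sequence entry point), bypassing the
# embedding.
nnForward <- function(par, XEMB, OBS, cfg, dts, training = FALSE,
                      Temb = NULL) {
  B <- nrow(XEMB)
  m <- ncol(XEMB)
  heads <- cfg@heads
  dropout <- if (training) cfg@dropout else 0
  emb <- if (is.null(Temb)) embedForward(par, XEMB, OBS, dts)
         else list(T = Temb, codes = NULL)
  H <- emb$T
  encCaches <- vector("list", length(par$enc))
  for (l in seq_along(par$enc)) {
    encCaches[[l]] <- blockForward(H, par$enc[[l]], B, m, heads, OBS, dropout)
    H <- encCaches[[l]]$H
  }
  # assemble the full-width latent sequence: transformed observed latents
  # plus the per-attribute learnable default token for missing attributes
  Z <- H
  for (j in seq_len(m)) {
    rows <- rowsOf(j, B)
    miss <- !OBS[, j]
    if (any(miss))
      Z[rows[miss], ] <- matrix(par$Dtok[j, ], sum(miss), ncol(Z),
                                byrow = TRUE)
  }
  Hd <- Z
  decCaches <- vector("list", length(par$dec))
  for (l in seq_along(par$dec)) {
    decCaches[[l]] <- blockForward(Hd, par$dec[[l]], B, m, heads, OBS,
                                   dropout)
    Hd <- decCaches[[l]]$H
  }
  lnf <- lnForward(Hd, par$gF, par$bF)
  Hf <- lnf$Y
  out <- headsForward(par, Hf, B, m, dts)
  list(heads = out, Hf = Hf,
       cache = list(emb = emb, encCaches = encCaches, Z = Z,
                    decCaches = decCaches, lnf = lnf, OBS = OBS,
                    XEMB = XEMB, B = B, m = m))
}

headsForward <- function(par, Hf, B, m, dts) {
  out <- vector("list", m)
  names(out) <- names(dts)
  for (j in seq_len(m)) {
    hf <- Hf[rowsOf(j, B), , drop = FALSE]
    hp <- par$heads[[j]]
    out[[j]] <- if (dts[j] %in% c("real", "positive")) {
      pre <- drop(hf %*% hp$Ws) + hp$bs
      list(mu = drop(hf %*% hp$Wm) + hp$bm,
           logsd = pmin(pmax(pre, -6), 6), preSd = pre)
    } else if (dts[j] == "count") {
      pre <- drop(hf %*% hp$Wl) + hp$bl
      list(loglam = pmin(pmax(pre, -15), 15), preLam = pre)
    } else {
      logits <- sweep(hf %*% t(hp$Wc), 2, hp$bc, "+")
      mx <- apply(logits, 1, max)
      lse <- mx + log(rowSums(exp(logits - mx)))
      list(logits = logits, logp = logits - lse)
    }
  }
  out
}

#' Negative log-likelihood of an observed value under typed parameters
#'
#' real and positive use the Gaussian NLL on the standardized (resp.
#' log-standardized) scale; count the Poisson NLL \eqn{\lambda - k \log
#' \lambda + \log k!}; categorical and ordered categorical the cross-entropy
#' of the true level.
#'
#' @param params list: real/positive \code{list(mean, sd)} (for positive,
#'   the parameters of the log value, and \code{value} is the raw positive
#'   value); count \code{list(rate)}; level types \code{list(probs)}
#' @param value the observed value (level index or level name)
#' @param dtype attribute type
#' @export
typedNLL <- function(params, value, dtype) {
  dtype <- match.arg(dtype, ATTRIBUTE_DTYPES)
  switch(dtype,
    real = {
      if (params$sd <= 0) stopf("SD must be > 0")
      0.5 * log(2 * pi * params$sd^2) +
        (value - params$mean)^2 / (2 * params$sd^2)
    },
    positive = {
      if (params$sd <= 0) stopf("SD must be > 0")
      if (value <= 0) stopf("positive attribute value must be > 0")
      lv <- log(value)
      0.5 * log(2 * pi * params$sd^2) +
        (lv - params$mean)^2 / (2 * params$sd^2)
    },
    count = {
      if (params$rate <= 0) stopf("Poisson rate must be > 0")
      params$rate - value * log(params$rate) + lgamma(value + 1)
    },
    {
      p <- params$probs
      if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
        stopf("probability vector must be nonnegative and sum to 1")
      idx <- if (is.character(value)) match(value, names(p)) else value
      if (is.na(idx) || idx < 1 || idx > length(p))
        stopf("value outside the declared levels")
      -log(max(p[idx], 1e-300))
    })
}

#' Mode of a typed output distribution on the natural scale
#'
#' real: the Gaussian mean, de-standardized; positive: the log-normal mode
#' exp(mu - sigma^2) computed from the (de-standardized) log-scale
#' parameters; count: floor(lambda) (an integer rate keeps lambda itself);
#' categorical and ordered categorical: the argmax level, ties resolved to
#' the lowest index.
#'
#' @param params as in \code{\link{typedNLL}}; for real/positive these may
#'   be on the standardized scale when a \code{standardizer} is supplied
#' @param dtype attribute type
#' @param standardizer optional fitted standardizer entry for the attribute
#' @return numeric value, or the level (name if available, else index)
#' @export
modeOf <- function(params, dtype, standardizer = NULL) {
  dtype <- match.arg(dtype, ATTRIBUTE_DTYPES)
  switch(dtype,
    real = {
      if (is.null(standardizer)) params$mean
      else params$mean * standardizer$sd + standardizer$mean
    },
    positive = {
      mu <- params$mean
      sdv <- params$sd
      if (!is.null(standardizer)) {
        mu <- mu * standardizer$logSd + standardizer$logMean
        sdv <- sdv * standardizer$logSd
      }
      exp(mu - sdv^2)
    },
    count = floor(params$rate),
    {
      p <- params$probs
      idx <- which.max(p) # which.max takes the first (lowest) index on ties
      if (!is.null(names(p))) names(p)[idx] else idx
    })
}

# Per-attribute loss over target cells and gradient w.r.t. head outputs.
lossGrad <- function(out, YTGT, TGT, dts) {
  B <- nrow(YTGT)
  m <- ncol(YTGT)
  N <- sum(TGT)
  if (N == 0) return(list(loss = NA_real_, dOut = NULL, n = 0))
  dOut <- vector("list", m)
  total <- 0
  for (j in seq_len(m)) {
    sel <- TGT[, j]
    o <- out[[j]]
    if (!any(sel)) next # dOut[[j]] stays NULL
    y <- YTGT[sel, j]
    if (dts[j] %in% c("real", "positive")) {
      mu <- o$mu[sel]
      lsd <- o$logsd[sel]
      sd2 <- exp(2 * lsd)
      r <- (y - mu)
      total <- total + sum(0.5 * log(2 * pi) + lsd + r^2 / (2 * sd2))
      dmu <- numeric(B); dls <- numeric(B)
      dmu[sel] <- -r / sd2 / N
      act <- (o$preSd[sel] > -6 & o$preSd[sel] < 6)
      dls[sel] <- (1 - r^2 / sd2) * act / N
      dOut[[j]] <- list(dmu = dmu, dlogsd = dls)
    } else if (dts[j] == "count") {
      ll <- o$loglam[sel]
      lam <- exp(ll)
      total <- total + sum(lam - y * ll + lgamma(y + 1))
      dll <- numeric(B)
      act <- (o$preLam[sel] > -15 & o$preLam[sel] < 15)
      dll[sel] <- (lam - y) * act / N
      dOut[[j]] <- list(dloglam = dll)
    } else {
      lp <- o$logp[sel, , drop = FALSE]
      idx <- cbind(seq_len(nrow(lp)), as.integer(y))
      total <- total - sum(lp[idx])
      p <- exp(o$logp)
      dlg <- matrix(0, B, ncol(p))
      dsel <- p[sel, , drop = FALSE]
      dsel[idx] <- dsel[idx] - 1
      dlg[sel, ] <- dsel / N
      dOut[[j]] <- list(dlogits = dlg)
    }
  }
  list(loss = total / N, dOut = dOut, n = N)
}
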