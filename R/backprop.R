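#' @include network.R
NULL

# Flatten a nested parameter list into one numeric vector (NULL leaves are
# skipped); unflatten restores the original shapes.  Used by the optimizer
# and by the finite-difference gradient checks.
flattenParams <- function(p) {
  leaves <- list()
  walk <- function(v) {
    if (is.list(v)) {
      lapply(v, walk)
    } else if (!is.null(v)) {
      leaves[[length(leaves) + 1L]] <<- as.numeric(v)
    }
    invisible(NULL)
  }
  walk(p)
  unlist(leaves, use.names = FALSE)
}

unflattenParams <- function(vec, skel) {
  pos <- 0L
  walk <- function(v) {
    if (is.list(v)) {
      lapply(v, walk)
    } else if (is.null(v)) {
      NULL
    } else {
      n <- length(v)
      out <- vec[(pos + 1L):(pos + n)]
      pos <<- pos + n
      if (is.matrix(v)) dim(out) <- dim(v)
      out
    }
  }
  walk(skel)
}

zeroLike <- function(p) mapLeaves(function(x) x * 0, p)

addGrads <- function(a, b) mapLeaves(function(x, y) x + y, a, b)

# 0/1 mask over the flattened parameter vector marking weight matrices and
# embeddings (decayed) vs. biases, gates and layer-norm gains (not decayed)
decayMask <- function(p) {
  decayNames <- c("A", "Wval", "Dtok", "Elev", "Wq", "Wk", "Wv", "Wo",
                  "W1", "W2", "Wm", "Ws", "Wl", "Wc")
  leaves <- list()
  walk <- function(v, nm, inDecay) {
    if (is.list(v)) {
      nms <- names(v) %||% rep("", length(v))
      for (i in seq_along(v))
        walk(v[[i]], nms[i],
             inDecay || nm %in% decayNames)
    } else if (!is.null(v)) {
      leaves[[length(leaves) + 1L]] <<-
        rep(as.numeric(inDecay || nm %in% decayNames), length(v))
    }
    invisible(NULL)
  }
  walk(p, "", FALSE)
  unlist(leaves, use.names = FALSE)
}

headsBackward <- function(par, dOut, Hf, B, m, dts) {
  d <- ncol(Hf)
  dHf <- matrix(0, nrow(Hf), d)
  gh <- vector("list", m)
  names(gh) <- names(par$heads)
  for (j in seq_len(m)) {
    if (is.null(dOut[[j]])) {
      gh[[j]] <- zeroLike(par$heads[[j]])
      next
    }
    rows <- rowsOf(j, B)
    hf <- Hf[rows, , drop = FALSE]
    hp <- par$heads[[j]]
    dj <- dOut[[j]]
    if (dts[j] %in% c("real", "positive")) {
      dHf[rows, ] <- dHf[rows, ] + outer(dj$dmu, hp$Wm) +
        outer(dj$dlogsd, hp$Ws)
      gh[[j]] <- list(Wm = drop(crossprod(hf, dj$dmu)), bm = sum(dj$dmu),
                      Ws = drop(crossprod(hf, dj$dlogsd)),
                      bs = sum(dj$dlogsd))
    } else if (dts[j] == "count") {
      dHf[rows, ] <- dHf[rows, ] + outer(dj$dloglam, hp$Wl)
      gh[[j]] <- list(Wl = drop(crossprod(hf, dj$dloglam)),
                      bl = sum(dj$dloglam))
    } else {
      dHf[rows, ] <- dHf[rows, ] + dj$dlogits %*% hp$Wc
      gh[[j]] <- list(Wc = crossprod(dj$dlogits, hf),
                      bc = colSums(dj$dlogits))
    }
  }
  list(dHf = dHf, gh = gh)
}

# Backward from head-output gradients down to the token matrix (everything
# except the embedding-layer parameter gradients).  keyMask is the mask the
# forward pass ran under.
nnBackwardCore <- function(par, fwd, dOut, cfg, dts) {
  cache <- fwd$cache
  B <- cache$B
  m <- cache$m
  heads <- cfg@heads
  keyMask <- cache$OBS

  hb <- headsBackward(par, dOut, fwd$Hf, B, m, dts)
  lf <- lnBackward(hb$dHf, cache$lnf, par$gF)
  dHd <- lf$dX
  gdec <- vector("list", length(par$dec))
  for (l in rev(seq_along(par$dec))) {
    bb <- blockBackward(dHd, cache$decCaches[[l]], par$dec[[l]], B, m, heads)
    dHd <- bb$dH
    gdec[[l]] <- bb$grads
  }
  dZ <- dHd
  dDtok <- par$Dtok * 0
  for (j in seq_len(m)) {
    rows <- rowsOf(j, B)
    miss <- !keyMask[, j]
    if (any(miss)) {
      dDtok[j, ] <- colSums(dZ[rows[miss], , drop = FALSE])
      dZ[rows[miss], ] <- 0
    }
  }
  dH <- dZ
  genc <- vector("list", length(par$enc))
  for (l in rev(seq_along(par$enc))) {
    bb <- blockBackward(dH, cache$encCaches[[l]], par$enc[[l]], B, m, heads)
    dH <- bb$dH
    genc[[l]] <- bb$grads
  }
  dT <- dH
  for (j in seq_len(m)) { # tokens exist only at key positions
    sel <- rowsOf(j, B)[!keyMask[, j]]
    if (length(sel)) dT[sel, ] <- 0
  }
  grads <- list(A = par$A * 0, Wval = par$Wval * 0, Dtok = dDtok,
                Elev = lapply(par$Elev, function(e)
                  if (is.null(e)) NULL else e * 0),
                enc = genc, dec = gdec, gF = lf$dg, bF = lf$db,
                heads = hb$gh)
  list(grads = grads, dT = dT)
}

# standard embedding-layer gradients for tokens built by embedForward
embedGradsInto <- function(grads, par, cache, dT, OBS, dts) {
  B <- cache$B
  XEMB <- cache$XEMB
  for (j in seq_len(cache$m)) {
    obs <- OBS[, j]
    if (!any(obs)) next
    dTj <- dT[rowsOf(j, B), , drop = FALSE]
    dTj[!obs, ] <- 0
    grads$A[j, ] <- grads$A[j, ] + colSums(dTj)
    if (dts[j] %in% LEVEL_DTYPES) {
      codes <- cache$emb$codes[[j]][obs]
      agg <- rowsum(dTj[obs, , drop = FALSE], group = codes)
      ridx <- as.integer(rownames(agg))
      grads$Elev[[j]][ridx, ] <- grads$Elev[[j]][ridx, , drop = FALSE] + agg
    } else {
      xj <- XEMB[, j]
      xj[!obs | is.na(xj)] <- 0
      grads$Wval[j, ] <- grads$Wval[j, ] + drop(crossprod(dTj, xj))
    }
  }
  grads
}

nnBackward <- function(par, fwd, dOut, cfg, dts) {
  core <- nnBackwardCore(par, fwd, dOut, cfg, dts)
  embedGradsInto(core$grads, par, fwd$cache, core$dT, fwd$cache$OBS, dts)
}

## ---- iterative (two-pass) decoding with gated feedback ----

# expected value of each head output on the embedding scale
imputedValues <- function(heads1, j, dts, std, attrs) {
  o <- heads1[[j]]
  dt <- dts[j]
  if (dt %in% c("real", "positive")) {
    list(v = o$mu)
  } else if (dt == "count") {
    lam <- exp(o$loglam)
    s <- std[[attrs[j]]]
    list(v = (log1p(lam) - s$embMean) / s$embSd, lam = lam)
  } else {
    list(p = exp(o$logp))
  }
}

# imputed value tokens for the feedback pass: a feedback cell of attribute
# j carries the token A_j + vhat * Wval_j (level types: probability-
# weighted level embeddings) -- the exact format of an observed-value
# token, so the conditioning pathways trained on observed tokens transfer
# verbatim to imputed ones.
imputedTokens <- function(par, heads1, T1, feedMask, dts, std, attrs, B, m) {
  T2 <- T1
  iv <- vector("list", m)
  for (j in seq_len(m)) {
    miss <- which(feedMask[, j])
    if (length(miss) == 0) next
    rows <- rowsOf(j, B)[miss]
    iv[[j]] <- imputedValues(heads1, j, dts, std, attrs)
    base <- if (dts[j] %in% LEVEL_DTYPES) {
      iv[[j]]$p[miss, , drop = FALSE] %*% par$Elev[[j]]
    } else {
      outer(iv[[j]]$v[miss], par$Wval[j, ])
    }
    T2[rows, ] <- sweep(base, 2, par$A[j, ], "+")
  }
  list(T2 = T2, iv = iv)
}

# full forward: pass 1 as nnForward; optionally a second pass where imputed
# value tokens for helper attributes (missing but NOT themselves queried /
# reconstruction targets) are fed back through the same network.  The
# leave-target-out rule is essential: a queried attribute must never see
# its own first-pass estimate, otherwise training degenerates into copying.
# The caller decides the feedback cells (feedMask); attributes the model
# was never trained on must not be included.
fullForward <- function(par, XEMB, OBS, cfg, dts, std, training = FALSE,
                        Temb = NULL, feedMask = NULL) {
  f1 <- nnForward(par, XEMB, OBS, cfg, dts, training = training,
                  Temb = Temb)
  if (cfg@passes == 1L || is.null(feedMask) || !any(feedMask))
    return(list(f1 = f1, f2 = NULL, heads = f1$heads, keyMask2 = NULL,
                imp = NULL, feedMask = NULL))
  B <- nrow(XEMB)
  m <- ncol(XEMB)
  attrs <- names(dts) %||% colnames(XEMB)
  imp <- imputedTokens(par, f1$heads, f1$cache$emb$T, feedMask, dts, std,
                       attrs, B, m)
  keyMask2 <- OBS | feedMask
  f2 <- nnForward(par, XEMB, keyMask2, cfg, dts, training = training,
                  Temb = imp$T2)
  list(f1 = f1, f2 = f2, heads = f2$heads, keyMask2 = keyMask2, imp = imp,
       feedMask = feedMask)
}

# backward through both passes; dOut1/dOut2 are head-output gradients of
# the (already weighted) pass losses
fullBackward <- function(par, ff, dOut1, dOut2, XEMB, OBS, cfg, dts, std) {
  if (is.null(ff$f2)) return(nnBackward(par, ff$f1, dOut1, cfg, dts))
  B <- nrow(XEMB)
  m <- ncol(XEMB)
  attrs <- names(dts) %||% colnames(XEMB)
  core2 <- nnBackwardCore(par, ff$f2, dOut2, cfg, dts)
  g2 <- core2$grads
  dT2 <- core2$dT
  # observed positions of T2 are the ordinary embedding tokens; reuse the
  # pass-1 embedding cache (identical tokens and codes at observed cells)
  g2 <- embedGradsInto(g2, par, ff$f1$cache, dT2, OBS, dts)
  # imputed positions: chain into gate, A, Wval/Elev, and the pass-1 heads
  dHeadExtra <- vector("list", m)
  for (j in seq_len(m)) {
    if (is.null(ff$imp$iv[[j]])) next # position did not feed back
    miss <- which(ff$feedMask[, j])
    if (length(miss) == 0) next
    rows <- rowsOf(j, B)[miss]
    dTj <- dT2[rows, , drop = FALSE]
    iv <- ff$imp$iv[[j]]
    if (dts[j] %in% LEVEL_DTYPES) {
      pmiss <- iv$p[miss, , drop = FALSE]
      g2$A[j, ] <- g2$A[j, ] + colSums(dTj)
      g2$Elev[[j]] <- g2$Elev[[j]] + crossprod(pmiss, dTj)
      dp <- dTj %*% t(par$Elev[[j]])               # nMiss x L
      inner <- rowSums(pmiss * dp)
      dlogits <- pmiss * (dp - inner)              # softmax backward
      full <- matrix(0, B, ncol(pmiss))
      full[miss, ] <- dlogits
      dHeadExtra[[j]] <- list(dlogits = full)
    } else {
      vmiss <- iv$v[miss]
      g2$A[j, ] <- g2$A[j, ] + colSums(dTj)
      g2$Wval[j, ] <- g2$Wval[j, ] + drop(crossprod(dTj, vmiss))
      dv <- drop(dTj %*% par$Wval[j, ])            # d loss / d vhat
      if (dts[j] == "count") {
        lam <- iv$lam[miss]
        s <- std[[attrs[j]]]
        o <- ff$f1$heads[[j]]
        act <- (o$preLam[miss] > -15 & o$preLam[miss] < 15)
        dll <- numeric(B)
        dll[miss] <- dv * lam / ((1 + lam) * s$embSd) * act
        dHeadExtra[[j]] <- list(dloglam = dll)
      } else {
        dmu <- numeric(B)
        dmu[miss] <- dv
        dHeadExtra[[j]] <- list(dmu = dmu, dlogsd = numeric(B))
      }
    }
  }
  # merge pass-1 head gradients: direct loss + feedback chain
  dOut1m <- vector("list", m)
  for (j in seq_len(m)) {
    a <- dOut1[[j]]
    b <- dHeadExtra[[j]]
    dOut1m[j] <- list(if (is.null(a)) b
                      else if (is.null(b)) a
                      else mapLeaves(function(x, y) x + y, a, b))
  }
  g1 <- nnBackward(par, ff$f1, dOut1m, cfg, dts)
  addGrads(g1, g2)
}

# One forward+backward evaluation of the masked-modeling loss.  With
# two-pass decoding the loss is the mean of the two passes' per-target
# NLLs (both passes are supervised).
netLossGrad <- function(par, XEMB, YTGT, OBSin, TGT, cfg, dts, std = NULL,
                        training = FALSE, wantGrad = TRUE) {
  feedMask <- !OBSin & !TGT # structurally missing helper cells
  ff <- fullForward(par, XEMB, OBSin, cfg, dts, std, training = training,
                    feedMask = feedMask)
  lg1 <- lossGrad(ff$f1$heads, YTGT, TGT, dts)
  if (is.null(ff$f2)) {
    if (!wantGrad || lg1$n == 0)
      return(list(loss = lg1$loss, grads = NULL, n = lg1$n))
    return(list(loss = lg1$loss,
                grads = nnBackward(par, ff$f1, lg1$dOut, cfg, dts),
                n = lg1$n))
  }
  lg2 <- lossGrad(ff$f2$heads, YTGT, TGT, dts)
  loss <- (lg1$loss + lg2$loss) / 2
  if (!wantGrad || lg1$n == 0)
    return(list(loss = loss, grads = NULL, n = lg1$n))
  half <- function(dOut) lapply(dOut, function(dj)
    if (is.null(dj)) NULL else mapLeaves(function(x) x / 2, dj))
  grads <- fullBackward(par, ff, half(lg1$dOut), half(lg2$dOut),
                        XEMB, OBSin, cfg, dts, std)
  list(loss = loss, grads = grads, n = lg1$n)
}
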