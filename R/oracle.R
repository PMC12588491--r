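#' @include simulate.R
NULL

# Gauss-Hermite nodes/weights (probabilists', for E over N(0,1)); n = 9.
ghNodes <- function() {
  gh <- pracmaFreeHermite(9L)
  list(x = gh$x * sqrt(2), w = gh$w / sqrt(pi))
}

# Hermite quadrature via eigen-decomposition of the Jacobi matrix
# (Golub-Welsch); avoids an extra dependency.
pracmaFreeHermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  b <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# P(x | z) for one attribute of a latent-factor config; sc = score vector
# (n draws), x a single observed value (level index for level types).
attrLikelihood <- function(a, sc, x) {
  switch(a$dtype,
    real = dnorm(x, mean = sc, sd = max(a$noise, 1e-12)),
    positive = dnorm(log(x), mean = sc, sd = max(a$noise, 1e-12)),
    count = {
      if (a$noise < 1e-12) {
        dpois(x, exp(pmin(sc, 30)))
      } else {
        gh <- ghNodes()
        out <- 0
        for (q in seq_along(gh$x))
          out <- out + gh$w[q] * dpois(x, exp(pmin(sc + a$noise * gh$x[q], 30)))
        out
      }
    },
    ordered_categorical = {
      thr <- c(-Inf, a$thresholds, Inf)
      if (a$noise < 1e-12) {
        as.numeric(sc > thr[x] & sc <= thr[x + 1])
      } else {
        pnorm((thr[x + 1] - sc) / a$noise) - pnorm((thr[x] - sc) / a$noise)
      }
    },
    categorical = {
      s <- sweep(sc, 2, a$intercept, "+")
      p <- exp(s - apply(s, 1, max))
      (p / rowSums(p))[, x]
    })
}

# conditional moments / level probabilities of the target given each latent
# draw; returns list(mean=, m2=) or list(probs = n x L matrix)
attrCondMoments <- function(a, sc) {
  switch(a$dtype,
    real = list(mean = sc, m2 = sc^2 + a$noise^2),
    positive = list(mean = exp(sc + a$noise^2 / 2),
                    m2 = exp(2 * sc + 2 * a$noise^2)),
    count = {
      if (a$noise < 1e-12) {
        lam <- exp(pmin(sc, 30))
        list(mean = lam, m2 = lam + lam^2)
      } else {
        gh <- ghNodes()
        m <- 0; m2 <- 0
        for (q in seq_along(gh$x)) {
          lam <- exp(pmin(sc + a$noise * gh$x[q], 30))
          m <- m + gh$w[q] * lam
          m2 <- m2 + gh$w[q] * (lam + lam^2)
        }
        list(mean = m, m2 = m2)
      }
    },
    ordered_categorical = {
      thr <- c(-Inf, a$thresholds, Inf)
      L <- length(a$levels)
      probs <- sapply(seq_len(L), function(l) {
        if (a$noise < 1e-12) as.numeric(sc > thr[l] & sc <= thr[l + 1])
        else pnorm((thr[l + 1] - sc) / a$noise) - pnorm((thr[l] - sc) / a$noise)
      })
      list(probs = matrix(probs, ncol = L))
    },
    categorical = {
      s <- sweep(sc, 2, a$intercept, "+")
      p <- exp(s - apply(s, 1, max))
      list(probs = p / rowSums(p))
    })
}

#' @describeIn trueConditional Latent-factor oracle.  Jointly Gaussian
#'   sub-case (all attributes of type \code{real}) is evaluated exactly;
#'   any other query uses self-normalized importance sampling over the
#'   latent vector with closed-form per-type likelihoods.
#' @export
setMethod("trueConditional", "LatentFactorOracle",
  function(oracle, target, given = list(), nMC = 20000L, seed = 1L,
           method = c("auto", "exact", "mc")) {
  method <- match.arg(method)
  cfg <- oracle@config
  if (!target %in% names(cfg@attrs)) stopf("unknown target '%s'", target)
  if (length(given) && !all(names(given) %in% names(cfg@attrs)))
    stopf("unknown conditioning attribute")
  if (target %in% names(given))
    stopf("target '%s' is also a conditioning attribute", target)
  allReal <- all(vapply(cfg@attrs[c(target, names(given))], `[[`, "",
                        "dtype") == "real")
  if (allReal && method != "mc")
    return(gaussianConditional(cfg, target, given))
  if (method == "exact")
    stopf("exact evaluation only available for all-real queries")

  given <- encodeGiven(cfg, given)
  withSeed(seed, {
    z <- matrix(rnorm(nMC * cfg@latentDim), nMC, cfg@latentDim)
    logw <- numeric(nMC)
    for (g in names(given)) {
      a <- cfg@attrs[[g]]
      lik <- attrLikelihood(a, simScore(a, z), given[[g]])
      logw <- logw + log(lik) # log(0) = -Inf marks impossible draws
    }
    if (!any(is.finite(logw)))
      stopf("conditioning event has probability ~ 0 (no draw carries weight)")
    w <- exp(logw - max(logw[is.finite(logw)]))
    w[!is.finite(w)] <- 0
    ess <- sum(w)^2 / sum(w^2)
    if (!is.finite(ess) || ess < 10)
      stopf(paste0("conditioning event has probability ~ 0 ",
                   "(effective sample size %.1f of %d)"), ess, nMC)
    wn <- w / sum(w)
    a <- cfg@attrs[[target]]
    mom <- attrCondMoments(a, simScore(a, z))
    if (!is.null(mom$probs)) {
      probs <- colSums(wn * mom$probs)
      names(probs) <- a$levels
      se <- sqrt(colSums(wn^2 * sweep(mom$probs, 2, probs)^2))
      list(probs = probs, mean = sum(probs * seq_along(probs)),
           se = max(se), method = "mc", ess = ess)
    } else {
      m <- sum(wn * mom$mean)
      v <- max(sum(wn * mom$m2) - m^2, 0)
      se <- sqrt(sum(wn^2 * (mom$mean - m)^2))
      list(mean = m, sd = sqrt(v), se = se, method = "mc", ess = ess)
    }
  })
})

encodeGiven <- function(cfg, given) {
  out <- list()
  for (g in names(given)) {
    a <- cfg@attrs[[g]]
    v <- given[[g]]
    if (a$dtype %in% LEVEL_DTYPES && is.character(v)) {
      idx <- match(v, a$levels)
      if (is.na(idx)) stopf("value '%s' not a level of '%s'", v, g)
      v <- idx
    }
    if (a$dtype == "positive" && v <= 0)
      stopf("conditioning value for positive attribute '%s' must be > 0", g)
    out[[g]] <- v
  }
  out
}

# exact conditional for jointly Gaussian (all-real) attributes
gaussianConditional <- function(cfg, target, given) {
  nms <- c(names(given), target)
  L <- do.call(rbind, lapply(cfg@attrs[nms], `[[`, "loading"))
  noise <- vapply(cfg@attrs[nms], `[[`, 0, "noise")
  mu <- vapply(cfg@attrs[nms], `[[`, 0, "intercept")
  S <- L %*% t(L) + diag(noise^2, length(nms))
  k <- length(given)
  t_i <- k + 1
  if (k == 0)
    return(list(mean = unname(mu[t_i]), sd = sqrt(S[t_i, t_i]), se = 0,
                method = "exact"))
  Sgg <- S[seq_len(k), seq_len(k), drop = FALSE]
  Stg <- S[t_i, seq_len(k), drop = FALSE]
  x <- unlist(given) - mu[seq_len(k)]
  w <- Stg %*% solve(Sgg)
  list(mean = unname(drop(mu[t_i] + w %*% x)),
       sd = sqrt(max(S[t_i, t_i] - drop(w %*% t(Stg)), 0)),
       se = 0, method = "exact")
}

#' @describeIn trueConditional Discrete chain oracle.  \code{method =
#'   "auto"}/\code{"exact"} enumerates the eight outcomes; \code{"mc"}
#'   simulates the chain and conditions by rejection, reporting a binomial
#'   standard error.
#' @export
setMethod("trueConditional", "DiscreteChainOracle",
  function(oracle, target, given = list(), nMC = 20000L, seed = 1L,
           method = c("auto", "exact", "mc")) {
  method <- match.arg(method)
  vars <- c("X", "Z", "Y")
  if (!target %in% vars) stopf("target must be one of X, Z, Y")
  if (length(given) && !all(names(given) %in% setdiff(vars, target)))
    stopf("invalid conditioning variables")
  joint <- expand.grid(X = 0:1, Z = 0:1, Y = 0:1)
  joint$p <- with(joint,
    ifelse(X == 1, oracle@pX1, 1 - oracle@pX1) *
    ifelse(Z == 1, oracle@pZ1gX[X + 1], 1 - oracle@pZ1gX[X + 1]) *
    ifelse(Y == 1, oracle@pY1gZ[Z + 1], 1 - oracle@pY1gZ[Z + 1]))
  if (method %in% c("auto", "exact")) {
    keep <- rep(TRUE, nrow(joint))
    for (g in names(given)) keep <- keep & joint[[g]] == given[[g]]
    denom <- sum(joint$p[keep])
    if (denom <= 0) stopf("conditioning event has probability 0")
    p1 <- sum(joint$p[keep & joint[[target]] == 1]) / denom
    list(probs = c(`0` = 1 - p1, `1` = p1), mean = p1, se = 0,
         method = "exact")
  } else {
    withSeed(seed, {
      X <- rbinom(nMC, 1, oracle@pX1)
      Z <- rbinom(nMC, 1, oracle@pZ1gX[X + 1])
      Y <- rbinom(nMC, 1, oracle@pY1gZ[Z + 1])
      draws <- data.frame(X = X, Z = Z, Y = Y)
      keep <- rep(TRUE, nMC)
      for (g in names(given)) keep <- keep & draws[[g]] == given[[g]]
      n <- sum(keep)
      if (n < 10) stopf("conditioning event too rare in %d draws", nMC)
      p1 <- mean(draws[[target]][keep])
      list(probs = c(`0` = 1 - p1, `1` = p1), mean = p1,
           se = sqrt(p1 * (1 - p1) / n), method = "mc", n = n)
    })
  }
})
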