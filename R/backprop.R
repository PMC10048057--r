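# Manual reverse-mode differentiation of the decoder, mirroring
# modelForward() stage by stage, plus the Adam / SGD update rules. Gradients
# are verified against central finite differences in the test suite.

# Full backward pass. `cache` comes from modelForward(..., training = TRUE,
# keepCache = TRUE); `labels` are 0-based true classes. Returns gradients
# named like the parameter list.
modelBackward <- function(model, cache, labels) {
  cfg <- model@config
  p <- model@params
  N <- cfg@nElectrodes; M <- cfg@nTimepoints
  Fb <- cfg@branchFilters; Ft <- nConcatChannels(cfg)
  C <- cfg@spatialFilters; K <- cfg@poolWidth; J <- nPooled(cfg)
  B <- cache$B

  # softmax + cross-entropy
  dLogits <- cache$probs
  dLogits[cbind(as.integer(labels) + 1L, seq_len(B))] <-
    dLogits[cbind(as.integer(labels) + 1L, seq_len(B))] - 1
  dLogits <- dLogits / B

  dFcW <- tcrossprod(dLogits, cache$Fmat)
  dFcB <- rowSums(dLogits)
  dF <- crossprod(p$fcW, dLogits)     # (C*J) x B
  dXf <- dF; dim(dXf) <- c(C, J * B)

  # attention product: Xf = pooledD * McExp
  dPooledD <- dXf * cache$McExp
  tmp <- dXf * cache$pooledD
  dMc <- matrix(0, C, B)
  for (j in seq_len(J))
    dMc <- dMc + tmp[, j + J * (seq_len(B) - 1L), drop = FALSE]
  dz <- dMc * cache$Mc * (1 - cache$Mc)

  reluA <- pmax(cache$hA, 0)
  reluM <- pmax(cache$hM, 0)
  dAttW1 <- tcrossprod(dz, reluA) + tcrossprod(dz, reluM)
  dhA <- crossprod(p$attW1, dz) * (cache$hA > 0)
  dhM <- crossprod(p$attW1, dz) * (cache$hM > 0)
  dAttW0 <- tcrossprod(dhA, cache$avgM) + tcrossprod(dhM, cache$maxM)
  dAvg <- crossprod(p$attW0, dhA)     # C x B
  dMax <- crossprod(p$attW0, dhM)

  # average-pool path spreads 1/J to every column of the trial; max-pool
  # path routes to the argmax column per (channel, trial)
  for (j in seq_len(J)) {
    cols <- j + J * (seq_len(B) - 1L)
    dPooledD[, cols] <- dPooledD[, cols] + dAvg / J
  }
  idx <- cbind(rep(seq_len(C), B),
               as.vector(cache$argM) + J * rep(seq_len(B) - 1L, each = C))
  dPooledD[idx] <- dPooledD[idx] + as.vector(dMax)

  # dropout
  dPooled <- if (is.null(cache$mask)) dPooledD else dPooledD * cache$mask

  # average pooling backward, then ELU backward
  dE <- poolBackwardCpp(dPooled, K)
  dY2 <- eluBackwardCpp(dE, cache$E)

  bnS <- bnBackwardGroupedCpp(dY2, cache$xhatS, cache$invS, p$bnSGamma, 1L)
  dY <- bnS$dX

  # spatial conv with the temporal-BN affine folded in:
  # Y = (Ws diag(g)) xhat + Ws beta + b
  rS <- rowSums(dY)
  dWsEff <- tcrossprod(dY, cache$xhatT)
  dSpatialW <- dWsEff * rep(cache$gRow, each = C) + outer(rS, cache$bRow)
  dSpatialB <- rS
  dH <- crossprod(cache$WsEff, dY)    # gradient at xhat
  bnT <- bnBackwardFromXhat(dH, cache$xhatT, cache$invT, p$bnTGamma, N)
  dA <- bnT$dX

  nBr <- length(cfg@branchKernels)
  dBranchW <- vector("list", nBr)
  dBranchB <- vector("list", nBr)
  for (i in seq_len(nBr)) {
    dZ <- gatherConcatCpp(dA, N, (i - 1L) * Fb, Fb)
    dBranchW[[i]] <- tcrossprod(dZ, cache$shs[[i]])
    dBranchB[[i]] <- rowSums(dZ)
  }

  list(branchW = dBranchW, branchB = dBranchB,
       bnTGamma = bnT$dgamma, bnTBeta = bnT$dbeta,
       spatialW = dSpatialW, spatialB = dSpatialB,
       bnSGamma = bnS$dgamma, bnSBeta = bnS$dbeta,
       attW0 = dAttW0, attW1 = dAttW1,
       fcW = dFcW, fcB = dFcB)
}

# Flatten the (possibly nested) parameter list into a flat named list of
# numeric objects, and rebuild it; used by the optimizer and the
# finite-difference gradient check.
flattenParams <- function(p) {
  out <- list()
  for (nm in names(p)) {
    if (is.list(p[[nm]])) {
      for (i in seq_along(p[[nm]]))
        out[[paste0(nm, i)]] <- p[[nm]][[i]]
    } else out[[nm]] <- p[[nm]]
  }
  out
}

unflattenParams <- function(flat, template) {
  for (nm in names(template)) {
    if (is.list(template[[nm]])) {
      for (i in seq_along(template[[nm]]))
        template[[nm]][[i]] <- flat[[paste0(nm, i)]]
    } else template[[nm]] <- flat[[nm]]
  }
  template
}

# One optimizer step. `opt` holds the optimizer kind, learning rate and
# Adam moment estimates; returns updated params and state.
optimizerStep <- function(params, grads, opt) {
  fp <- flattenParams(params)
  fg <- flattenParams(grads)
  if (opt$kind == "sgd") {
    for (nm in names(fp)) fp[[nm]] <- fp[[nm]] - opt$lr * fg[[nm]]
  } else {
    opt$t <- opt$t + 1L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (nm in names(fp)) {
      g <- fg[[nm]]
      opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
      opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
      mh <- opt$m[[nm]] / (1 - b1^opt$t)
      vh <- opt$v[[nm]] / (1 - b2^opt$t)
      fp[[nm]] <- fp[[nm]] - opt$lr * mh / (sqrt(vh) + eps)
    }
  }
  list(params = unflattenParams(fp, params), opt = opt)
}

initOptimizer <- function(params, kind, lr) {
  fp <- flattenParams(params)
  zeros <- lapply(fp, function(x) x * 0)
  list(kind = kind, lr = lr, t = 0L, m = zeros, v = zeros)
}

# Update BN running statistics from the batch statistics in the cache
# (biased batch variance is used for normalization; the running variance is
# updated with the unbiased estimate, following common framework practice).
updateRunningStats <- function(model, cache) {
  bs <- cache$batchStats
  if (is.null(bs)) return(model)
  st <- model@state
  mom <- st$momentum
  nT <- cache$cntT
  nS <- model@config@nTimepoints * cache$B
  ubT <- bs$vT * nT / max(nT - 1, 1)
  ubS <- bs$vS * nS / max(nS - 1, 1)
  st$bnTMean <- (1 - mom) * st$bnTMean + mom * bs$mT
  st$bnTVar <- (1 - mom) * st$bnTVar + mom * ubT
  st$bnSMean <- (1 - mom) * st$bnSMean + mom * bs$mS
  st$bnSVar <- (1 - mom) * st$bnSVar + mom * ubS
  st$nUpdates <- st$nUpdates + 1L
  model@state <- st
  model
}
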