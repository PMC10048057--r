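# The three-class decoder: a multi-scale temporal convolution module
# (parallel 1-D convolutions with kernels (1,3), (1,5), (1,7), 8 filters
# each, batch-normalized, linear activation, concatenated to 24 feature
# channels), a spatial convolution module (kernel (N,1), 24 -> 48 channels,
# BN, ELU, average pooling (1,K), dropout), a channel-attention stage
# (shared two-layer bottleneck perceptron on global average- and max-pooled
# descriptors, sigmoid gate, channel-wise product), and a softmax classifier
# on the flattened 48 * M/K features.
#
# Everything runs on BLAS matrix operations. The internal data layout per
# mini-batch of B trials is:
#   X30    N  x (M*B)     input, columns ordered (m fastest, then b)
#   A      (F*N) x (M*B)  concatenated temporal features, rows (c-major,
#                         then electrode), F = total feature channels (24)
#   Y      C  x (M*B)     spatial features, C = spatialFilters (48)
#   pooled C  x (J*B)     after average pooling, J = M/K
# Column-major flattening of R arrays makes these reshapes copy-free.

#' Decoder architecture configuration
#'
#' @param nElectrodes number of EEG channels N (e.g. 30).
#' @param nTimepoints time points per trial M (e.g. 768 for 6 s at 128 Hz);
#'   must be divisible by `poolWidth`.
#' @param branchKernels odd temporal kernel widths (default `c(3, 5, 7)`).
#' @param branchFilters filters per branch (default 8).
#' @param spatialFilters spatial convolution output channels (default 48).
#' @param poolWidth average pooling width K (default 64).
#' @param dropout dropout rate after pooling (default 0.5).
#' @param attentionReduction attention bottleneck ratio r (default 8).
#' @param nClasses output classes (default 3).
#' @return a [ModelConfig-class].
#' @examples
#' cfg <- modelConfig(30, 768)
#' countParameters(cfg)
#' @export
modelConfig <- function(nElectrodes, nTimepoints, branchKernels = c(3, 5, 7),
                        branchFilters = 8, spatialFilters = 48,
                        poolWidth = 64, dropout = 0.5,
                        attentionReduction = 8, nClasses = 3) {
  new("ModelConfig",
      nElectrodes = as.integer(nElectrodes),
      nTimepoints = as.integer(nTimepoints),
      branchKernels = as.integer(branchKernels),
      branchFilters = as.integer(branchFilters),
      spatialFilters = as.integer(spatialFilters),
      poolWidth = as.integer(poolWidth),
      dropout = as.numeric(dropout),
      attentionReduction = as.integer(attentionReduction),
      nClasses = as.integer(nClasses))
}

# Total concatenated temporal feature channels.
nConcatChannels <- function(cfg) cfg@branchFilters * length(cfg@branchKernels)

# Pooled width J = M / K.
nPooled <- function(cfg) cfg@nTimepoints %/% cfg@poolWidth

#' Count trainable parameters
#'
#' Deterministic function of the configuration; the `"breakdown"` attribute
#' documents the per-layer counts (convolution weights and biases, BN scale
#' and shift, attention perceptron, classifier).
#'
#' @param cfg a [ModelConfig-class].
#' @return integer parameter count with a named `"breakdown"` attribute.
#' @export
countParameters <- function(cfg) {
  validObject(cfg)
  Fb <- cfg@branchFilters
  Ft <- nConcatChannels(cfg)
  C <- cfg@spatialFilters
  r <- cfg@attentionReduction
  J <- nPooled(cfg)
  breakdown <- c(
    temporalConv = sum(Fb * (cfg@branchKernels + 1L)),
    temporalBN = 2L * Ft,
    spatialConv = C * (Ft * cfg@nElectrodes) + C,
    spatialBN = 2L * C,
    attention = 2L * C * (C %/% r),
    classifier = cfg@nClasses * (C * J) + cfg@nClasses
  )
  structure(sum(breakdown), breakdown = breakdown)
}

#' Initialize a decoder
#'
#' Weights are drawn uniformly in `(-1/sqrt(fanIn), 1/sqrt(fanIn))`; BN
#' scale/shift start at 1/0 and running statistics at 0/1. Uses the current
#' R RNG (seed with `set.seed()` for reproducibility).
#'
#' @param cfg a [ModelConfig-class].
#' @return an [MSTCNModel-class].
#' @export
initModel <- function(cfg) {
  validObject(cfg)
  Fb <- cfg@branchFilters
  Ft <- nConcatChannels(cfg)
  N <- cfg@nElectrodes
  C <- cfg@spatialFilters
  r <- cfg@attentionReduction
  J <- nPooled(cfg)
  u <- function(nr, nc, fanIn) {
    lim <- 1 / sqrt(fanIn)
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  params <- list(
    branchW = lapply(cfg@branchKernels, function(S) u(Fb, S, S)),
    branchB = lapply(cfg@branchKernels, function(S) numeric(Fb)),
    bnTGamma = rep(1, Ft), bnTBeta = numeric(Ft),
    spatialW = u(C, Ft * N, Ft * N), spatialB = numeric(C),
    bnSGamma = rep(1, C), bnSBeta = numeric(C),
    attW0 = u(C %/% r, C, C), attW1 = u(C, C %/% r, C %/% r),
    fcW = u(cfg@nClasses, C * J, C * J), fcB = numeric(cfg@nClasses)
  )
  state <- list(
    bnTMean = numeric(Ft), bnTVar = rep(1, Ft),
    bnSMean = numeric(C), bnSVar = rep(1, C),
    momentum = 0.1, eps = 1e-5, nUpdates = 0L
  )
  new("MSTCNModel", config = cfg, params = params, state = state)
}

#' Forward pass of the decoder
#'
#' Runs a batch of trials through the network. In training mode batch
#' normalization uses batch statistics (and updates the running statistics
#' in the returned cache) and dropout is active; in inference mode the
#' running statistics are used and dropout is off, so the pass is
#' deterministic.
#'
#' @param model an [MSTCNModel-class].
#' @param x one trial (N x M matrix) or a batch (N x M x B array) of
#'   normalized trials.
#' @param training logical; training mode (default `FALSE`).
#' @param keepCache keep intermediate activations for the backward pass.
#' @return list with `probs` (nClasses x B class probabilities, columns sum
#'   to 1), `shapes` (named list of intermediate tensor shapes), and, if
#'   requested, `cache`.
#' @export
modelForward <- function(model, x, training = FALSE, keepCache = FALSE) {
  cfg <- model@config
  p <- model@params
  st <- model@state
  N <- cfg@nElectrodes; M <- cfg@nTimepoints
  Fb <- cfg@branchFilters; Ft <- nConcatChannels(cfg)
  C <- cfg@spatialFilters; K <- cfg@poolWidth; J <- nPooled(cfg)
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  if (!all(is.finite(x))) stop("non-finite values in model input")
  d <- dim(x)
  if (d[1] != N || d[2] != M)
    stop("input shape (", d[1], ", ", d[2], ") does not match config (N = ",
         N, ", M = ", M, ")")
  B <- d[3]
  X30 <- x; dim(X30) <- c(N, M * B)

  # ----- multi-scale temporal convolution, BN, concatenation -----
  nB <- length(cfg@branchKernels)
  A <- matrix(0, Ft * N, M * B)
  shs <- vector("list", nB)
  for (i in seq_len(nB)) {
    S <- cfg@branchKernels[i]
    sh <- im2colTimeCpp(X30, M, S)
    Z <- p$branchW[[i]] %*% sh + p$branchB[[i]]
    fillConcatCpp(A, Z, N, (i - 1L) * Fb)
    if (keepCache) shs[[i]] <- sh
  }
  cntT <- N * M * B
  if (training) {
    bs <- bnStatsGrouped(A, N)
    mT <- bs$mean; vT <- bs$var
  } else {
    mT <- st$bnTMean; vT <- st$bnTVar
  }
  invT <- 1 / sqrt(vT + st$eps)
  xhatT <- bnNormalizeGrouped(A, N, mT, invT)

  # ----- spatial convolution, BN, ELU, average pooling, dropout -----
  # the affine part of the temporal BN (gamma, beta) is folded into the
  # spatial convolution: Ws (gamma (.) xhat + beta) = (Ws diag(g)) xhat +
  # (Ws beta); mathematically identical, avoids materializing the scaled
  # tensor
  gRow <- rep(p$bnTGamma, each = N)
  bRow <- rep(p$bnTBeta, each = N)
  WsEff <- p$spatialW * rep(gRow, each = C)
  bEff <- as.vector(p$spatialW %*% bRow) + p$spatialB
  Y <- WsEff %*% xhatT + bEff
  if (training) {
    bsS <- bnStatsGrouped(Y, 1L)
    mS <- bsS$mean; vS <- bsS$var
  } else {
    mS <- st$bnSMean; vS <- st$bnSVar
  }
  invS <- 1 / sqrt(pmax(vS, 0) + st$eps)
  baS <- bnApplyGrouped(Y, 1L, mS, invS, p$bnSGamma, p$bnSBeta)
  xhatS <- baS$xhat; Y2 <- baS$out
  E <- eluForwardCpp(Y2)
  pooled <- poolForwardCpp(E, K)
  if (training && cfg@dropout > 0) {
    keep <- 1 - cfg@dropout
    mask <- matrix(stats::rbinom(C * J * B, 1L, keep) / keep, C, J * B)
    pooledD <- pooled * mask
  } else {
    mask <- NULL
    pooledD <- pooled
  }

  # ----- channel attention -----
  PJ <- pooledD; dim(PJ) <- c(C * J, B)
  avgM <- matrix(0, C, B); maxM <- matrix(-Inf, C, B)
  argM <- matrix(1L, C, B)
  for (j in seq_len(J)) {
    blk <- PJ[((j - 1L) * C + 1L):(j * C), , drop = FALSE]
    avgM <- avgM + blk
    upd <- blk > maxM
    maxM[upd] <- blk[upd]
    argM[upd] <- j
  }
  avgM <- avgM / J
  hA <- p$attW0 %*% avgM
  hM <- p$attW0 %*% maxM
  z <- p$attW1 %*% pmax(hA, 0) + p$attW1 %*% pmax(hM, 0)
  Mc <- 1 / (1 + exp(-z))
  McExp <- Mc[, rep(seq_len(B), each = J), drop = FALSE]
  Xf <- pooledD * McExp

  # ----- classifier -----
  Fmat <- Xf; dim(Fmat) <- c(C * J, B)
  logits <- p$fcW %*% Fmat + p$fcB
  lmax <- apply(logits, 2L, max)
  ex <- exp(logits - rep(lmax, each = nrow(logits)))
  probs <- ex / rep(colSums(ex), each = nrow(ex))

  out <- list(
    probs = probs,
    shapes = list(
      input = c(1L, N, M),
      concat = c(Ft, N, M),
      spatial = c(C, 1L, M),
      pooled = c(C, 1L, J),
      attended = c(C, 1L, J),
      flatten = C * J,
      output = cfg@nClasses
    )
  )
  if (keepCache) {
    out$cache <- list(
      B = B, shs = shs, xhatT = xhatT, invT = invT,
      cntT = cntT, gRow = gRow, bRow = bRow, WsEff = WsEff,
      xhatS = xhatS, invS = invS,
      E = E, pooledD = pooledD, mask = mask, avgM = avgM, maxM = maxM,
      argM = argM, hA = hA, hM = hM, Mc = Mc, McExp = McExp,
      Fmat = Fmat, probs = probs,
      batchStats = if (training) list(mT = mT, vT = vT, mS = mS, vS = vS)
    )
  }
  out
}

#' Multi-scale temporal convolution module output
#'
#' Runs only the temporal convolution branches (conv + BN, linear
#' activation, concatenation) on one trial, returning the concatenated
#' feature tensor. Each branch output equals the branch convolution run
#' independently; concatenation is along the feature-channel axis.
#'
#' @param model an [MSTCNModel-class].
#' @param x one trial, N x M matrix.
#' @param training use batch statistics for BN (default `FALSE`).
#' @return array (`branchFilters * nBranches`, N, M).
#' @export
mstcnForward <- function(model, x, training = FALSE) {
  stageTensors(model, x, training)$concat
}

#' Spatial convolution module output
#'
#' Spatial convolution (kernel (N, 1), collapsing the electrode axis), BN,
#' ELU, average pooling and (in training mode) dropout, applied to a
#' concatenated temporal feature tensor.
#'
#' @param model an [MSTCNModel-class].
#' @param x one trial, N x M matrix (the module is run in its network
#'   context, i.e. on the temporal features of this trial).
#' @param training training mode.
#' @return array (`spatialFilters`, 1, M/K).
#' @export
spatialForward <- function(model, x, training = FALSE) {
  stageTensors(model, x, training)$pooled
}

#' Channel-attention weights and output
#'
#' Computes the sigmoid channel gates from global average- and max-pooled
#' descriptors passed through the shared bottleneck perceptron, and the
#' recalibrated feature map.
#'
#' @param xs feature array (C, H, W) or matrix (C, W).
#' @param W0 bottleneck weight matrix (C/r x C), no bias.
#' @param W1 expansion weight matrix (C x C/r), no bias.
#' @return list with `weights` (C x 1 x 1 array, all in (0, 1)) and
#'   `output` (same shape as `xs`).
#' @export
channelAttention <- function(xs, W0, W1) {
  d <- dim(xs)
  if (is.null(d)) stop("xs must be a matrix or array")
  if (length(d) == 3L) { C <- d[1]; W <- d[2] * d[3] } else { C <- d[1]; W <- d[2] }
  if (nrow(W1) != C || ncol(W0) != C)
    stop("attention weight shapes do not match C = ", C)
  xm <- xs; dim(xm) <- c(C, W)
  avg <- rowMeans(xm)
  mx <- apply(xm, 1L, max)
  z <- W1 %*% pmax(W0 %*% avg, 0) + W1 %*% pmax(W0 %*% mx, 0)
  w <- 1 / (1 + exp(-z))
  out <- xs * as.vector(w)
  list(weights = array(w, c(C, 1L, 1L)), output = out)
}

# Stage tensors of a single trial, reshaped to their (channel, height,
# width) form for inspection and testing.
stageTensors <- function(model, x, training = FALSE) {
  cfg <- model@config
  fw <- modelForward(model, x, training = training, keepCache = TRUE)
  N <- cfg@nElectrodes; M <- cfg@nTimepoints
  Ft <- nConcatChannels(cfg); C <- cfg@spatialFilters; J <- nPooled(cfg)
  A2 <- fw$cache$xhatT * fw$cache$gRow + fw$cache$bRow  # (Ft*N) x M
  concat <- array(0, c(Ft, N, M))
  for (c0 in seq_len(Ft))
    concat[c0, , ] <- A2[((c0 - 1L) * N + 1L):(c0 * N), ]
  pooled <- array(fw$cache$pooledD, c(C, 1L, J))
  attended <- array(fw$cache$pooledD * fw$cache$McExp, c(C, 1L, J))
  list(concat = concat, pooled = pooled, attended = attended,
       probs = fw$probs[, 1L])
}

#' Cross-entropy loss
#'
#' Mean over the batch of `-log p(true class)`; for one-hot targets this is
#' the categorical cross-entropy. Zero probabilities for the true class are
#' clamped at 1e-12 with a warning.
#'
#' @param probs class-probability matrix (nClasses x B) or vector.
#' @param labels integer class labels (0-based), length B.
#' @return scalar loss.
#' @examples
#' lossCrossEntropy(matrix(1/3, 3, 1), 0L)  # log(3)
#' @export
lossCrossEntropy <- function(probs, labels) {
  if (is.vector(probs)) probs <- matrix(probs, ncol = 1L)
  B <- ncol(probs)
  if (length(labels) != B) stop("one label per probability column required")
  pt <- probs[cbind(as.integer(labels) + 1L, seq_len(B))]
  if (any(pt <= 0)) {
    warning("zero probability for a true class; clamping at 1e-12")
    pt <- pmax(pt, 1e-12)
  }
  -mean(log(pt))
}

#' Predict class labels
#'
#' Deterministic inference-mode forward pass; ties in the argmax are broken
#' toward the lowest class index.
#'
#' @param model a trained [MSTCNModel-class].
#' @param trials an [EEGTrialSet-class] or an N x M x B array.
#' @param batchSize forward batch size (default 64).
#' @return list with `labels` (0-based predictions) and `probs`
#'   (nClasses x B).
#' @export
predictModel <- function(model, trials, batchSize = 64L) {
  x <- if (is(trials, "EEGTrialSet")) aperm(trials@data, c(2, 3, 1)) else trials
  B <- dim(x)[3]
  probs <- matrix(0, model@config@nClasses, B)
  for (s in seq(1L, B, by = batchSize)) {
    e <- min(s + batchSize - 1L, B)
    probs[, s:e] <- modelForward(model, x[, , s:e, drop = FALSE])$probs
  }
  labels <- apply(probs, 2L, which.max) - 1L   # which.max: first (lowest) tie
  list(labels = as.integer(labels), probs = probs)
}
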