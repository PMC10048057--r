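test_that("configuration validity guards the architecture invariants", {
  expect_error(modelConfig(30, 770), "divisible by poolWidth \\(64\\)")
  expect_error(modelConfig(30, 768, branchKernels = c(2, 4, 6)), "odd")
  expect_error(modelConfig(30, 768, attentionReduction = 7),
               "change attentionReduction")
  cfg <- modelConfig(30, 768)
  expect_equal(cfg@branchKernels, c(3L, 5L, 7L))
  expect_equal(cfg@poolWidth, 64L)
})

test_that("intermediate tensors have the documented shapes", {
  set.seed(51)
  cfg <- modelConfig(30, 768)
  m <- initModel(cfg)
  x <- matrix(rnorm(30 * 768), 30, 768)
  expect_equal(dim(mstcnForward(m, x)), c(24L, 30L, 768L))
  expect_equal(dim(spatialForward(m, x)), c(48L, 1L, 12L))
  fw <- modelForward(m, x)
  expect_equal(fw$shapes$concat, c(24L, 30L, 768L))
  expect_equal(fw$shapes$pooled, c(48L, 1L, 12L))
  expect_equal(fw$shapes$flatten, 576L)
  expect_length(fw$probs, 3L)
  expect_equal(sum(fw$probs), 1, tolerance = 1e-6)
  # arbitrary valid (N, M)
  cfg2 <- modelConfig(14, 256)
  m2 <- initModel(cfg2)
  fw2 <- modelForward(m2, matrix(rnorm(14 * 256), 14, 256))
  expect_equal(fw2$shapes$concat, c(24L, 14L, 256L))
  expect_equal(fw2$shapes$pooled, c(48L, 1L, 4L))
  expect_error(modelForward(m, matrix(rnorm(20), 4, 5)), "does not match")
  xBad <- x; xBad[1, 1] <- NA
  expect_error(modelForward(m, xBad), "non-finite")
})

test_that("temporal branches equal independent convolutions, concatenated", {
  set.seed(52)
  cfg <- modelConfig(4, 16, branchKernels = c(3, 5), branchFilters = 2,
                     spatialFilters = 6, poolWidth = 8,
                     attentionReduction = 2)
  m <- initModel(cfg)
  x <- matrix(rnorm(4 * 16), 4, 16)
  conc <- mstcnForward(m, x)           # BN in inference mode: stats 0/1
  eps <- m@state$eps
  # direct same-padded cross-correlation oracle per branch/filter/electrode
  for (i in 1:2) {
    S <- cfg@branchKernels[i]
    h <- (S - 1) / 2
    for (f in 1:2) {
      w <- m@params$branchW[[i]][f, ]
      for (n in 1:4) {
        ref <- vapply(1:16, function(t0) {
          acc <- m@params$branchB[[i]][f]
          for (s in 1:S) {
            tt <- t0 + s - h - 1
            if (tt >= 1 && tt <= 16) acc <- acc + w[s] * x[n, tt]
          }
          acc
        }, numeric(1))
        c0 <- (i - 1) * 2 + f
        expect_equal(conc[c0, n, ], ref / sqrt(1 + eps), tolerance = 1e-10)
      }
    }
  }
})

test_that("zeroed convolutions propagate zeros through BN and ELU", {
  set.seed(53)
  cfg <- modelConfig(6, 64, poolWidth = 16, attentionReduction = 8)
  m <- initModel(cfg)
  m@params$branchW <- lapply(m@params$branchW, function(w) w * 0)
  m@params$branchB <- lapply(m@params$branchB, function(b) b * 0)
  x <- matrix(rnorm(6 * 64), 6, 64)
  expect_equal(max(abs(mstcnForward(m, x))), 0)
  # with the spatial path also zeroed, ELU(0) = 0 and pooling of a
  # constant block is that constant
  m@params$spatialW <- m@params$spatialW * 0
  m@params$spatialB <- m@params$spatialB * 0
  expect_equal(max(abs(spatialForward(m, x))), 0)
})

test_that("channel attention matches a hand-evaluated closed form", {
  # zero MLP -> sigmoid(0) = 0.5 gates
  xs <- array(rnorm(6 * 1 * 4), c(6, 1, 4))
  att0 <- channelAttention(xs, matrix(0, 3, 6), matrix(0, 6, 3))
  expect_equal(as.vector(att0$weights), rep(0.5, 6))
  expect_equal(att0$output, 0.5 * xs)
  # 2-channel hand computation
  xs2 <- array(c(1, -1, 2, 3, -2, 0.5), c(2, 1, 3))
  W0 <- matrix(c(0.5, -0.25, 1, 0.75), 2, 2)
  W1 <- matrix(c(1, 0.5, -0.5, 0.25), 2, 2)
  avg <- rowMeans(xs2[, 1, ]); mx <- apply(xs2[, 1, ], 1, max)
  zHand <- W1 %*% pmax(W0 %*% avg, 0) + W1 %*% pmax(W0 %*% mx, 0)
  att <- channelAttention(xs2, W0, W1)
  expect_equal(as.vector(att$weights), as.vector(1 / (1 + exp(-zHand))))
  expect_equal(att$output, xs2 * as.vector(att$weights))
  # gates strictly in (0, 1) for random finite inputs
  set.seed(54)
  att2 <- channelAttention(matrix(rnorm(8 * 5), 8, 5),
                           matrix(rnorm(16), 2, 8), matrix(rnorm(16), 8, 2))
  expect_true(all(att2$weights > 0 & att2$weights < 1))
})

test_that("attention weights permute with feature channels", {
  set.seed(55)
  xs <- matrix(rnorm(8 * 6), 8, 6)
  W0 <- matrix(rnorm(2 * 8), 2, 8)
  W1 <- matrix(rnorm(8 * 2), 8, 2)
  w <- as.vector(channelAttention(xs, W0, W1)$weights)
  perm <- sample(8)
  wP <- as.vector(channelAttention(xs[perm, ], W0[, perm],
                                   W1[perm, ])$weights)
  expect_equal(wP, w[perm])
})

test_that("cross-entropy loss matches its closed forms", {
  expect_equal(lossCrossEntropy(rep(1 / 3, 3), 1L), log(3))
  expect_equal(lossCrossEntropy(c(0, 1, 0), 1L), 0)
  probs <- cbind(c(0.5, 0.3, 0.2), c(0.25, 0.25, 0.5))
  expect_equal(lossCrossEntropy(probs, c(0L, 0L)), (log(2) + log(4)) / 2)
  expect_warning(l <- lossCrossEntropy(c(0, 1, 0), 0L), "clamping")
  expect_equal(l, -log(1e-12))
})

test_that("parameter counts are deterministic and scale as documented", {
  cfg <- modelConfig(30, 768)
  n1 <- countParameters(cfg)
  expect_identical(n1, countParameters(modelConfig(30, 768)))
  bd <- attr(n1, "breakdown")
  expect_equal(unname(bd["temporalConv"]), 8 * (4 + 6 + 8))
  expect_equal(unname(bd["spatialConv"]), 48 * 24 * 30 + 48)
  expect_equal(unname(bd["attention"]), 2 * 48 * 6)
  expect_equal(unname(bd["classifier"]), 3 * 576 + 3)
  # doubling branch filters doubles the spatial conv weight count
  cfg2 <- modelConfig(30, 768, branchFilters = 16)
  bd2 <- attr(countParameters(cfg2), "breakdown")
  expect_equal(unname(bd2["spatialConv"] - 48), 2 * unname(bd["spatialConv"] - 48))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(56)
  cfg <- modelConfig(4, 32, branchKernels = c(3, 5), branchFilters = 2,
                     spatialFilters = 6, poolWidth = 8, dropout = 0,
                     attentionReduction = 2)
  m <- initModel(cfg)
  B <- 4
  xb <- array(rnorm(4 * 32 * B), c(4, 32, B))
  yb <- c(0L, 1L, 2L, 1L)
  fw <- modelForward(m, xb, training = TRUE, keepCache = TRUE)
  gr <- forceMI:::modelBackward(m, fw$cache, yb)
  fg <- forceMI:::flattenParams(gr)
  fp <- forceMI:::flattenParams(m@params)
  lossAt <- function(flat) {
    mm <- m
    mm@params <- forceMI:::unflattenParams(flat, m@params)
    f <- modelForward(mm, xb, training = TRUE)
    lossCrossEntropy(f$probs, yb)
  }
  eps <- 1e-5
  for (nm in names(fp)) {
    k <- sample(length(fp[[nm]]), min(3, length(fp[[nm]])))
    for (j in k) {
      up <- fp; up[[nm]][j] <- up[[nm]][j] + eps
      dn <- fp; dn[[nm]][j] <- dn[[nm]][j] - eps
      num <- (lossAt(up) - lossAt(dn)) / (2 * eps)
      expect_equal(fg[[nm]][j], num, tolerance = 1e-4,
                   label = paste("grad", nm, j))
    }
  }
  # gradients are finite everywhere
  expect_true(all(vapply(fg, function(g) all(is.finite(g)), logical(1))))
})

test_that("inference mode is deterministic and training mode is not", {
  set.seed(57)
  cfg <- modelConfig(6, 64, poolWidth = 16)
  m <- initModel(cfg)
  x <- matrix(rnorm(6 * 64), 6, 64)
  p1 <- modelForward(m, x)$probs
  p2 <- modelForward(m, x)$probs
  expect_identical(p1, p2)
})

test_that("the decoder can memorize a tiny random training set", {
  set.seed(58)
  n <- 12
  dat <- array(rnorm(n * 6 * 64), c(n, 6, 64))
  labels <- rep(0:2, each = 4)
  trials <- normalizeTrials(new("EEGTrialSet", data = dat,
                                labels = as.integer(labels), fs = 128,
                                window = c(0, 0.5),
                                channelLabels = paste0("e", 1:6)))
  cfg <- modelConfig(6, 64, poolWidth = 16, dropout = 0)
  fit <- trainModel(trials, cfg, trainConfig(nIterations = 200, batchSize = 4,
                                             seed = 58))
  pr <- predictModel(fit$model, trials)
  expect_equal(mean(pr$labels == labels), 1)
})
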