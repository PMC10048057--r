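test_that("stratified folds are balanced, disjoint and exhaustive", {
  labels <- rep(0:2, each = 72)
  folds <- kfoldSplit(labels, 4, seed = 7)
  sizes <- vapply(folds, function(f) length(f$test), integer(1))
  expect_equal(sizes, rep(54L, 4))
  for (f in folds) {
    expect_equal(as.vector(table(labels[f$test])), rep(18L, 3))
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), seq_along(labels))
  }
  expect_setequal(unlist(lapply(folds, `[[`, "test")), seq_along(labels))
  # deterministic given the seed
  expect_identical(folds, kfoldSplit(labels, 4, seed = 7))
  expect_false(identical(folds, kfoldSplit(labels, 4, seed = 8)))
  # uneven class sizes stay within one trial per fold
  f2 <- kfoldSplit(c(rep(0, 10), rep(1, 7), rep(2, 9)), 4, seed = 1)
  perClass <- sapply(f2, function(f) table(factor(c(rep(0, 10), rep(1, 7),
                                                    rep(2, 9))[f$test],
                                                  levels = 0:2)))
  expect_true(all(apply(perClass, 1, function(v) diff(range(v)) <= 1)))
  expect_error(kfoldSplit(c(0, 0, 0, 1, 2), 4), "fewer than 4")
})

test_that("accuracy readings match hand-counted confusion matrices", {
  perfect <- diag(c(18L, 18L, 18L))
  acc <- accuracyFromConfusion(perfect)
  expect_equal(unname(acc["fractionCorrect"]), 100)
  expect_equal(unname(acc["macroOvr"]), 100)
  conf <- rbind(c(16, 2, 0), c(1, 17, 0), c(0, 0, 18))
  acc2 <- accuracyFromConfusion(conf)
  expect_equal(unname(acc2["fractionCorrect"]), 100 * 51 / 54)
  # one-vs-rest by hand: (51 + 51 + 54) / (3 * 54)
  expect_equal(unname(acc2["macroOvr"]), 100 * 156 / 162)
  # report from raw predictions reproduces the confusion matrix
  set.seed(61)
  true <- sample(0:2, 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.7, true, sample(0:2, 60, replace = TRUE))
  rep0 <- classificationReport(true, pred)
  expect_equal(sum(rep0$confusion), 60)
  expect_equal(unname(rowSums(rep0$confusion)),
               as.vector(table(factor(true, 0:2))))
  expect_equal(rep0$fractionCorrect, 100 * mean(true == pred))
  expect_equal(unname(accuracyFromConfusion(rep0$confusion)["fractionCorrect"]),
               rep0$fractionCorrect)
})

test_that("paired t-test handles conventions and matches the formula", {
  expect_equal(pairedTTest(c(80, 85, 90), c(80, 85, 90)),
               list(t = 0, p = 1, meanDiff = 0, df = 2L))
  expect_error(pairedTTest(c(80, 85, 90), c(78, 83, 88)), "zero-variance")
  expect_error(pairedTTest(1:3, 1:4), "equal length")
  a <- c(86.4, 90.1, 75.0); b <- c(82.3, 88.8, 70.1)
  res <- pairedTTest(a, b)
  d <- a - b
  tHand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$t, tHand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(tHand), df = 2), tolerance = 1e-12)
})

test_that("training is seeded-deterministic and inert at lr = 0", {
  trials <- tinySeparableTrials()
  cfg <- modelConfig(6, 64, poolWidth = 16)
  tc <- trainConfig(nIterations = 3, batchSize = 8, seed = 5)
  f1 <- trainModel(trials, cfg, tc, heldOut = trials)
  f2 <- trainModel(trials, cfg, tc, heldOut = trials)
  expect_identical(f1$lossCurve, f2$lossCurve)
  expect_identical(f1$accCurve, f2$accCurve)
  expect_identical(f1$model@params, f2$model@params)
  # lr = 0 leaves the initialization untouched
  tc0 <- trainConfig(nIterations = 3, batchSize = 8, seed = 5, lr = 0)
  f0 <- trainModel(trials, cfg, tc0)
  set.seed(5)
  init <- initModel(cfg)
  expect_equal(f0$model@params, init@params)
  # per-iteration loss varies only through batch composition and dropout
  expect_lt(diff(range(f0$lossCurve)), 0.05)
})

test_that("loss falls on separable data for both optimizers", {
  trials <- tinySeparableTrials(nPerClass = 10)
  cfg <- modelConfig(6, 64, poolWidth = 16, dropout = 0)
  fitA <- trainModel(trials, cfg, trainConfig(nIterations = 30,
                                              batchSize = 10, seed = 6))
  expect_lt(fitA$lossCurve[30], fitA$lossCurve[1])
  fitS <- trainModel(trials, cfg, trainConfig(nIterations = 30,
                                              batchSize = 10, seed = 6,
                                              optimizer = "sgd", lr = 0.01))
  expect_lt(fitS$lossCurve[30], fitS$lossCurve[1])
})

test_that("cross-validation reports cohere with their own folds", {
  trials <- tinySeparableTrials(nPerClass = 8)
  cfg <- modelConfig(6, 64, poolWidth = 16, dropout = 0)
  tc <- trainConfig(nIterations = 20, batchSize = 8, seed = 13, folds = 2)
  rep0 <- crossValidate(trials, cfg, tc)
  expect_s4_class(rep0, "EvalReport")
  expect_length(rep0@foldAccuracy, 2)
  expect_equal(sum(rep0@confusion), nTrials(trials))
  expect_equal(unname(rowSums(rep0@confusion)), c(8L, 8L, 8L))
  # pooled confusion agrees with the pooled accuracy
  pooled <- 100 * sum(diag(rep0@confusion)) / sum(rep0@confusion)
  expect_equal(mean(rep0@foldAccuracy), pooled)  # equal fold sizes
  expect_length(rep0@lossCurves[[1]], 20)
  expect_length(rep0@accCurves[[1]], 20)
  # learns the separable structure
  expect_gt(mean(rep0@foldAccuracy), 60)
  # reproducible end to end
  rep1 <- crossValidate(trials, cfg, tc)
  expect_identical(rep0@foldAccuracy, rep1@foldAccuracy)
  expect_identical(rep0@confusion, rep1@confusion)
})

test_that("kernel sweep validates triples and reuses identical splits", {
  trials <- tinySeparableTrials(nPerClass = 6)
  cfg <- modelConfig(6, 64, poolWidth = 16, dropout = 0)
  tc <- trainConfig(nIterations = 4, batchSize = 6, seed = 3, folds = 2)
  expect_error(kernelSweep(trials, list(c(5, 3, 7)), tc, cfg),
               "strictly increasing")
  expect_error(kernelSweep(trials, list(c(3, 4, 7)), tc, cfg), "odd")
  tab <- kernelSweep(trials, list(c(3, 7, 11)), tc, cfg)
  # the default triple is always included
  expect_true("3-5-7" %in% tab$label)
  expect_equal(nrow(tab), 2L)
  expect_true(all(diff(tab$meanAccuracy) <= 0))   # sorted decreasing
  tab2 <- kernelSweep(trials, list(c(3, 7, 11)), tc, cfg)
  expect_identical(tab, tab2)
})
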