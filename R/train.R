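#' Training configuration
#'
#' @param nIterations training iterations (default 500); one iteration is
#'   one full pass (epoch) over the training set.
#' @param batchSize mini-batch size (default 16).
#' @param lr learning rate (default 0.001).
#' @param optimizer `"adam"` (default) or `"sgd"` (plain gradient descent).
#' @param seed RNG seed governing split, initialization, shuffling and
#'   dropout (default 1).
#' @param folds cross-validation folds (default 4).
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(nIterations = 500, batchSize = 16, lr = 0.001,
                        optimizer = "adam", seed = 1, folds = 4) {
  new("TrainConfig", nIterations = as.integer(nIterations),
      batchSize = as.integer(batchSize), lr = as.numeric(lr),
      optimizer = optimizer, seed = as.integer(seed),
      folds = as.integer(folds))
}

#' Stratified k-fold split
#'
#' Splits trial indices into k disjoint folds whose union is all trials,
#' preserving per-class proportions within one trial per fold. The split is
#' a deterministic function of the labels and the seed.
#'
#' @param labels per-trial class labels.
#' @param k number of folds (default 4).
#' @param seed RNG seed.
#' @return list of `k` lists with integer elements `train` and `test`.
#' @export
kfoldSplit <- function(labels, k = 4, seed = 1) {
  labels <- as.integer(labels)
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    if (length(idx) < k)
      stop("class ", cls, " has fewer than ", k, " trials")
    fold[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
}

# Convert an EEGTrialSet (or array) to the (N, M, B) layout + labels.
asModelInput <- function(trials) {
  if (is(trials, "EEGTrialSet"))
    list(x = aperm(trials@data, c(2, 3, 1)), y = trials@labels)
  else stop("expected an EEGTrialSet")
}

#' Train the decoder
#'
#' Supervised mini-batch training with cross-entropy loss. One iteration is
#' one full pass over the training set; the training loss is recorded per
#' iteration and, if a held-out set is supplied, so is its inference-mode
#' accuracy, yielding the loss and accuracy curves. Training is a
#' deterministic function of the inputs and `cfg@seed` on CPU.
#'
#' @param trials an [EEGTrialSet-class] of normalized training trials.
#' @param modelCfg a [ModelConfig-class]; defaults to the trial dimensions.
#' @param cfg a [TrainConfig-class].
#' @param heldOut optional [EEGTrialSet-class] scored each iteration.
#' @param model optional pre-initialized [MSTCNModel-class] to continue
#'   training.
#' @return list with `model` (the final-iteration weights; no early
#'   stopping), `lossCurve` and `accCurve`.
#' @export
trainModel <- function(trials, modelCfg = NULL, cfg = trainConfig(),
                       heldOut = NULL, model = NULL) {
  inp <- asModelInput(trials)
  d <- dim(inp$x)
  if (is.null(modelCfg)) modelCfg <- modelConfig(d[1], d[2])
  set.seed(cfg@seed)
  if (is.null(model)) model <- initModel(modelCfg)
  opt <- initOptimizer(model@params, cfg@optimizer, cfg@lr)
  nTr <- d[3]
  lossCurve <- numeric(cfg@nIterations)
  accCurve <- if (!is.null(heldOut)) numeric(cfg@nIterations) else numeric(0)
  for (it in seq_len(cfg@nIterations)) {
    ord <- sample(nTr)
    losses <- numeric(0)
    for (s in seq(1L, nTr, by = cfg@batchSize)) {
      b <- ord[s:min(s + cfg@batchSize - 1L, nTr)]
      fw <- modelForward(model, inp$x[, , b, drop = FALSE],
                         training = TRUE, keepCache = TRUE)
      loss <- lossCrossEntropy(fw$probs, inp$y[b])
      if (!is.finite(loss))
        stop("non-finite training loss at iteration ", it,
             "; try a lower learning rate")
      losses <- c(losses, loss)
      grads <- modelBackward(model, fw$cache, inp$y[b])
      stepRes <- optimizerStep(model@params, grads, opt)
      model@params <- stepRes$params
      opt <- stepRes$opt
      model <- updateRunningStats(model, fw$cache)
    }
    lossCurve[it] <- mean(losses)
    if (!is.null(heldOut)) {
      pr <- predictModel(model, heldOut)
      accCurve[it] <- 100 * mean(pr$labels == heldOut@labels)
    }
  }
  list(model = model, lossCurve = lossCurve, accCurve = accCurve)
}

#' Confusion matrix and the two accuracy readings
#'
#' Builds the confusion matrix (rows true, columns predicted) and computes
#' accuracy both as the plain fraction correct and as the macro-averaged
#' one-vs-rest form of the binary accuracy formula
#' `(TP + TN) / (TP + TN + FP + FN)` (the two coincide only for two
#' classes).
#'
#' @param true,predicted 0-based class labels.
#' @param nClasses number of classes (default 3).
#' @return list with `confusion`, `fractionCorrect` (%), `macroOvr` (%).
#' @export
classificationReport <- function(true, predicted, nClasses = 3) {
  conf <- matrix(0L, nClasses, nClasses,
                 dimnames = list(true = 0:(nClasses - 1),
                                 predicted = 0:(nClasses - 1)))
  for (i in seq_along(true))
    conf[true[i] + 1L, predicted[i] + 1L] <-
      conf[true[i] + 1L, predicted[i] + 1L] + 1L
  list(confusion = conf,
       fractionCorrect = 100 * sum(diag(conf)) / sum(conf),
       macroOvr = 100 * macroOvrAccuracy(conf))
}

#' Accuracy readings from a confusion matrix
#'
#' @param conf confusion matrix, rows true, columns predicted.
#' @return named vector with `fractionCorrect` and `macroOvr`, in percent.
#' @examples
#' accuracyFromConfusion(diag(c(18, 18, 18)))
#' @export
accuracyFromConfusion <- function(conf) {
  c(fractionCorrect = 100 * sum(diag(conf)) / sum(conf),
    macroOvr = 100 * macroOvrAccuracy(conf))
}

macroOvrAccuracy <- function(conf) {
  n <- sum(conf)
  k <- nrow(conf)
  mean(vapply(seq_len(k), function(c0) {
    tp <- conf[c0, c0]
    fn <- sum(conf[c0, ]) - tp
    fp <- sum(conf[, c0]) - tp
    tn <- n - tp - fn - fp
    (tp + tn) / n
  }, numeric(1)))
}

#' Evaluate a trained decoder on a trial set
#'
#' @param model a trained [MSTCNModel-class].
#' @param trials an [EEGTrialSet-class].
#' @return list with `confusion`, `fractionCorrect`, `macroOvr`,
#'   `predicted`.
#' @export
evaluateModel <- function(model, trials) {
  pr <- predictModel(model, trials)
  rep0 <- classificationReport(trials@labels, pr$labels,
                               model@config@nClasses)
  rep0$predicted <- pr$labels
  rep0
}

#' Stratified cross-validated training and evaluation
#'
#' Runs [kfoldSplit()], trains one decoder per fold (the held-out fold
#' supplies the per-iteration accuracy curve), and pools the held-out
#' predictions into an [EvalReport-class].
#'
#' @param trials an [EEGTrialSet-class] of normalized trials.
#' @param modelCfg optional [ModelConfig-class].
#' @param cfg a [TrainConfig-class].
#' @param verbose print per-fold progress.
#' @return an [EvalReport-class].
#' @export
crossValidate <- function(trials, modelCfg = NULL, cfg = trainConfig(),
                          verbose = FALSE) {
  folds <- kfoldSplit(trials@labels, cfg@folds, cfg@seed)
  d <- dim(trials@data)
  if (is.null(modelCfg)) modelCfg <- modelConfig(d[2], d[3])
  foldAcc <- numeric(length(folds))
  foldOvr <- numeric(length(folds))
  lossCurves <- vector("list", length(folds))
  accCurves <- vector("list", length(folds))
  conf <- matrix(0L, modelCfg@nClasses, modelCfg@nClasses,
                 dimnames = list(true = seq_len(modelCfg@nClasses) - 1,
                                 predicted = seq_len(modelCfg@nClasses) - 1))
  for (f in seq_along(folds)) {
    tr <- subsetTrials(trials, folds[[f]]$train)
    te <- subsetTrials(trials, folds[[f]]$test)
    foldCfg <- cfg
    foldCfg@seed <- cfg@seed + 101L * f
    fit <- trainModel(tr, modelCfg, foldCfg, heldOut = te)
    ev <- evaluateModel(fit$model, te)
    foldAcc[f] <- ev$fractionCorrect
    foldOvr[f] <- ev$macroOvr
    conf <- conf + ev$confusion
    lossCurves[[f]] <- fit$lossCurve
    accCurves[[f]] <- fit$accCurve
    if (verbose)
      message(sprintf("fold %d/%d: accuracy %.1f%%", f, length(folds),
                      ev$fractionCorrect))
  }
  new("EvalReport", foldAccuracy = foldAcc, macroOvrAccuracy = foldOvr,
      confusion = conf, lossCurves = lossCurves, accCurves = accCurves,
      settings = list(seed = cfg@seed, folds = cfg@folds,
                      nIterations = cfg@nIterations,
                      batchSize = cfg@batchSize, lr = cfg@lr,
                      optimizer = cfg@optimizer,
                      branchKernels = modelCfg@branchKernels,
                      nElectrodes = modelCfg@nElectrodes,
                      nTimepoints = modelCfg@nTimepoints))
}

# Subset an EEGTrialSet by trial indices.
subsetTrials <- function(trials, idx) {
  new("EEGTrialSet", data = trials@data[idx, , , drop = FALSE],
      labels = trials@labels[idx], fs = trials@fs, window = trials@window,
      channelLabels = trials@channelLabels)
}

#' Paired t-test on per-subject accuracies
#'
#' Two-sided paired t-test (via [stats::t.test()]). Identical vectors give
#' the conventional `t = 0`, `p = 1`; a constant non-zero difference (zero
#' variance) is a degenerate input and raises an error.
#'
#' @param accA,accB equal-length paired accuracy vectors (one per subject).
#' @return list with `t`, `p`, `meanDiff`, `df`.
#' @export
pairedTTest <- function(accA, accB) {
  if (length(accA) != length(accB))
    stop("paired vectors must have equal length")
  if (length(accA) < 2L) stop("need at least 2 pairs")
  d <- accA - accB
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 1, meanDiff = 0, df = length(d) - 1L))
    stop("zero-variance differences; paired t-test undefined")
  }
  ht <- stats::t.test(accA, accB, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       meanDiff = unname(ht$estimate), df = unname(ht$parameter))
}

#' Temporal kernel-size combination sweep
#'
#' Re-runs the full cross-validation for each combination of the three
#' temporal kernel widths, with identical seeds and therefore identical
#' fold splits across combinations, and tabulates mean accuracy. The
#' default combination (3, 5, 7) is always included.
#'
#' @param trials an [EEGTrialSet-class].
#' @param kernelTriples list of strictly increasing odd width triples.
#' @param cfg a [TrainConfig-class].
#' @param modelCfg optional base [ModelConfig-class]; its kernel widths are
#'   replaced per combination.
#' @param verbose print progress.
#' @return data.frame with columns `s`, `m`, `l`, `label`, `meanAccuracy`,
#'   `sdAccuracy`, sorted by decreasing mean accuracy.
#' @export
kernelSweep <- function(trials, kernelTriples = list(c(3, 5, 7), c(3, 7, 11),
                                                     c(3, 9, 15)),
                        cfg = trainConfig(), modelCfg = NULL,
                        verbose = FALSE) {
  hasDefault <- any(vapply(kernelTriples, function(kt)
    identical(as.integer(kt), c(3L, 5L, 7L)), logical(1)))
  if (!hasDefault) kernelTriples <- c(list(c(3, 5, 7)), kernelTriples)
  for (kt in kernelTriples) {
    if (is.unsorted(kt, strictly = TRUE) || any(kt %% 2 != 1))
      stop("kernel triples must be strictly increasing odd widths")
  }
  d <- dim(trials@data)
  if (is.null(modelCfg)) modelCfg <- modelConfig(d[2], d[3])
  rows <- lapply(kernelTriples, function(kt) {
    mc <- modelCfg
    mc@branchKernels <- as.integer(kt)
    rep0 <- crossValidate(trials, mc, cfg, verbose = FALSE)
    if (verbose)
      message(sprintf("kernels (%s): %.1f%%",
                      paste(kt, collapse = ","),
                      mean(rep0@foldAccuracy)))
    data.frame(s = kt[1], m = kt[2], l = kt[3],
               label = paste(kt, collapse = "-"),
               meanAccuracy = mean(rep0@foldAccuracy),
               sdAccuracy = stats::sd(rep0@foldAccuracy))
  })
  out <- do.call(rbind, rows)
  out[order(-out$meanAccuracy), , drop = FALSE]
}
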