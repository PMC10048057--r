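#' Run the simulate / preprocess / ersp / train pipeline
#'
#' Executes the requested stages in order on one output directory:
#' `simulate` writes a synthetic session container, `preprocess` turns a
#' session into a normalized trial-set container, `ersp` writes a
#' long-format CSV of ERSP maps, and `train` runs stratified
#' cross-validation and writes metrics, confusion, and curve CSVs plus a
#' JSON summary. A reproducibility manifest (configuration snapshot, seed,
#' package version, input digests, timestamp) is written last; a stage
#' failure leaves the outputs of completed stages intact. All randomness
#' derives from `config$seed`, so a rerun with the same configuration
#' reproduces the metrics byte-identically on CPU.
#'
#' The configuration is a JSON file (or an equivalent named list) with
#' fields `stages` (subset of simulate/preprocess/ersp/train), `seed`, and
#' one optional block per stage; unknown fields are an error. If
#' `config$inputDigests` is given, each named input file must match its
#' recorded MD5 digest before anything runs.
#'
#' @param config path to a JSON configuration file, or a named list.
#' @param outDir output directory (created if needed).
#' @return invisibly, the manifest as a named list.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  known <- c("stages", "seed", "simulate", "preprocess", "ersp", "train",
             "inputDigests")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  stages <- config$stages
  if (is.null(stages)) stages <- c("simulate", "preprocess", "train")
  badStage <- setdiff(stages, c("simulate", "preprocess", "ersp", "train"))
  if (length(badStage))
    stop("unknown stage(s): ", paste(badStage, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  digests <- config$inputDigests
  if (!is.null(digests)) {
    for (f in names(digests)) {
      if (!file.exists(f)) stop("declared input file missing: ", f)
      got <- unname(tools::md5sum(f))
      if (!identical(got, digests[[f]]))
        stop("input digest mismatch for ", f, ": expected ", digests[[f]],
             ", found ", got)
    }
  }

  usedInputs <- character(0)
  sessionPath <- file.path(outDir, "session.rds")
  trialsPath <- file.path(outDir, "trials.rds")

  if ("simulate" %in% stages) {
    sc <- config$simulate
    cfg <- sessionConfig(
      fs = sc$fs %||% 1000,
      nRounds = sc$nRounds %||% 9L,
      trialsPerRound = sc$trialsPerRound %||% 24L,
      seed = seed)
    rec <- generateSession(cfg)
    writeRecordingContainer(rec, sessionPath)
    if (isTRUE(sc$edf)) writeEDF(rec, file.path(outDir, "session.edf"))
  }

  if ("preprocess" %in% stages) {
    pc <- config$preprocess
    inPath <- pc$`in` %||% sessionPath
    usedInputs <- c(usedInputs, inPath)
    rec <- if (grepl("\\.edf$", inPath, ignore.case = TRUE))
      readEDF(inPath) else readRecordingContainer(inPath)
    trials <- preprocessChain(
      rec,
      window = as.numeric(pc$window %||% c(0, 6)),
      targetFs = pc$targetFs %||% 128,
      normalize = !isFALSE(pc$normalize))
    writeTrialSetContainer(trials, trialsPath)
  }

  if ("ersp" %in% stages) {
    ec <- config$ersp
    inPath <- ec$`in` %||% trialsPath
    usedInputs <- c(usedInputs, inPath)
    trials <- readTrialSetContainer(inPath)
    chans <- ec$channels %||% "C3"
    maps <- list()
    for (ch in chans)
      for (cls in 0:2)
        maps[[paste0(ch, "_class", cls)]] <- erspMap(trials, ch, class = cls)
    erspTable(maps, file.path(outDir, "ersp.csv"))
  }

  if ("train" %in% stages) {
    tc <- config$train
    inPath <- tc$`in` %||% trialsPath
    usedInputs <- c(usedInputs, inPath)
    trials <- readTrialSetContainer(inPath)
    cfg <- trainConfig(
      nIterations = tc$nIterations %||% 500,
      batchSize = tc$batchSize %||% 16,
      lr = tc$lr %||% 0.001,
      optimizer = tc$optimizer %||% "adam",
      seed = seed,
      folds = tc$folds %||% 4)
    rep0 <- crossValidate(trials, cfg = cfg)
    utils::write.csv(
      data.frame(fold = seq_along(rep0@foldAccuracy),
                 accuracy = rep0@foldAccuracy,
                 macroOvr = rep0@macroOvrAccuracy),
      file.path(outDir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(rep0@confusion),
                     file.path(outDir, "confusion.csv"), row.names = FALSE)
    curves <- do.call(rbind, lapply(seq_along(rep0@lossCurves), function(f)
      data.frame(fold = f, iteration = seq_along(rep0@lossCurves[[f]]),
                 loss = rep0@lossCurves[[f]],
                 accuracy = rep0@accCurves[[f]])))
    utils::write.csv(curves, file.path(outDir, "curves.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(meanAccuracy = mean(rep0@foldAccuracy),
           sdAccuracy = stats::sd(rep0@foldAccuracy),
           foldAccuracy = rep0@foldAccuracy,
           settings = rep0@settings),
      file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "forceMI",
    version = as.character(utils::packageVersion("forceMI")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    stages = stages,
    config = config,
    inputDigests = as.list(
      if (length(usedInputs))
        vapply(unique(usedInputs), function(f) unname(tools::md5sum(f)),
               character(1))
      else character(0))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
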