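#' @title Accessors for forceMI containers
#' @description Small accessor generics: sampling rate, channel labels,
#'   signal/trial data, event table, and trial labels.
#' @param object a forceMI container object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))

#' @rdname accessors
#' @export
setGeneric("eventTable", function(object) standardGeneric("eventTable"))

#' @rdname accessors
#' @export
setGeneric("trialData", function(object) standardGeneric("trialData"))

#' @rdname accessors
#' @export
setGeneric("trialLabels", function(object) standardGeneric("trialLabels"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("erspValues", function(object) standardGeneric("erspValues"))

#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@fs)

#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGTrialSet", function(object) object@fs)

#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(object) object@channelLabels)

#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGTrialSet", function(object) object@channelLabels)

#' @rdname accessors
#' @export
setMethod("signalMatrix", "EEGRecording", function(object) object@signals)

#' @rdname accessors
#' @export
setMethod("eventTable", "EEGRecording", function(object) object@events)

#' @rdname accessors
#' @export
setMethod("trialData", "EEGTrialSet", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("trialLabels", "EEGTrialSet", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("nTrials", "EEGTrialSet", function(object) dim(object@data)[1])

#' @rdname accessors
#' @export
setMethod("erspValues", "ERSPMap", function(object) object@db)

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording:", nrow(object@signals), "channels x",
      ncol(object@signals), "samples @", object@fs, "Hz\n")
  cat("  duration:", round(ncol(object@signals) / object@fs, 2), "s;",
      nrow(object@events), "events\n")
  if (nrow(object@events))
    cat("  classes:", paste(names(table(object@events$label)),
        table(object@events$label), sep = ":", collapse = " "), "\n")
  invisible(object)
})

setMethod("show", "EEGTrialSet", function(object) {
  d <- dim(object@data)
  cat("EEGTrialSet:", d[1], "trials x", d[2], "channels x", d[3],
      "time points @", object@fs, "Hz\n")
  cat("  window:", object@window[1], "to", object@window[2],
      "s relative to MI onset\n")
  if (length(object@labels))
    cat("  classes:", paste(names(table(object@labels)),
        table(object@labels), sep = ":", collapse = " "), "\n")
  invisible(object)
})

setMethod("show", "ERSPMap", function(object) {
  cat("ERSPMap: channel", object@channel, "-", length(object@freqs),
      "frequencies x", length(object@times), "times,", object@nTrials,
      "trials\n")
  cat("  baseline:", object@baselineWindow[1], "to",
      object@baselineWindow[2], "s; dB range",
      round(min(object@db), 2), "to", round(max(object@db), 2), "\n")
  invisible(object)
})

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig: N =", object@nElectrodes, ", M =", object@nTimepoints,
      "\n")
  cat("  temporal branches: kernels (1,",
      paste(object@branchKernels, collapse = "), (1,"), ") x",
      object@branchFilters, "filters\n")
  cat("  spatial filters:", object@spatialFilters, "; pool (1,",
      object@poolWidth, "); dropout", object@dropout,
      "; attention r =", object@attentionReduction, "\n")
  cat("  classes:", object@nClasses, "; trainable parameters:",
      countParameters(object), "\n")
  invisible(object)
})

setMethod("show", "MSTCNModel", function(object) {
  cat("MSTCNModel (fitted:", !is.null(object@state$nUpdates) &&
        object@state$nUpdates > 0, ")\n")
  show(object@config)
  invisible(object)
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport:", length(object@foldAccuracy), "folds\n")
  cat(sprintf("  accuracy: %.1f +/- %.1f %% (fraction correct)\n",
              mean(object@foldAccuracy), stats::sd(object@foldAccuracy)))
  cat(sprintf("  accuracy: %.1f %% (macro one-vs-rest)\n",
              mean(object@macroOvrAccuracy)))
  cat("  pooled confusion (rows true, cols predicted):\n")
  print(object@confusion)
  invisible(object)
})
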