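#' @import methods
NULL

#' Continuous multichannel EEG recording
#'
#' Holds a continuous EEG signal matrix (channel x sample, microvolts),
#' its sampling rate, ordered channel labels, and trial event markers.
#' Events mark the onset of the motor-imagery period of each trial and carry
#' the force-class label (0 = small, 1 = medium, 2 = large).
#'
#' @slot signals numeric matrix, channels in rows, samples in columns.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector of unique channel labels, one per row.
#' @slot events data.frame with integer columns `onset` (1-based sample index
#'   of the MI-period onset) and `label` (force class).
#' @export
setClass("EEGRecording",
  slots = c(
    signals = "matrix",
    fs = "numeric",
    channelLabels = "character",
    events = "data.frame"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@signals) != length(object@channelLabels))
    msg <- c(msg, "one channel label per signal row is required")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  ev <- object@events
  if (nrow(ev)) {
    if (!all(c("onset", "label") %in% names(ev)))
      msg <- c(msg, "events must have columns 'onset' and 'label'")
    else {
      if (is.unsorted(ev$onset))
        msg <- c(msg, "events must be sorted by onset")
      if (any(ev$onset < 1L) || any(ev$onset > ncol(object@signals)))
        msg <- c(msg, "event onsets must lie within the signal")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Epoched EEG trials
#'
#' Trials epoched relative to the motor-imagery onset, as a
#' (trial x channel x time) array with per-trial force-class labels.
#'
#' @slot data numeric array (trial x channel x time); all values finite.
#' @slot labels integer vector of force classes (0, 1, 2), one per trial.
#' @slot fs sampling rate in Hz.
#' @slot window numeric length-2, epoch window (start, end) in seconds
#'   relative to MI onset.
#' @slot channelLabels channel labels, one per array slice.
#' @export
setClass("EEGTrialSet",
  slots = c(
    data = "array",
    labels = "integer",
    fs = "numeric",
    window = "numeric",
    channelLabels = "character"
  )
)

setValidity("EEGTrialSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a trial x channel x time array")
  else {
    if (d[1] != length(object@labels))
      msg <- c(msg, "one label per trial is required")
    if (d[2] != length(object@channelLabels))
      msg <- c(msg, "one channel label per channel is required")
  }
  if (!all(is.finite(object@data)))
    msg <- c(msg, "trial data must be finite")
  if (length(object@labels) && !all(object@labels %in% 0:2))
    msg <- c(msg, "labels must be in {0, 1, 2}")
  if (length(object@window) != 2L || diff(object@window) <= 0)
    msg <- c(msg, "window must be (start, end) with end > start")
  if (length(msg)) msg else TRUE
})

#' Single-channel spectrogram
#'
#' Magnitude-squared short-time Fourier transform of one trial channel.
#'
#' @slot power numeric matrix (frequency x time), non-negative.
#' @slot freqs frequencies in Hz, one per row.
#' @slot times times in seconds (relative to MI onset), one per column.
#' @export
setClass("Spectrogram",
  slots = c(power = "matrix", freqs = "numeric", times = "numeric")
)

setValidity("Spectrogram", function(object) {
  msg <- character()
  if (nrow(object@power) != length(object@freqs))
    msg <- c(msg, "one frequency per power row is required")
  if (ncol(object@power) != length(object@times))
    msg <- c(msg, "one time per power column is required")
  if (any(object@power < 0))
    msg <- c(msg, "power must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Event-related spectral perturbation map
#'
#' Trial-averaged time-frequency power of one channel expressed in dB
#' relative to the pre-MI baseline window.
#'
#' @slot db numeric matrix (frequency x time), baseline-relative dB.
#' @slot freqs frequencies in Hz.
#' @slot times times in seconds relative to MI onset.
#' @slot nTrials number of trials averaged.
#' @slot channel channel label.
#' @slot baselineWindow baseline window (start, end) in seconds.
#' @slot edgeCols logical, one per time column: `TRUE` where the STFT
#'   analysis window crossed the epoch edge (reflection-padded frames);
#'   flagged, not dropped, and excluded from the baseline mean.
#' @export
setClass("ERSPMap",
  slots = c(
    db = "matrix",
    freqs = "numeric",
    times = "numeric",
    nTrials = "integer",
    channel = "character",
    baselineWindow = "numeric",
    edgeCols = "logical"
  )
)

setValidity("ERSPMap", function(object) {
  msg <- character()
  if (!all(is.finite(object@db)))
    msg <- c(msg, "dB values must be finite")
  if (nrow(object@db) != length(object@freqs) ||
      ncol(object@db) != length(object@times))
    msg <- c(msg, "db dimensions must match freqs x times")
  if (length(object@edgeCols) &&
      length(object@edgeCols) != length(object@times))
    msg <- c(msg, "edgeCols must flag each time column")
  if (length(msg)) msg else TRUE
})

#' Decoder architecture configuration
#'
#' Every architecture hyperparameter of the three-class decoder: the
#' multi-scale temporal convolution branch kernels and filter counts, the
#' spatial convolution filter count, the average-pooling width, the dropout
#' rate, the channel-attention reduction ratio, and the class count.
#'
#' @slot nElectrodes number of EEG channels N.
#' @slot nTimepoints number of time points M per trial; must be divisible by
#'   `poolWidth`.
#' @slot branchKernels odd temporal kernel widths, one per branch
#'   (default 3, 5, 7).
#' @slot branchFilters filters per temporal branch (default 8).
#' @slot spatialFilters spatial convolution output channels C (default 48);
#'   must be divisible by `attentionReduction`.
#' @slot poolWidth average pooling width K (default 64).
#' @slot dropout dropout probability after pooling (default 0.5).
#' @slot attentionReduction channel-attention bottleneck ratio r (default 8).
#' @slot nClasses number of output classes (default 3).
#' @export
setClass("ModelConfig",
  slots = c(
    nElectrodes = "integer",
    nTimepoints = "integer",
    branchKernels = "integer",
    branchFilters = "integer",
    spatialFilters = "integer",
    poolWidth = "integer",
    dropout = "numeric",
    attentionReduction = "integer",
    nClasses = "integer"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (object@nElectrodes < 2L) msg <- c(msg, "nElectrodes must be >= 2")
  if (object@nTimepoints < object@poolWidth)
    msg <- c(msg, "nTimepoints must be >= poolWidth")
  if (object@nTimepoints %% object@poolWidth != 0L)
    msg <- c(msg, sprintf(
      "nTimepoints (%d) must be divisible by poolWidth (%d)",
      object@nTimepoints, object@poolWidth))
  if (length(object@branchKernels) < 1L)
    msg <- c(msg, "at least one branch kernel is required")
  if (any(object@branchKernels %% 2L != 1L) || any(object@branchKernels < 1L))
    msg <- c(msg, "branch kernels must be positive odd widths")
  if (object@spatialFilters %% object@attentionReduction != 0L)
    msg <- c(msg, sprintf(paste0(
      "spatialFilters (%d) must be divisible by attentionReduction (%d); ",
      "change attentionReduction"),
      object@spatialFilters, object@attentionReduction))
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Fitted decoder
#'
#' Bundles the architecture configuration, all trainable parameters, and the
#' batch-normalization running statistics used in inference mode.
#'
#' @slot config a [ModelConfig-class].
#' @slot params named list of weight matrices and vectors.
#' @slot state named list of batch-normalization running statistics.
#' @export
setClass("MSTCNModel",
  slots = c(config = "ModelConfig", params = "list", state = "list")
)

#' Training configuration
#'
#' @slot nIterations training iterations; one iteration is one full pass over
#'   the training set (default 500).
#' @slot batchSize mini-batch size (default 16).
#' @slot lr learning rate (default 0.001).
#' @slot optimizer "adam" (default) or "sgd".
#' @slot seed integer RNG seed governing split, initialization and dropout.
#' @slot folds cross-validation fold count (default 4).
#' @export
setClass("TrainConfig",
  slots = c(
    nIterations = "integer",
    batchSize = "integer",
    lr = "numeric",
    optimizer = "character",
    seed = "integer",
    folds = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@lr < 0) msg <- c(msg, "lr must be >= 0")
  if (!object@optimizer %in% c("adam", "sgd"))
    msg <- c(msg, "optimizer must be 'adam' or 'sgd'")
  if (object@folds < 2L) msg <- c(msg, "folds must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Cross-validated evaluation report
#'
#' @slot foldAccuracy per-fold fraction-correct accuracy in percent.
#' @slot macroOvrAccuracy per-fold macro-averaged one-vs-rest accuracy in
#'   percent (the binary accuracy formula applied per class and averaged).
#' @slot confusion pooled confusion matrix; rows are true classes, columns
#'   predicted classes.
#' @slot lossCurves per-fold numeric vectors of training loss per iteration.
#' @slot accCurves per-fold numeric vectors of held-out accuracy (percent)
#'   per iteration.
#' @slot settings list fingerprint of the model/training configuration and
#'   seed used.
#' @export
setClass("EvalReport",
  slots = c(
    foldAccuracy = "numeric",
    macroOvrAccuracy = "numeric",
    confusion = "matrix",
    lossCurves = "list",
    accCurves = "list",
    settings = "list"
  )
)
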