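#' Bilateral mastoid re-referencing
#'
#' Subtracts the mean of the two mastoid channels from every channel. The
#' mastoid channels are retained (they become zero-information). If neither
#' mastoid label is present the recording is returned unchanged with a
#' warning (recordings referenced against external mastoids carry no mastoid
#' channels); a single missing mastoid is an error.
#'
#' @param rec an [EEGRecording-class].
#' @param mastoidLabels the two mastoid channel labels (default M1, M2).
#' @return the re-referenced [EEGRecording-class].
#' @export
rereferenceMastoid <- function(rec, mastoidLabels = c("M1", "M2")) {
  present <- mastoidLabels %in% rec@channelLabels
  if (!any(present)) {
    warning("mastoid channels ", paste(mastoidLabels, collapse = "/"),
            " not present; skipping re-referencing")
    return(rec)
  }
  if (!all(present))
    stop("mastoid channel '", mastoidLabels[!present][1L],
         "' absent from recording")
  i <- match(mastoidLabels, rec@channelLabels)
  ref <- colMeans(rec@signals[i, , drop = FALSE])
  rec@signals <- rec@signals - rep(ref, each = nrow(rec@signals))
  rec
}

#' Broadband band-pass and line-notch filtering
#'
#' Zero-phase 0.5-100 Hz band-pass followed by a zero-phase 50 Hz notch
#' (49-51 Hz band-stop), both Hamming windowed-sinc FIR filters. Requires
#' `fs > 200` Hz so the 100 Hz band edge lies inside the Nyquist range.
#'
#' @param rec an [EEGRecording-class].
#' @param band broadband pass edges in Hz (default 0.5, 100).
#' @param notch notch stop-band edges in Hz (default 49, 51).
#' @return the filtered [EEGRecording-class].
#' @export
filterChain <- function(rec, band = c(0.5, 100), notch = c(49, 51)) {
  if (rec@fs <= 200)
    stop("fs must exceed 200 Hz for the ", band[2], " Hz band edge")
  bp <- designFIR(rec@fs, band, "pass", transition = 0.5)
  bs <- designFIR(rec@fs, notch, "stop", transition = 1)
  rec@signals <- filterRows(filterRows(rec@signals, bp), bs)
  rec
}

#' Common average reference
#'
#' Subtracts the instantaneous mean over the included channels from each
#' included channel. Ocular and mastoid channels are excluded from the
#' average by default and left untouched. After CAR the per-sample mean over
#' included channels is exactly zero.
#'
#' @param rec an [EEGRecording-class].
#' @param exclude channel labels excluded from the average (and unchanged).
#' @return the re-referenced [EEGRecording-class].
#' @export
carReference <- function(rec, exclude = c("HEOG", "VEOG", "M1", "M2")) {
  inc <- which(!rec@channelLabels %in% exclude)
  if (length(inc) < 2L)
    stop("common average reference needs at least 2 included channels")
  avg <- colMeans(rec@signals[inc, , drop = FALSE])
  rec@signals[inc, ] <- rec@signals[inc, , drop = FALSE] -
    rep(avg, each = length(inc))
  rec
}

#' Sensorimotor-band FIR filtering
#'
#' Zero-phase Hamming windowed-sinc FIR band-pass over the mu/beta range
#' (8-30 Hz by default), removing drift and movement artifacts outside the
#' rhythms that carry the ERD features.
#'
#' @param rec an [EEGRecording-class]; `fs` must exceed 60 Hz.
#' @param band pass-band edges in Hz.
#' @param transition FIR transition width in Hz (default 5).
#' @return the filtered [EEGRecording-class].
#' @export
miBandpass <- function(rec, band = c(8, 30), transition = 5) {
  if (rec@fs <= 60)
    stop("fs must exceed 60 Hz for the ", band[2], " Hz band edge")
  b <- designFIR(rec@fs, band, "pass", transition = transition)
  rec@signals <- filterRows(rec@signals, b)
  rec
}

#' Resample a recording
#'
#' Polyphase resampling to the target rate (128 Hz by default). Event onset
#' samples are rescaled by `targetFs/fs` and rounded to the nearest sample.
#' The signal must already be band-limited below `targetFs/2` (guaranteed by
#' [miBandpass()] in the standard chain).
#'
#' @param rec an [EEGRecording-class].
#' @param targetFs target sampling rate in Hz; must be below `fs`.
#' @return the resampled [EEGRecording-class].
#' @export
downsampleRecording <- function(rec, targetFs = 128) {
  if (targetFs >= rec@fs)
    stop("targetFs (", targetFs, ") must be below fs (", rec@fs, ")")
  g <- gcdInt(round(targetFs), round(rec@fs))
  p <- round(targetFs) / g
  q <- round(rec@fs) / g
  out <- t(apply(rec@signals, 1L, function(x) signal::resample(x, p, q)))
  ev <- rec@events
  if (nrow(ev)) {
    ev$onset <- as.integer(round((ev$onset - 1L) * targetFs / rec@fs)) + 1L
    ev$onset <- pmin(ev$onset, ncol(out))
  }
  new("EEGRecording", signals = out, fs = targetFs,
      channelLabels = rec@channelLabels, events = ev)
}

gcdInt <- function(a, b) if (b == 0) a else gcdInt(b, a %% b)

#' Drop ocular channels
#'
#' Removes the HEOG and VEOG channels; all other channels are unchanged and
#' keep their order. A no-op (with a warning) if no ocular channel is
#' present.
#'
#' @param rec an [EEGRecording-class].
#' @param eogLabels ocular channel labels to remove.
#' @return the reduced [EEGRecording-class].
#' @export
dropEOG <- function(rec, eogLabels = c("HEOG", "VEOG")) {
  drop <- rec@channelLabels %in% eogLabels
  if (!any(drop)) {
    warning("no ocular channels (", paste(eogLabels, collapse = "/"),
            ") present; nothing to drop")
    return(rec)
  }
  new("EEGRecording", signals = rec@signals[!drop, , drop = FALSE],
      fs = rec@fs, channelLabels = rec@channelLabels[!drop],
      events = rec@events)
}

#' Epoch a recording into trials
#'
#' Cuts a window relative to each event's MI onset. The default (0, 6) s
#' classification window gives M = 768 time points at 128 Hz; the (-1, 6) s
#' window used for ERSP baselining gives 896.
#'
#' @param rec an [EEGRecording-class] with events.
#' @param window epoch window (start, end) in seconds relative to MI onset.
#' @return an [EEGTrialSet-class] (trial x channel x time).
#' @export
epochTrials <- function(rec, window = c(0, 6)) {
  if (nrow(rec@events) == 0L) stop("recording has no events to epoch")
  nSamp <- round(diff(window) * rec@fs)
  startOff <- round(window[1] * rec@fs)
  nCh <- nrow(rec@signals)
  nTr <- nrow(rec@events)
  dat <- array(0, c(nTr, nCh, nSamp))
  for (i in seq_len(nTr)) {
    from <- rec@events$onset[i] + startOff
    to <- from + nSamp - 1L
    if (from < 1L || to > ncol(rec@signals))
      stop("epoch window (", window[1], ", ", window[2],
           ") s exceeds recording bounds for trial ", i)
    dat[i, , ] <- rec@signals[, from:to]
  }
  new("EEGTrialSet", data = dat, labels = as.integer(rec@events$label),
      fs = rec@fs, window = as.numeric(window),
      channelLabels = rec@channelLabels)
}

#' Per-trial z-normalization
#'
#' Standardizes each trial with a single scalar mean and population standard
#' deviation computed over all its channels and time points, so every trial
#' has mean 0 and SD 1. Per-channel normalization is available as an option.
#'
#' @param trials an [EEGTrialSet-class].
#' @param perChannel if `TRUE`, normalize each channel of each trial
#'   separately instead of globally (default `FALSE`).
#' @return the normalized [EEGTrialSet-class].
#' @export
normalizeTrials <- function(trials, perChannel = FALSE) {
  d <- dim(trials@data)
  for (i in seq_len(d[1])) {
    x <- trials@data[i, , ]
    if (perChannel) {
      mu <- rowMeans(x)
      sdv <- sqrt(rowMeans((x - mu)^2))
      if (any(sdv == 0))
        stop("zero-variance channel in trial ", i, "; cannot normalize")
      trials@data[i, , ] <- (x - mu) / sdv
    } else {
      mu <- mean(x)
      sdv <- sqrt(mean((x - mu)^2))
      if (sdv == 0)
        stop("zero-variance trial ", i, "; cannot normalize")
      trials@data[i, , ] <- (x - mu) / sdv
    }
  }
  trials
}

#' Full preprocessing chain
#'
#' Applies, in order: bilateral mastoid re-referencing, 0.5-100 Hz band-pass
#' plus 50 Hz notch, common average reference, 8-30 Hz FIR band-pass,
#' resampling to 128 Hz, ocular channel removal, epoching, and per-trial
#' z-normalization.
#'
#' @param rec an [EEGRecording-class].
#' @param window epoch window (start, end) s relative to MI onset.
#' @param targetFs resampling target in Hz (default 128).
#' @param normalize apply [normalizeTrials()] (default `TRUE`).
#' @param mastoidLabels passed to [rereferenceMastoid()].
#' @return an [EEGTrialSet-class].
#' @export
preprocessChain <- function(rec, window = c(0, 6), targetFs = 128,
                            normalize = TRUE,
                            mastoidLabels = c("M1", "M2")) {
  rec <- withCallingHandlers(
    rereferenceMastoid(rec, mastoidLabels),
    warning = function(w) invokeRestart("muffleWarning"))
  rec <- filterChain(rec)
  rec <- carReference(rec)
  rec <- miBandpass(rec)
  if (targetFs < rec@fs) rec <- downsampleRecording(rec, targetFs)
  rec <- withCallingHandlers(
    dropEOG(rec),
    warning = function(w) invokeRestart("muffleWarning"))
  trials <- epochTrials(rec, window)
  if (normalize) trials <- normalizeTrials(trials)
  trials
}
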