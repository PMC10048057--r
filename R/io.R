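# Session and trial containers (RDS-based) and a minimal EDF+ reader/writer
# (16-bit European Data Format with an annotations channel carrying the
# trial event markers). The EDF code is self-contained base R.

#' Write / read the package's recording container
#'
#' Stores an [EEGRecording-class] (signals, sampling rate, channel labels,
#' events) in a single-file RDS container.
#'
#' @param rec an [EEGRecording-class].
#' @param path file path.
#' @return `readRecordingContainer` returns the [EEGRecording-class].
#' @export
writeRecordingContainer <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  saveRDS(list(type = "forceMI-recording", version = 1L,
               signals = rec@signals, fs = rec@fs,
               channelLabels = rec@channelLabels, events = rec@events),
          path)
  invisible(path)
}

#' @rdname writeRecordingContainer
#' @export
readRecordingContainer <- function(path) {
  x <- readRDS(path)
  if (!identical(x$type, "forceMI-recording"))
    stop("not a forceMI recording container: ", path)
  new("EEGRecording", signals = x$signals, fs = x$fs,
      channelLabels = x$channelLabels, events = x$events)
}

#' Write / read the package's trial-set container
#'
#' @param trials an [EEGTrialSet-class].
#' @param path file path.
#' @return `readTrialSetContainer` returns the [EEGTrialSet-class].
#' @export
writeTrialSetContainer <- function(trials, path) {
  stopifnot(is(trials, "EEGTrialSet"))
  saveRDS(list(type = "forceMI-trials", version = 1L, data = trials@data,
               labels = trials@labels, fs = trials@fs,
               window = trials@window,
               channelLabels = trials@channelLabels),
          path)
  invisible(path)
}

#' @rdname writeTrialSetContainer
#' @export
readTrialSetContainer <- function(path) {
  x <- readRDS(path)
  if (!identical(x$type, "forceMI-trials"))
    stop("not a forceMI trial container: ", path)
  new("EEGTrialSet", data = x$data, labels = x$labels, fs = x$fs,
      window = x$window, channelLabels = x$channelLabels)
}

padField <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

#' Write a recording to EDF+
#'
#' Writes continuous signals as 16-bit EDF with one-second data records and
#' an `EDF Annotations` channel carrying one `class <k>` annotation per
#' trial event at its MI-onset time. The recording is zero-padded to a
#' whole number of records. Physical ranges are taken per channel from the
#' data.
#'
#' @param rec an [EEGRecording-class]; `fs` must be a whole number.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path) {
  fs <- rec@fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  fs <- as.integer(fs)
  nCh <- nrow(rec@signals)
  nSamp <- ncol(rec@signals)
  nRec <- ceiling(nSamp / fs)
  sig <- rec@signals
  if (nRec * fs > nSamp)
    sig <- cbind(sig, matrix(0, nCh, nRec * fs - nSamp))

  physMin <- apply(sig, 1L, min)
  physMax <- apply(sig, 1L, max)
  flat <- physMax - physMin < 1e-9
  physMin[flat] <- physMin[flat] - 1
  physMax[flat] <- physMax[flat] + 1
  digMin <- -32768L; digMax <- 32767L
  dig <- round((sig - physMin) / (physMax - physMin) *
                 (digMax - digMin) + digMin)
  storage.mode(dig) <- "integer"

  # annotation payload per record: a timestamp TAL plus one TAL per event;
  # each TAL is nul-terminated, so the payload is assembled as raw bytes
  tals <- lapply(seq_len(nRec) - 1L, function(r)
    list(sprintf("+%d\x14\x14", r)))
  if (nrow(rec@events)) {
    t <- (rec@events$onset - 1L) / fs
    r <- pmin(floor(t) + 1L, nRec)
    for (i in seq_along(t))
      tals[[r[i]]] <- c(tals[[r[i]]],
        sprintf("+%.4f\x14class %d\x14", t[i], rec@events$label[i]))
  }
  talRaw <- lapply(tals, function(strs)
    unlist(lapply(strs, function(s) c(charToRaw(s), as.raw(0L)))))
  annBytes <- max(vapply(talRaw, length, integer(1)))
  annSamp <- max(16L, as.integer(ceiling(annBytes / 2)))

  ns <- nCh + 1L
  con <- file(path, "wb")
  on.exit(close(con))
  wf <- function(x, width) writeChar(padField(x, width), con, width,
                                     eos = NULL)
  wf("0", 8); wf("X X X X", 80); wf("Startdate X X X X", 80)
  wf("01.01.00", 8); wf("00.00.00", 8)
  wf(256L * (ns + 1L), 8); wf("EDF+C", 44)
  wf(nRec, 8); wf(1, 8); wf(ns, 4)
  for (lab in rec@channelLabels) wf(lab, 16); wf("EDF Annotations", 16)
  for (i in seq_len(ns)) wf("", 80)                       # transducer
  for (i in seq_len(nCh)) wf("uV", 8); wf("", 8)          # dimension
  for (v in physMin) wf(sprintf("%.4f", v), 8); wf(-1, 8)
  for (v in physMax) wf(sprintf("%.4f", v), 8); wf(1, 8)
  for (i in seq_len(ns)) wf(digMin, 8)
  for (i in seq_len(ns)) wf(digMax, 8)
  for (i in seq_len(ns)) wf("", 80)                       # prefiltering
  for (i in seq_len(nCh)) wf(fs, 8); wf(annSamp, 8)
  for (i in seq_len(ns)) wf("", 32)

  for (r in seq_len(nRec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
    raw0 <- talRaw[[r]]
    writeBin(c(raw0, raw(2L * annSamp - length(raw0))), con)
  }
  invisible(path)
}

#' Read an EDF(+) file
#'
#' Reads 16-bit EDF with uniform per-channel sampling rates; `class <k>`
#' annotations in an `EDF Annotations` channel are decoded back into trial
#' events.
#'
#' @param path EDF file path.
#' @return an [EEGRecording-class].
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rf <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rf(8); rf(80); rf(80); rf(8); rf(8)
  rf(8); rf(44)
  nRec <- as.integer(rf(8))
  recDur <- as.numeric(rf(8))
  ns <- as.integer(rf(4))
  labels <- vapply(seq_len(ns), function(i) rf(16), character(1))
  for (i in seq_len(ns)) rf(80)
  for (i in seq_len(ns)) rf(8)
  physMin <- vapply(seq_len(ns), function(i) as.numeric(rf(8)), numeric(1))
  physMax <- vapply(seq_len(ns), function(i) as.numeric(rf(8)), numeric(1))
  digMin <- vapply(seq_len(ns), function(i) as.numeric(rf(8)), numeric(1))
  digMax <- vapply(seq_len(ns), function(i) as.numeric(rf(8)), numeric(1))
  for (i in seq_len(ns)) rf(80)
  sampPerRec <- vapply(seq_len(ns), function(i) as.integer(rf(8)),
                       integer(1))
  for (i in seq_len(ns)) rf(32)

  annIdx <- which(labels == "EDF Annotations")
  sigIdx <- setdiff(seq_len(ns), annIdx)
  fs <- sampPerRec[sigIdx] / recDur
  if (length(unique(fs)) != 1L)
    stop("channels with differing sampling rates are not supported")
  fs <- fs[1L]

  sig <- matrix(0, length(sigIdx), nRec * sampPerRec[sigIdx[1L]])
  annRaw <- raw(0)
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      if (i %in% annIdx) {
        annRaw <- c(annRaw, readBin(con, "raw", 2L * sampPerRec[i]))
      } else {
        v <- readBin(con, "integer", sampPerRec[i], size = 2L,
                     signed = TRUE, endian = "little")
        j <- match(i, sigIdx)
        phys <- (v - digMin[i]) / (digMax[i] - digMin[i]) *
          (physMax[i] - physMin[i]) + physMin[i]
        cols <- ((r - 1L) * sampPerRec[i] + 1L):(r * sampPerRec[i])
        sig[j, cols] <- phys
      }
    }
  }

  events <- data.frame(onset = integer(0), label = integer(0))
  if (length(annRaw)) {
    txt <- rawToChar(annRaw[annRaw != as.raw(0L)], multiple = FALSE)
    hits <- regmatches(txt,
      gregexpr("\\+[0-9.]+\x14class [0-9]+\x14", txt))[[1]]
    if (length(hits)) {
      t <- as.numeric(sub("\\+([0-9.]+)\x14.*", "\\1", hits))
      lab <- as.integer(sub(".*class ([0-9]+)\x14", "\\1", hits))
      events <- data.frame(onset = as.integer(round(t * fs)) + 1L,
                           label = lab)
      events <- events[order(events$onset), , drop = FALSE]
      rownames(events) <- NULL
    }
  }
  new("EEGRecording", signals = sig, fs = fs,
      channelLabels = labels[sigIdx], events = events)
}
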