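#' Short-time Fourier transform power of one signal
#'
#' Hann-windowed magnitude-squared STFT. The signal is reflection-padded by
#' half a window so the frame centers cover the whole epoch; columns whose
#' analysis window crosses the epoch edge are flagged in the `"edge"`
#' attribute of the returned power matrix rather than dropped.
#'
#' @param x numeric vector (one channel of one trial).
#' @param fs sampling rate in Hz.
#' @param windowSec analysis window length in seconds (default 1, giving
#'   1 Hz frequency resolution).
#' @param overlap fractional window overlap in `[0, 1)` (default 0.875).
#' @param t0 time of the first sample in seconds (e.g. -1 for an epoch that
#'   starts 1 s before MI onset).
#' @return a [Spectrogram-class].
#' @export
stftPower <- function(x, fs, windowSec = 1, overlap = 0.875, t0 = 0) {
  win <- round(windowSec * fs)
  if (win < 8L) stop("window must span at least 8 samples")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  n <- length(x)
  if (win > n) stop("window (", win, " samples) longer than signal (", n, ")")
  hop <- max(1L, round(win * (1 - overlap)))
  w <- 0.5 * (1 - cos(2 * pi * seq(0L, win - 1L) / win))
  half <- win %/% 2L
  xp <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  centers <- seq(1L, n, by = hop)
  nf <- win %/% 2L + 1L
  pow <- matrix(0, nf, length(centers))
  for (j in seq_along(centers)) {
    seg <- xp[centers[j] + seq_len(win) - 1L]   # centered on centers[j]
    sp <- stats::fft(w * seg)[seq_len(nf)]
    pow[, j] <- Mod(sp)^2
  }
  freqs <- seq(0L, win %/% 2L) * fs / win
  times <- t0 + (centers - 1L) / fs
  sg <- new("Spectrogram", power = pow, freqs = freqs, times = times)
  attr(sg@power, "edge") <- centers - half < 1L | centers + half > n
  sg
}

#' Event-related spectral perturbation map for one channel
#'
#' Averages magnitude-squared STFT power across trials, then expresses it in
#' dB relative to the frequency-wise mean baseline power over the pre-MI
#' window: `db(f,t) = 10 log10(P(f,t) / B(f))` with `B(f)` the time-mean of
#' the trial-averaged power over the baseline window (divisive baseline).
#' With `baselineMode = "log"` the dB conversion and baseline subtraction
#' are instead done per trial before averaging.
#'
#' @param trials an [EEGTrialSet-class] whose window covers the baseline
#'   (e.g. epoched at (-1, 6) s).
#' @param channel channel label to analyze.
#' @param class optional force class; if given, only trials of that class
#'   are used.
#' @param windowSec,overlap STFT parameters, see [stftPower()].
#' @param baselineWindow baseline window in seconds (default (-1, 0)).
#' @param baselineMode `"divisive"` (default) or `"log"`.
#' @return an [ERSPMap-class].
#' @export
erspMap <- function(trials, channel, class = NULL, windowSec = 1,
                    overlap = 0.875, baselineWindow = c(-1, 0),
                    baselineMode = c("divisive", "log")) {
  baselineMode <- match.arg(baselineMode)
  ci <- match(channel, trials@channelLabels)
  if (is.na(ci)) stop("channel '", channel, "' not in trial set")
  if (trials@window[1] > baselineWindow[1])
    stop("epoch window must include the baseline window (",
         baselineWindow[1], ", ", baselineWindow[2], ") s")
  idx <- seq_len(nTrials(trials))
  if (!is.null(class)) idx <- idx[trials@labels == classIndex(class)]
  if (length(idx) < 1L) stop("no trials to average")

  acc <- NULL
  baseCols <- edge <- NULL
  for (i in idx) {
    sg <- stftPower(trials@data[i, ci, ], trials@fs, windowSec, overlap,
                    t0 = trials@window[1])
    if (is.null(baseCols)) {
      # frames whose window crossed the epoch edge are biased by the
      # reflection padding; they are flagged and kept out of the baseline
      edge <- attr(sg@power, "edge")
      baseCols <- sg@times >= baselineWindow[1] &
        sg@times < baselineWindow[2] & !edge
      if (!any(baseCols))
        stop("no interior STFT columns fall in the baseline window")
    }
    if (baselineMode == "log") {
      bl <- rowMeans(sg@power[, baseCols, drop = FALSE])
      if (any(bl <= 0)) stop("zero baseline power at some frequency")
      p <- 10 * log10(sg@power / bl)
    } else p <- sg@power
    acc <- if (is.null(acc)) p else acc + p
  }
  pbar <- acc / length(idx)
  if (baselineMode == "divisive") {
    bl <- rowMeans(pbar[, baseCols, drop = FALSE])
    if (any(bl <= 0)) stop("zero baseline power at some frequency")
    db <- 10 * log10(pbar / bl)
  } else db <- pbar
  attributes(db) <- attributes(db)["dim"]
  sg1 <- stftPower(trials@data[idx[1L], ci, ], trials@fs, windowSec,
                   overlap, t0 = trials@window[1])
  new("ERSPMap", db = db, freqs = sg1@freqs, times = sg1@times,
      nTrials = length(idx), channel = channel,
      baselineWindow = as.numeric(baselineWindow), edgeCols = edge)
}

#' Band-averaged ERSP curve
#'
#' Mean of the dB rows with `lo <= f <= hi`, per time column: the ERSP
#' curve of a frequency band (e.g. 13-14 Hz alpha or 24-28 Hz beta).
#'
#' @param map an [ERSPMap-class].
#' @param band band edges (lo, hi) in Hz.
#' @return named numeric vector of dB values, names are times in seconds.
#' @export
bandCurve <- function(map, band) {
  rows <- map@freqs >= band[1] & map@freqs <= band[2]
  if (!any(rows)) stop("no map frequencies in band (", band[1], ", ",
                       band[2], ") Hz")
  v <- colMeans(map@db[rows, , drop = FALSE])
  names(v) <- map@times
  v
}

#' Per-channel band power for topographic display
#'
#' Mean ERSP (dB) in one band over one time window for every channel; the
#' values behind a scalp topography of ERD depth.
#'
#' @param trials an [EEGTrialSet-class] epoched to cover the baseline.
#' @param band band edges (lo, hi) in Hz.
#' @param timeWindow averaging window in seconds (default (0, 6), the MI
#'   period).
#' @param class optional force class restriction.
#' @param ... passed to [erspMap()].
#' @return named numeric vector, one dB value per channel.
#' @export
channelBandPower <- function(trials, band, timeWindow = c(0, 6),
                             class = NULL, ...) {
  out <- numeric(length(trials@channelLabels))
  names(out) <- trials@channelLabels
  for (ch in trials@channelLabels) {
    m <- erspMap(trials, ch, class = class, ...)
    cols <- m@times >= timeWindow[1] & m@times <= timeWindow[2] & !m@edgeCols
    rows <- m@freqs >= band[1] & m@freqs <= band[2]
    out[ch] <- mean(m@db[rows, cols])
  }
  out
}

#' Export ERSP maps as a long-format table
#'
#' @param maps a named list of [ERSPMap-class] objects (names used as the
#'   channel/class tag) or a single map.
#' @param file optional CSV path; if given the table is also written there.
#' @return data.frame with columns `tag`, `channel`, `freq`, `time`, `db`.
#' @export
erspTable <- function(maps, file = NULL) {
  if (is(maps, "ERSPMap")) maps <- list(ersp = maps)
  rows <- lapply(names(maps), function(nm) {
    m <- maps[[nm]]
    data.frame(tag = nm, channel = m@channel,
               freq = rep(m@freqs, times = length(m@times)),
               time = rep(m@times, each = length(m@freqs)),
               db = as.vector(m@db))
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
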