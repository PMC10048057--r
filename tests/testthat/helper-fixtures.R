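# Shared fixtures: small montages and cached synthetic data so expensive
# generation happens once per test run.

# Five-channel montage around the C3 focus plus two distant channels;
# enough to exercise focal/neighbour/far behaviour cheaply.
smallMontage <- function() {
  m <- montage1020()
  m[m$label %in% c("C3", "FC3", "CP3", "CZ", "T6", "O2"), , drop = FALSE]
}

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtureEnv[[name]])) .fixtureEnv[[name]] <- build()
  .fixtureEnv[[name]]
}

# A batch of single-channel (C3) trials epoched at (-1, 6) s around MI
# onset, for ERSP tests. Returns an EEGTrialSet.
c3TrialSet <- function(n, erd, fs = 128, seed = 1, label = 0L) {
  set.seed(seed)
  tl <- trialTimeline()
  mont <- smallMontage()
  a <- round((miOnset(tl) - 1) * fs) + 1L
  b <- round((miOnset(tl) + tl@miS) * fs)
  dat <- array(0, c(n, 1L, b - a + 1L))
  for (i in seq_len(n))
    dat[i, 1, ] <- generateTrial(tl, erd, label, mont, noiseSpec(), fs)["C3", a:b]
  new("EEGTrialSet", data = dat, labels = rep(as.integer(label), n),
      fs = fs, window = c(-1, 6), channelLabels = "C3")
}

# Small recording for preprocessing tests: given per-channel generator
# functions of time, build an EEGRecording.
toneRecording <- function(fs, dur, chanFuns, labels = NULL, events = NULL) {
  t <- (seq_len(round(fs * dur)) - 1) / fs
  sig <- do.call(rbind, lapply(chanFuns, function(f) f(t)))
  if (is.null(labels)) labels <- paste0("ch", seq_along(chanFuns))
  if (is.null(events)) events <- data.frame(onset = integer(0),
                                            label = integer(0))
  new("EEGRecording", signals = sig, fs = fs, channelLabels = labels,
      events = events)
}

rms <- function(x) sqrt(mean(x^2))

# Tiny normalized trial set with a strong class-dependent spatial pattern;
# cheap separable data for training sanity checks (not a full EEG
# simulation).
tinySeparableTrials <- function(nPerClass = 8, N = 6, M = 64, seed = 1) {
  set.seed(seed)
  n <- 3 * nPerClass
  dat <- array(stats::rnorm(n * N * M, sd = 1), c(n, N, M))
  labels <- rep(0:2, each = nPerClass)
  t <- seq_len(M)
  for (i in seq_len(n)) {
    ch <- labels[i] + 1L          # class-specific channel carries a rhythm
    dat[i, ch, ] <- dat[i, ch, ] + 3 * sin(2 * pi * 8 * t / M)
  }
  normalizeTrials(new("EEGTrialSet", data = dat,
                      labels = as.integer(labels), fs = 128,
                      window = c(0, M / 128),
                      channelLabels = paste0("ch", seq_len(N))))
}

# Per-channel band-power ratio (MI / baseline) in dB via direct FFT band
# integration; the independent oracle used against the generator.
bandPowerDb <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  10 * log10(sum(sp[f >= lo & f <= hi]))
}

# Settled-window ERD readout: mean band-curve dB over the portion of the MI
# period clear of the onset ramp plus STFT window half-width and of
# edge-flagged frames.
settledDepth <- function(m, band, from = 1, to = 5.5) {
  cv <- bandCurve(m, band)
  t <- as.numeric(names(cv))
  mean(cv[t >= from & t <= to & !m@edgeCols])
}
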