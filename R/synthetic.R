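#' Trial timeline of the force motor-imagery paradigm
#'
#' One trial is preparation, cue, motor imagery (MI), and rest, in that
#' order. The defaults (2, 4, 6, 4 s) give the paradigm's 16-second trial;
#' time zero of all epoch windows is the MI onset (i.e. `prepS + cueS`
#' seconds into the trial).
#'
#' @param prepS,cueS,miS,restS period durations in seconds, all positive.
#' @return a `TrialTimeline` object.
#' @examples
#' tl <- trialTimeline()
#' totalDuration(tl)  # 16
#' @export
trialTimeline <- function(prepS = 2, cueS = 4, miS = 6, restS = 4) {
  new("TrialTimeline", prepS = prepS, cueS = cueS, miS = miS, restS = restS)
}

#' @rdname trialTimeline
#' @export
setClass("TrialTimeline",
  slots = c(prepS = "numeric", cueS = "numeric", miS = "numeric",
            restS = "numeric")
)

setValidity("TrialTimeline", function(object) {
  d <- c(object@prepS, object@cueS, object@miS, object@restS)
  if (length(d) != 4L || any(!is.finite(d)) || any(d <= 0))
    "all period durations must be positive" else TRUE
})

#' @param object a `TrialTimeline`.
#' @return `totalDuration` returns the total trial duration in seconds.
#' @rdname trialTimeline
#' @export
setGeneric("totalDuration", function(object) standardGeneric("totalDuration"))

#' @rdname trialTimeline
#' @export
setMethod("totalDuration", "TrialTimeline", function(object)
  object@prepS + object@cueS + object@miS + object@restS)

#' @rdname trialTimeline
#' @export
setGeneric("miOnset", function(object) standardGeneric("miOnset"))

#' @return `miOnset` returns the MI-period onset in seconds from trial start.
#' @rdname trialTimeline
#' @export
setMethod("miOnset", "TrialTimeline", function(object)
  object@prepS + object@cueS)

#' Event-related desynchronization specification
#'
#' Describes the class-dependent suppression of narrowband oscillatory power
#' during the MI period: which bands are suppressed, how deep the
#' suppression is per force class, where it is focused on the scalp, and how
#' far it spreads. Depth magnitudes and spatial extents must be
#' non-decreasing from small to large force, mirroring the finding that ERD
#' deepens and its activation area widens with imagined force level.
#'
#' @param bands two-column matrix (or length-2 vector) of band edges in Hz;
#'   defaults to the 13-14 Hz alpha and 24-28 Hz beta feature bands. Bands
#'   must lie within 8-30 Hz.
#' @param depthDb per-class suppression depth in dB (small, medium, large),
#'   non-decreasing. Defaults 2, 4, 6 dB.
#' @param focalChannels scalp focus of the suppression; default `"C3"`
#'   (contralateral sensorimotor cortex for right-limb imagery).
#' @param spatialSigma per-class Gaussian spatial falloff scale in montage
#'   head-radius units, non-decreasing. Defaults 0.20, 0.35, 0.50.
#' @param onsetRampS linear ramp duration of the suppression after MI onset
#'   in seconds (default 0.5).
#' @param deepen if `TRUE` (default) the suppression depth additionally
#'   drifts linearly from 0.8x to 1.2x the nominal depth across the MI
#'   period, so band power gradually decreases with time while its MI-mean
#'   stays at the nominal depth.
#' @param depthJitterSd per-trial lognormal jitter (SD on the log scale) of
#'   the realized depth; default 0.1.
#' @return an `ERDSpec` object.
#' @export
erdSpec <- function(bands = rbind(c(13, 14), c(24, 28)),
                    depthDb = c(2, 4, 6),
                    focalChannels = "C3",
                    spatialSigma = c(0.20, 0.35, 0.50),
                    onsetRampS = 0.5,
                    deepen = TRUE,
                    depthJitterSd = 0.1) {
  if (is.null(dim(bands))) bands <- matrix(bands, nrow = 1L)
  new("ERDSpec", bands = bands, depthDb = depthDb,
      focalChannels = focalChannels, spatialSigma = spatialSigma,
      onsetRampS = onsetRampS, deepen = deepen,
      depthJitterSd = depthJitterSd)
}

#' @rdname erdSpec
#' @export
setClass("ERDSpec",
  slots = c(bands = "matrix", depthDb = "numeric", spatialSigma = "numeric",
            focalChannels = "character", onsetRampS = "numeric",
            deepen = "logical", depthJitterSd = "numeric")
)

setValidity("ERDSpec", function(object) {
  msg <- character()
  if (ncol(object@bands) != 2L || any(object@bands[, 1] >= object@bands[, 2]))
    msg <- c(msg, "bands must be (low, high) pairs with low < high")
  if (any(object@bands < 8) || any(object@bands > 30))
    msg <- c(msg, "bands must lie within 8-30 Hz")
  if (length(object@depthDb) != 3L || any(object@depthDb < 0) ||
      is.unsorted(abs(object@depthDb)))
    msg <- c(msg, paste0("depthDb must give non-decreasing suppression ",
                         "magnitudes for classes small, medium, large"))
  if (length(object@spatialSigma) != 3L || any(object@spatialSigma <= 0) ||
      is.unsorted(object@spatialSigma))
    msg <- c(msg, "spatialSigma must be positive and non-decreasing")
  if (object@onsetRampS < 0)
    msg <- c(msg, "onsetRampS must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Null (class-indistinguishable) ERD specification
#'
#' All classes share the same depth and spatial extent, so class labels carry
#' no information; used for chance-level controls.
#'
#' @param depthDb common suppression depth in dB (default 4).
#' @param spatialSigma common spatial falloff scale (default 0.35).
#' @param ... passed to [erdSpec()].
#' @export
nullErdSpec <- function(depthDb = 4, spatialSigma = 0.35, ...) {
  erdSpec(depthDb = rep(depthDb, 3), spatialSigma = rep(spatialSigma, 3), ...)
}

#' Background noise specification for the synthetic generator
#'
#' @param pinkAmp standard deviation (microvolts) of the 1/f background.
#' @param pinkExponent spectral exponent of the 1/f background.
#' @param whiteAmp white-noise floor SD (microvolts).
#' @param lineAmp 50 Hz line-noise amplitude (microvolts).
#' @param lineHz line frequency (Hz).
#' @param oscAmp ongoing narrowband oscillation SD (microvolts), recycled
#'   over the ERD bands. Defaults make the oscillation dominate the in-band
#'   background by two orders of magnitude (a prominent idling rhythm), so a
#'   configured suppression depth is recovered by spectral analysis with
#'   little background dilution.
#' @param amDepth depth (log scale) of the slow lognormal amplitude
#'   modulation of the oscillations.
#' @param eogAmp SD of the low-frequency ocular activity on HEOG/VEOG.
#' @return a plain list.
#' @export
noiseSpec <- function(pinkAmp = 10, pinkExponent = 1, whiteAmp = 2,
                      lineAmp = 5, lineHz = 50, oscAmp = c(15, 20),
                      amDepth = 0.2, eogAmp = 40) {
  list(pinkAmp = pinkAmp, pinkExponent = pinkExponent, whiteAmp = whiteAmp,
       lineAmp = lineAmp, lineHz = lineHz, oscAmp = oscAmp,
       amDepth = amDepth, eogAmp = eogAmp)
}

#' Session configuration for the synthetic generator
#'
#' Defaults follow the paradigm: nine rounds of 24 trials, the force level
#' fixed within a round, every three consecutive rounds in ascending force
#' order, sampled at 1000 Hz.
#'
#' @param fs sampling rate in Hz (default 1000).
#' @param nRounds number of rounds (default 9).
#' @param trialsPerRound trials per round (default 24).
#' @param roundClassOrder force class (0, 1, 2) per round; default
#'   `rep(c(0, 1, 2), length.out = nRounds)`.
#' @param noise background noise specification, see [noiseSpec()].
#' @param seed integer RNG seed.
#' @return a `SessionConfig` object.
#' @export
sessionConfig <- function(fs = 1000, nRounds = 9L, trialsPerRound = 24L,
                          roundClassOrder = NULL, noise = noiseSpec(),
                          seed = 1L) {
  if (is.null(roundClassOrder))
    roundClassOrder <- rep(c(0L, 1L, 2L), length.out = nRounds)
  new("SessionConfig", fs = fs, nRounds = as.integer(nRounds),
      trialsPerRound = as.integer(trialsPerRound),
      roundClassOrder = as.integer(roundClassOrder), noise = noise,
      seed = as.integer(seed))
}

#' @rdname sessionConfig
#' @export
setClass("SessionConfig",
  slots = c(fs = "numeric", nRounds = "integer", trialsPerRound = "integer",
            roundClassOrder = "integer", noise = "list", seed = "integer")
)

setValidity("SessionConfig", function(object) {
  msg <- character()
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (object@nRounds < 1L || object@trialsPerRound < 1L)
    msg <- c(msg, "nRounds and trialsPerRound must be >= 1")
  if (length(object@roundClassOrder) != object@nRounds)
    msg <- c(msg, "roundClassOrder must give one class per round")
  if (length(object@roundClassOrder) &&
      !all(object@roundClassOrder %in% 0:2))
    msg <- c(msg, "round classes must be in {0, 1, 2}")
  if (length(msg)) msg else TRUE
})

# Map "small"/"medium"/"large" (or 0:2) to the integer class code.
classIndex <- function(class) {
  if (is.character(class)) {
    i <- match(class, c("small", "medium", "large"))
    if (is.na(i)) stop("unknown class label '", class,
                       "'; use small/medium/large or 0/1/2")
    return(i - 1L)
  }
  class <- as.integer(class)
  if (!class %in% 0:2) stop("unknown class label '", class, "'")
  class
}

# Per-channel ERD depth (dB) for one class: nominal depth scaled by a
# Gaussian falloff in montage distance from the nearest focal channel.
erdChannelDepth <- function(erd, class, montage) {
  k <- classIndex(class) + 1L
  fall <- rep(0, nrow(montage))
  for (fc in erd@focalChannels) {
    d <- montageDistance(montage, fc)
    fall <- pmax(fall, exp(-d^2 / (2 * erd@spatialSigma[k]^2)))
  }
  fall[montage$type != "eeg"] <- 0
  erd@depthDb[k] * fall
}

#' Generate one synthetic force-MI trial
#'
#' Produces a (channel x time) matrix for a single trial. Background
#' activity on every scalp channel is 1/f-colored noise plus a white floor,
#' a 50 Hz line component, and ongoing narrowband oscillations
#' (amplitude-modulated band-limited Gaussian noise) in the ERD bands.
#' During the MI period the oscillation amplitude on the focal channel and
#' its neighbours is attenuated by `10^(-depth/20)`, with a Gaussian spatial
#' falloff whose scale grows with force class, a linear onset ramp, and
#' (optionally) a slow within-trial deepening. The ramp-and-drift profile is
#' normalized to unit mean over the MI period, so the configured depth is
#' the mean suppression in dB actually injected. Ocular channels carry
#' low-frequency drift instead.
#'
#' Randomness comes from the current R RNG; call `set.seed()` first for
#' reproducible trials.
#'
#' @param timeline a [trialTimeline()].
#' @param erd an [erdSpec()].
#' @param class force class: 0/1/2 or "small"/"medium"/"large".
#' @param montage electrode layout, see [montage1020()]; must contain all
#'   focal channels.
#' @param noise background specification, see [noiseSpec()].
#' @param fs sampling rate in Hz.
#' @return numeric matrix (channels x samples) with channel labels as row
#'   names, in microvolts.
#' @export
generateTrial <- function(timeline = trialTimeline(), erd = erdSpec(),
                          class = 0L, montage = montage1020(),
                          noise = noiseSpec(), fs = 1000) {
  validObject(timeline); validObject(erd)
  for (fc in erd@focalChannels)
    if (!fc %in% montage$label)
      stop("focal channel '", fc, "' absent from montage")
  n <- round(totalDuration(timeline) * fs)
  tt <- (seq_len(n) - 1) / fs
  miStart <- miOnset(timeline)
  miEnd <- miStart + timeline@miS

  # suppression time profile in [0, 1] x deepening factor
  inMI <- tt >= miStart & tt < miEnd
  prof <- numeric(n)
  if (any(inMI)) {
    rel <- tt[inMI] - miStart
    ramp <- if (erd@onsetRampS > 0) pmin(rel / erd@onsetRampS, 1) else 1
    deepenF <- if (erd@deepen) 0.8 + 0.4 * rel / timeline@miS else 1
    shape <- ramp * deepenF
    # calibration: the profile is normalized to unit MI-mean, so the
    # configured depth equals the mean suppression (in dB) over the MI
    # period regardless of ramp or drift shape
    prof[inMI] <- shape / mean(shape)
  }

  depth <- erdChannelDepth(erd, class, montage)
  jitter <- exp(stats::rnorm(1L, 0, erd@depthJitterSd))
  oscAmp <- rep_len(noise$oscAmp, nrow(erd@bands))

  sig <- matrix(0, nrow(montage), n, dimnames = list(montage$label, NULL))
  for (ch in seq_len(nrow(montage))) {
    if (montage$type[ch] == "eog") {
      x <- noise$eogAmp * coloredNoise(n, 2.5) +
        noise$whiteAmp * stats::rnorm(n) +
        noise$lineAmp * sin(2 * pi * noise$lineHz * tt +
                              stats::runif(1L, 0, 2 * pi))
      sig[ch, ] <- x
      next
    }
    x <- noise$pinkAmp * coloredNoise(n, noise$pinkExponent) +
      noise$whiteAmp * stats::rnorm(n) +
      noise$lineAmp * sin(2 * pi * noise$lineHz * tt +
                            stats::runif(1L, 0, 2 * pi))
    for (j in seq_len(nrow(erd@bands))) {
      osc <- bandNoise(n, fs, erd@bands[j, 1], erd@bands[j, 2])
      am <- exp(noise$amDepth * bandNoise(n, fs, 0.06, 0.4, taperHz = 0.05))
      gain <- 10^(-(depth[ch] * jitter * prof) / 20)
      x <- x + oscAmp[j] * osc * am * gain
    }
    sig[ch, ] <- x
  }
  sig
}

#' Generate a full synthetic session
#'
#' Concatenates `nRounds x trialsPerRound` trials into one continuous
#' recording with an event marker at each MI-period onset carrying the
#' round's force class. Ocular (HEOG/VEOG) channels are included so the
#' preprocessing channel-drop step is exercised.
#'
#' @param cfg a [sessionConfig()].
#' @param timeline a [trialTimeline()].
#' @param erd an [erdSpec()].
#' @param montage electrode layout, see [montage1020()].
#' @return an [EEGRecording-class] seeded from `cfg@seed` (two sessions with
#'   the same configuration are identical).
#' @examples
#' cfg <- sessionConfig(fs = 128, nRounds = 3, trialsPerRound = 1, seed = 7)
#' rec <- generateSession(cfg)
#' eventTable(rec)
#' @export
generateSession <- function(cfg = sessionConfig(),
                            timeline = trialTimeline(),
                            erd = erdSpec(),
                            montage = montage1020()) {
  validObject(cfg)
  set.seed(cfg@seed)
  nPer <- round(totalDuration(timeline) * cfg@fs)
  nTr <- cfg@nRounds * cfg@trialsPerRound
  sig <- matrix(0, nrow(montage), nPer * nTr,
                dimnames = list(montage$label, NULL))
  onset <- integer(nTr)
  label <- integer(nTr)
  miOff <- round(miOnset(timeline) * cfg@fs)
  k <- 0L
  for (r in seq_len(cfg@nRounds)) {
    cls <- cfg@roundClassOrder[r]
    for (i in seq_len(cfg@trialsPerRound)) {
      k <- k + 1L
      off <- (k - 1L) * nPer
      sig[, off + seq_len(nPer)] <- generateTrial(timeline, erd, cls,
                                                  montage, cfg@noise, cfg@fs)
      onset[k] <- off + miOff + 1L
      label[k] <- cls
    }
  }
  new("EEGRecording", signals = sig, fs = cfg@fs,
      channelLabels = montage$label,
      events = data.frame(onset = onset, label = label))
}
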