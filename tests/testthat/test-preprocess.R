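test_that("mastoid re-referencing matches the direct formula", {
  set.seed(1)
  sig <- matrix(rnorm(4 * 100), 4, 100)
  rec <- new("EEGRecording", signals = sig, fs = 100,
             channelLabels = c("C3", "C4", "M1", "M2"),
             events = data.frame(onset = integer(0), label = integer(0)))
  out <- rereferenceMastoid(rec)
  ref <- (sig[3, ] + sig[4, ]) / 2
  expect_equal(signalMatrix(out)[1, ], sig[1, ] - ref)
  expect_equal(signalMatrix(out)[2, ], sig[2, ] - ref)
  # identical signal on all channels -> all zero
  same <- rec; same@signals <- matrix(rep(sig[1, ], 4), 4, byrow = TRUE)
  expect_equal(max(abs(signalMatrix(rereferenceMastoid(same)))), 0)
  # zero mastoids -> identity
  zm <- rec; zm@signals[3:4, ] <- 0
  expect_equal(signalMatrix(rereferenceMastoid(zm)), zm@signals)
  # absent mastoids -> warning, unchanged; one missing -> error
  noM <- new("EEGRecording", signals = sig[1:2, ], fs = 100,
             channelLabels = c("C3", "C4"),
             events = data.frame(onset = integer(0), label = integer(0)))
  expect_warning(out2 <- rereferenceMastoid(noM), "skipping")
  expect_identical(signalMatrix(out2), signalMatrix(noM))
  oneM <- new("EEGRecording", signals = sig[1:3, ], fs = 100,
              channelLabels = c("C3", "C4", "M1"),
              events = data.frame(onset = integer(0), label = integer(0)))
  expect_error(rereferenceMastoid(oneM), "absent")
})

test_that("broadband chain notches 50 Hz, keeps 10 Hz, rejects DC", {
  fs <- 1000
  rec <- toneRecording(fs, 10, list(
    function(t) sin(2 * pi * 50 * t),
    function(t) sin(2 * pi * 10 * t),
    function(t) rep(1, length(t))))
  out <- signalMatrix(filterChain(rec))
  mid <- 2001:8000   # avoid edge transients
  expect_lt(rms(out[1, mid]) / rms(sin(2 * pi * 50 * (mid / fs))), 0.1)
  expect_lt(abs(rms(out[2, mid]) / rms(sin(2 * pi * 10 * (mid / fs))) - 1), 0.1)
  expect_lt(mean(abs(out[3, mid])), 0.01)
  expect_error(filterChain(toneRecording(150, 2, list(function(t) t))),
               "exceed")
})

test_that("CAR conserves a zero mean and scales a lone source by (k-1)/k", {
  set.seed(2)
  sig <- matrix(rnorm(5 * 200), 5, 200)
  rec <- new("EEGRecording", signals = sig, fs = 100,
             channelLabels = paste0("E", 1:5),
             events = data.frame(onset = integer(0), label = integer(0)))
  out <- signalMatrix(carReference(rec, exclude = character(0)))
  expect_lt(max(abs(colMeans(out))), 1e-12)
  # one nonzero channel among k
  solo <- rec; solo@signals[] <- 0; solo@signals[2, ] <- sig[2, ]
  out2 <- signalMatrix(carReference(solo, exclude = character(0)))
  expect_equal(out2[2, ], sig[2, ] * 4 / 5)
  # identical channels cancel
  same <- rec; same@signals <- matrix(rep(sig[1, ], 5), 5, byrow = TRUE)
  expect_equal(max(abs(signalMatrix(carReference(same, exclude = character(0))))), 0)
  # excluded channels untouched, excluded from the average
  outE <- carReference(rec, exclude = "E5")
  expect_identical(signalMatrix(outE)[5, ], sig[5, ])
  expect_lt(max(abs(colMeans(signalMatrix(outE)[1:4, ]))), 1e-12)
  expect_error(carReference(rec, exclude = paste0("E", 1:4)), "at least 2")
})

test_that("8-30 Hz FIR keeps the mu band and rejects drift and high beta", {
  fs <- 250
  rec <- toneRecording(fs, 10, list(
    function(t) sin(2 * pi * 4 * t),
    function(t) sin(2 * pi * 15 * t),
    function(t) sin(2 * pi * 45 * t)))
  out <- signalMatrix(miBandpass(rec))
  mid <- 501:2000
  ref <- rms(sin(2 * pi * 15 * (1:1500) / fs))
  expect_lt(rms(out[1, mid]) / ref, 0.1)
  expect_lt(abs(rms(out[2, mid]) / ref - 1), 0.1)
  expect_lt(rms(out[3, mid]) / ref, 0.1)
})

test_that("resampling to 128 Hz preserves length, tones and markers", {
  fs <- 1000
  rec <- toneRecording(fs, 10, list(function(t) sin(2 * pi * 15 * t)),
                       events = data.frame(onset = 6001L, label = 1L))
  out <- downsampleRecording(rec)
  expect_equal(samplingRate(out), 128)
  expect_equal(ncol(signalMatrix(out)), 1280L)
  # event at t = 6 s lands 768 samples (0-based) into the new rate
  expect_equal(eventTable(out)$onset - 1L, 768L)
  sp <- Mod(stats::fft(signalMatrix(out)[1, ]))
  f <- (seq_along(sp) - 1) * 128 / length(sp)
  expect_equal(f[which.max(sp[f <= 64])], 15, tolerance = 0.11)
  expect_error(downsampleRecording(rec, targetFs = 1000), "below fs")
})

test_that("ocular channels drop cleanly and order is preserved", {
  sig <- matrix(rnorm(5 * 50), 5, 50)
  rec <- new("EEGRecording", signals = sig, fs = 100,
             channelLabels = c("C3", "HEOG", "CZ", "VEOG", "C4"),
             events = data.frame(onset = integer(0), label = integer(0)))
  out <- dropEOG(rec)
  expect_identical(channelLabels(out), c("C3", "CZ", "C4"))
  expect_identical(signalMatrix(out), sig[c(1, 3, 5), ])
  expect_warning(dropEOG(out), "nothing to drop")
})

test_that("epoching cuts the right windows and flags out-of-bounds trials", {
  fs <- 128
  rec <- toneRecording(fs, 40, list(function(t) t, function(t) 2 * t),
                       labels = c("a", "b"),
                       events = data.frame(onset = c(10 * fs + 1L, 30 * fs + 1L),
                                           label = c(0L, 2L)))
  ts1 <- epochTrials(rec, c(0, 6))
  expect_equal(dim(trialData(ts1)), c(2L, 2L, 768L))
  expect_equal(trialLabels(ts1), c(0L, 2L))
  ts2 <- epochTrials(rec, c(-1, 6))
  expect_equal(dim(trialData(ts2))[3], 896L)
  # first sample of the (0, .) window is the marker sample itself
  expect_equal(trialData(ts1)[1, 1, 1], 10)
  expect_error(epochTrials(rec, c(-1, 11)), "trial 2")
})

test_that("per-trial z-normalization matches the hand-worked example", {
  dat <- array(0, c(1, 2, 2))
  dat[1, , ] <- rbind(c(1, 3), c(2, 4))   # trial [[1,2],[3,4]] row-major
  ts1 <- new("EEGTrialSet", data = dat, labels = 0L, fs = 10,
             window = c(0, 0.2), channelLabels = c("a", "b"))
  out <- trialData(normalizeTrials(ts1))[1, , ]
  mu <- 2.5; sdv <- sqrt(1.25)
  expect_equal(out, (rbind(c(1, 3), c(2, 4)) - mu) / sdv, tolerance = 1e-12)
  expect_equal(as.vector(round(sort(as.vector(out)), 3)),
               c(-1.342, -0.447, 0.447, 1.342))
  # mean 0, population SD 1
  set.seed(3)
  dat2 <- array(rnorm(3 * 4 * 50, 5, 2), c(3, 4, 50))
  ts2 <- new("EEGTrialSet", data = dat2, labels = c(0L, 1L, 2L), fs = 10,
             window = c(0, 5), channelLabels = paste0("e", 1:4))
  nrm <- normalizeTrials(ts2)
  for (i in 1:3) {
    x <- trialData(nrm)[i, , ]
    expect_lt(abs(mean(x)), 1e-6)
    expect_lt(abs(sqrt(mean((x - mean(x))^2)) - 1), 1e-6)
  }
  # affine invariance
  aff <- ts2; aff@data <- 3 * ts2@data + 7
  expect_equal(trialData(normalizeTrials(aff)), trialData(nrm))
  # zero-variance trial errors
  flat <- ts2; flat@data[2, , ] <- 1
  expect_error(normalizeTrials(flat), "zero-variance trial 2")
})

test_that("epoch and normalize commute with trial permutation", {
  fs <- 128
  set.seed(4)
  rec <- toneRecording(fs, 40, list(function(t) rnorm(length(t)),
                                    function(t) rnorm(length(t))),
                       labels = c("a", "b"),
                       events = data.frame(onset = c(5L, 10L, 20L) * fs + 1L,
                                           label = c(0L, 1L, 2L)))
  ts1 <- normalizeTrials(epochTrials(rec, c(0, 2)))
  perm <- c(3L, 1L, 2L)
  rec2 <- rec
  rec2@events <- rec@events[perm, ]
  rec2@events <- rec2@events[order(rec2@events$onset), ]  # stays sorted
  # permuting trials after epoching equals epoching in any order
  ts2 <- forceMI:::subsetTrials(ts1, perm)
  expect_equal(trialData(ts2)[2, , ], trialData(ts1)[1, , ])
  expect_equal(trialLabels(ts2), trialLabels(ts1)[perm])
})

test_that("the full chain yields finite mu/beta-dominant trials", {
  rec <- fixture("session6", function()
    generateSession(sessionConfig(fs = 250, nRounds = 3, trialsPerRound = 2,
                                  seed = 17)))
  trials <- fixture("trials6", function() preprocessChain(rec, window = c(0, 3)))
  expect_equal(dim(trialData(trials)), c(6L, 30L, 384L))
  expect_true(all(is.finite(trialData(trials))))
  expect_false(any(c("HEOG", "VEOG") %in% channelLabels(trials)))
  # in-band (8-30 Hz) power dominates
  x <- trialData(trials)[1, , ]
  sp <- Mod(t(apply(x, 1, stats::fft)))^2
  f <- (seq_len(ncol(x)) - 1) * samplingRate(trials) / ncol(x)
  inb <- (f >= 8 & f <= 30) | (f >= 128 - 30 & f <= 128 - 8)
  expect_gt(sum(sp[, inb]) / sum(sp), 0.9)
})
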