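test_that("wavelet filter is linear, length-preserving and band-selective", {
  expect_equal(dwtSubbandFilter(numeric(256)), numeric(256))
  fs <- 256
  t <- (0:(8 * fs - 1)) / fs
  pass <- dwtSubbandFilter(sin(2 * pi * 10 * t))    # 10 Hz: inside 4-32 Hz
  stopband <- dwtSubbandFilter(sin(2 * pi * 1 * t)) # 1 Hz: below the band
  expect_length(pass, length(t))
  rms <- function(x) sqrt(mean(x^2))
  ratioPass <- rms(pass) / rms(sin(2 * pi * 10 * t))
  ratioStop <- rms(stopband) / rms(sin(2 * pi * 1 * t))
  expect_gt(ratioPass / ratioStop, 10)
})

test_that("keeping every band reconstructs the input", {
  set.seed(8)
  x <- rnorm(1000)
  y <- dwtSubbandFilter(x, keep = c(paste0("d", 1:5), "a5"))
  expect_lt(max(abs(y - x)) / max(abs(x)), 1e-8)
  expect_error(dwtSubbandFilter(rnorm(16), levels = 5), "too short")
  expect_error(dwtSubbandFilter(rnorm(256), keep = "d9"), "unknown band")
})

test_that("segment windows tile the recording and label by any overlap", {
  set.seed(10)
  rec <- EEGRecording(matrix(rnorm(2 * 2560), 2), fs = 256,
                      annotations = data.frame(onset_s = 3.9, offset_s = 4.1))
  segs <- labelSegments(rec, T = 1024L, step = 1024L)
  expect_equal(nSegments(segs), 2L)          # floor(2560 / 1024)
  expect_equal(segLabels(segs), c(1L, 1L))   # 0.2 s event straddles both
  # step = T partitions the usable signal
  expect_equal(sum(rep(4, nSegments(segs))), floor(2560 / 1024) * 4)
  # random annotations against a brute-force oracle
  for (rep in 1:5) {
    ann <- randomIntervals(5, tMax = 9, maxLen = 2)
    ann <- seizureIntervals(ann$onset_s, pmin(ann$offset_s, 10))
    rec2 <- EEGRecording(matrix(rnorm(2560), 1), fs = 256, annotations = ann)
    s <- labelSegments(rec2, T = 256L, step = 128L)
    st <- segStarts(s)
    expect_equal(segLabels(s),
                 as.integer(bruteOverlap(annotations(rec2), st, st + 1)))
  }
})

test_that("ictal oversampling uses step floor(T/n_over) and enumerates windows", {
  expect_equal(1024L %/% 5L, 204L)
  # a 2048-sample ictal stream with T=1024, step 204 gives 6 windows
  expect_length(seq(1L, 2048L - 1024L + 1L, by = 204L), 6L)

  fs <- 256
  ev <- data.frame(onset_s = c(100, 300), duration_s = 4, type = "spike_wave",
                   gain = 4)
  cfg <- synthConfig(durationS = 3000, nChannels = 2, seed = 31, events = ev,
                     rhythms = data.frame(freq_hz = numeric(0),
                                          amplitude = numeric(0)))
  rec <- generateRecording(cfg)
  parts <- buildTrainingSet(rec, splitPlan(1:2, nOver = 5L,
                                           calibrationDurationS = 300))
  # ictal stream = 2 events x 4 s = 2048 samples -> 6 overlapped windows
  expect_equal(parts$info$delta, 204L)
  expect_equal(parts$info$ictalSegments, 6L)
  expect_true(all(segLabels(parts$train)[1:6] == 1L))
})

test_that("training material is disjoint from test events and calibration", {
  ev <- data.frame(onset_s = c(60, 120, 500, 900), duration_s = 10,
                   type = "spike_wave", gain = 4)
  cfg <- synthConfig(durationS = 1800, nChannels = 2, seed = 17, events = ev)
  rec <- generateRecording(cfg)
  plan <- splitPlan(1:2, nOver = 5L, calibrationDurationS = 300)
  parts <- buildTrainingSet(rec, plan)
  fs <- sampleRate(rec)
  testEvIdx <- unlist(lapply(3:4, function(i)
    (floor(ev$onset_s[i] * fs) + 1L):floor((ev$onset_s[i] + 10) * fs)))
  # no test-event leakage into ictal training or calibration or chunks
  expect_length(intersect(parts$info$trainSampleIdx, testEvIdx), 0L)
  expect_length(intersect(parts$info$calSampleIdx, testEvIdx), 0L)
  expect_length(intersect(parts$info$chunkSampleIdx, testEvIdx), 0L)
  expect_length(intersect(parts$info$calSampleIdx,
                          parts$info$chunkSampleIdx), 0L)
  # interictal duration before segmentation ~= n_over * L_sz
  expect_equal(length(parts$info$chunkSampleIdx),
               plan$nOver * parts$info$LszSamples,
               tolerance = 1e-3)
  # both test events survive with re-referenced annotations
  expect_equal(nrow(annotations(parts$test)), 2L)
  # calibration stream is seizure-free by construction
  expect_equal(nrow(annotations(parts$calibration)), 0L)
  # labels inside the test stream still match its annotations
  segs <- labelSegments(parts$test, 1024L, 1024L)
  st <- segStarts(segs)
  expect_equal(segLabels(segs),
               as.integer(bruteOverlap(annotations(parts$test), st, st + 4)))
})

test_that("split construction fails cleanly without enough seizure-free data", {
  ev <- data.frame(onset_s = 10, duration_s = 30, type = "spike_wave", gain = 4)
  cfg <- synthConfig(durationS = 120, nChannels = 1, seed = 2, events = ev)
  rec <- generateRecording(cfg)
  expect_error(buildTrainingSet(rec, splitPlan(1L, calibrationDurationS = 200)),
               "calibration")
  expect_error(buildTrainingSet(rec, splitPlan(1L, calibrationDurationS = 60)),
               "interictal")
})
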