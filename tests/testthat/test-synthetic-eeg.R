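test_that("templates are zero-mean, unit-max, of the requested length", {
  for (type in c("spike_wave", "rhythmic_burst", "sharp_wave")) {
    w <- makeTemplate(type, 2, 256)
    expect_length(w, 512)
    expect_equal(max(abs(w)), 1)
    expect_equal(mean(w), 0, tolerance = 1e-12)
  }
  expect_error(makeTemplate("wiggle", 1, 256), "unknown template type")
})

test_that("spike-wave template has its dominant spectral peak in 2-4 Hz", {
  fs <- 256
  w <- makeTemplate("spike_wave", 8, fs)
  spec <- Mod(fft(w))^2
  freq <- (seq_along(w) - 1) * fs / length(w)
  half <- freq > 0 & freq <= fs / 2
  peak <- freq[half][which.max(spec[half])]
  expect_gte(peak, 2)
  expect_lte(peak, 4)
})

test_that("generation is deterministic and annotations match the config", {
  ev <- data.frame(onset_s = c(5, 20, 40), duration_s = c(5, 8, 3),
                   type = "spike_wave", gain = 5)
  cfg <- synthConfig(durationS = 60, nChannels = 3, events = ev, seed = 9)
  r1 <- generateRecording(cfg)
  r2 <- generateRecording(cfg)
  expect_identical(recData(r1), recData(r2))
  expect_equal(annotations(r1),
               data.frame(onset_s = ev$onset_s,
                          offset_s = ev$onset_s + ev$duration_s))
  # different seed changes the data
  r3 <- generateRecording(synthConfig(durationS = 60, nChannels = 3,
                                      events = ev, seed = 10))
  expect_false(identical(recData(r1), recData(r3)))
  expect_error(
    synthConfig(durationS = 60, events = data.frame(
      onset_s = c(1, 3), duration_s = c(5, 5), type = "spike_wave", gain = 1)),
    "overlapping")
})

test_that("channel substreams are stable under channel-count changes", {
  ev <- data.frame(onset_s = 2, duration_s = 3, type = "spike_wave", gain = 4)
  r2 <- generateRecording(synthConfig(durationS = 10, nChannels = 2,
                                      events = ev, seed = 5))
  r5 <- generateRecording(synthConfig(durationS = 10, nChannels = 5,
                                      events = ev, seed = 5))
  expect_identical(recData(r2), recData(r5)[1:2, ])
})

test_that("injected spike-wave events raise 2-12 Hz band power in-span", {
  cfg <- synthConfig(durationS = 120, nChannels = 4, seed = 21,
                     events = data.frame(onset_s = c(20, 70),
                                         duration_s = 10,
                                         type = "spike_wave", gain = 5))
  rec <- generateRecording(cfg)
  fs <- sampleRate(rec)
  bandPower <- function(x) {
    sp <- stats::spec.pgram(x, spans = 5, taper = 0, plot = FALSE)
    f <- sp$freq * fs
    mean(sp$spec[f >= 2 & f <= 12])
  }
  inIdx <- c(20 * fs + 1:(10 * fs), 70 * fs + 1:(10 * fs))
  outIdx <- c(40 * fs + 1:(10 * fs), 95 * fs + 1:(10 * fs))
  pin <- mean(apply(recData(rec)[, inIdx], 1, bandPower))
  pout <- mean(apply(recData(rec)[, outIdx], 1, bandPower))
  expect_gt(pin, pout)
})

test_that("gain-0 events leave the background untouched but annotated", {
  ev <- data.frame(onset_s = 5, duration_s = 5, type = "spike_wave", gain = 0)
  base <- synthConfig(durationS = 20, nChannels = 2, seed = 3)
  null <- synthConfig(durationS = 20, nChannels = 2, seed = 3, events = ev)
  expect_identical(recData(generateRecording(base)),
                   recData(generateRecording(null)))
  expect_equal(nrow(annotations(generateRecording(null))), 1L)
})

test_that("generator configs round-trip through JSON and YAML files", {
  cfg <- synthConfig(durationS = 30, nChannels = 2, seed = 4,
                     events = data.frame(onset_s = 5, duration_s = 5,
                                         type = "spike_wave", gain = 3))
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), js, auto_unbox = TRUE, digits = NA)
  expect_identical(recData(generateRecording(synthConfigFromFile(js))),
                   recData(generateRecording(cfg)))
  skip_if_not_installed("yaml")
  yl <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), yl)
  cfg2 <- synthConfigFromFile(yl)
  expect_equal(cfg2$events, cfg$events)
  expect_identical(recData(generateRecording(cfg2)),
                   recData(generateRecording(cfg)))
})

test_that("segment labelling recovers exactly the configured event overlaps", {
  cfg <- synthConfig(durationS = 100, nChannels = 2, seed = 13,
                     events = data.frame(onset_s = c(10.5, 50),
                                         duration_s = c(7, 3),
                                         type = "rhythmic_burst", gain = 3))
  rec <- generateRecording(cfg)
  segs <- labelSegments(rec, T = 1024L, step = 1024L)
  starts <- segStarts(segs)
  expect_equal(segLabels(segs),
               as.integer(bruteOverlap(annotations(rec), starts, starts + 4)))
})
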