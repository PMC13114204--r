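test_that("EDF write/read round-trips labels, rate, length and samples", {
  set.seed(1)
  rec <- EEGRecording(matrix(rnorm(2 * 2560, sd = 40), 2), fs = 256,
                      channelLabels = c("FP1", "F7"))
  path <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, path)
  back <- readEDF(path)
  expect_identical(channelLabels(back), c("FP1", "F7"))
  expect_equal(sampleRate(back), 256)
  expect_equal(nSamples(back), 2560)
  # exact up to 16-bit quantization of the per-channel physical range
  qstep <- 2 * max(abs(recData(rec))) / 65535
  expect_lt(max(abs(recData(back) - recData(rec))), 2 * qstep)
})

test_that("EDF channel selection and error paths behave", {
  set.seed(2)
  rec <- EEGRecording(matrix(rnorm(18 * 512), 18), fs = 256,
                      channelLabels = paste0("E", 1:18))
  path <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, path)
  expect_equal(nChannels(readEDF(path)), 18)
  expect_equal(channelLabels(readEDF(path, channels = c("e3", " E5 "))),
               c("E3", "E5"))   # case/whitespace-insensitive matching
  expect_error(readEDF(path, channels = "CZ"), "not present")
  expect_error(readEDF(tempfile()), "not found")
})

test_that("annotation reading validates, sorts and merges", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("onset_s,offset_s\n10,20\n15,25", path)
  expect_equal(readAnnotations(path),
               data.frame(onset_s = 10, offset_s = 25))
  writeLines("onset_s,offset_s", path)
  expect_equal(nrow(readAnnotations(path)), 0L)
  writeLines("onset_s,offset_s\n20,10", path)
  expect_error(readAnnotations(path), "offset")
  writeLines("onset_s,offset_s\n-5,10", path)
  expect_error(readAnnotations(path), "negative")
})

test_that("annotation merge equals a brute-force sweep and round-trips", {
  set.seed(7)
  for (rep in 1:5) {
    iv <- randomIntervals(50)
    merged <- seizureIntervals(iv$onset_s, iv$offset_s)
    # brute force: mark covered time on a fine grid of endpoints
    pts <- sort(unique(c(iv$onset_s, iv$offset_s)))
    mids <- (pts[-1] + pts[-length(pts)]) / 2
    covered <- bruteOverlap(iv, mids, mids)
    runs <- rle(covered)
    expect_equal(nrow(merged), sum(runs$values))
    # each midpoint's coverage agrees
    expect_equal(bruteOverlap(merged, mids, mids), covered)
    path <- withr::local_tempfile(fileext = ".csv")
    writeAnnotations(merged, path)
    expect_equal(readAnnotations(path), merged)
  }
})

test_that("montage derivations are elementwise differences", {
  rec <- EEGRecording(rbind(FP1 = c(1, 2), F7 = c(0.5, 0.5)), fs = 256,
                      channelLabels = c("FP1", "F7"))
  out <- applyMontage(rec, bipolarMontage("FP1-F7"))
  expect_equal(recData(out)[1, ], c(0.5, 1.5))

  set.seed(3)
  rec4 <- EEGRecording(matrix(rnorm(4 * 100), 4), fs = 100,
                       channelLabels = c("A", "B", "C", "D"))
  mont <- bipolarMontage(c("B-D", "A-C", "C-B"))
  out4 <- applyMontage(rec4, mont)
  x <- recData(rec4)
  expect_equal(recData(out4),
               rbind(x[2, ] - x[4, ], x[1, ] - x[3, ], x[3, ] - x[2, ]),
               ignore_attr = TRUE)
  # referential montage passes signals through
  ident <- applyMontage(rec4, bipolarMontage(c("A", "B", "C", "D")))
  expect_equal(recData(ident), recData(rec4), ignore_attr = TRUE)
  expect_error(applyMontage(rec4, bipolarMontage("A-Z")), "not present")
})

test_that("montage application is linear in the input", {
  set.seed(4)
  rec <- EEGRecording(matrix(rnorm(3 * 50), 3), fs = 50,
                      channelLabels = c("A", "B", "C"))
  mont <- bipolarMontage(c("A-B", "B-C"))
  a <- 3.7
  scaled <- EEGRecording(a * recData(rec), fs = 50,
                         channelLabels = channelLabels(rec))
  expect_equal(recData(applyMontage(scaled, mont)),
               a * recData(applyMontage(rec, mont)))
})

test_that("slicing is half-open, re-references annotations, and composes", {
  set.seed(5)
  rec <- EEGRecording(matrix(rnorm(2 * 2560), 2), fs = 256,
                      annotations = data.frame(onset_s = 5, offset_s = 9))
  expect_equal(nSamples(sliceRecording(rec, 2, 6)), 1024)
  expect_equal(annotations(sliceRecording(rec, 2, 6)),
               data.frame(onset_s = 3, offset_s = 4))
  # identity slice
  expect_equal(recData(sliceRecording(rec, 0, 10)), recData(rec))
  # composition: slice [a,b) then [c,d) == slice [a+c, a+d)
  s1 <- sliceRecording(sliceRecording(rec, 1, 8), 2, 5)
  s2 <- sliceRecording(rec, 3, 6)
  expect_equal(recData(s1), recData(s2))
  expect_equal(annotations(s1), annotations(s2))
  expect_error(sliceRecording(rec, -1, 5), "out of range")
  expect_error(sliceRecording(rec, 6, 3), "out of range")
})
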