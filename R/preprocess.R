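# Segmentation, labelling, and patient-specific train / calibration / test
# construction.
#
# The training design oversamples the scarce ictal class: the selected
# training seizure events are concatenated into a continuous ictal stream
# and cut with a sliding window of T samples and step floor(T / n_over)
# (~80% overlap at n_over = 5), while interictal training data are drawn
# without overlap from 2*n_over seizure-free chunks of half the total
# training-seizure length each, giving an ictal:interictal duration ratio
# of about 1:n_over. A contiguous seizure-free calibration span (default
# 20 min) is reserved for post-processing calibration, and the remainder
# of the recording, in chronological order, forms the test stream.

#' Cut a recording into fixed-length labelled segments
#'
#' Windows start at samples `0, step, 2*step, ...`; a trailing window with
#' fewer than `T` samples is dropped. A segment is labelled ictal (1) iff
#' its half-open time interval intersects any annotated seizure interval
#' (any-overlap rule). All channels are cut synchronously.
#'
#' @param rec an [EEGRecording-class].
#' @param T window length in samples (default 1024, i.e. 4 s at 256 Hz).
#' @param step window step in samples (default `T`: non-overlapping).
#' @return a [SegmentSet-class].
#' @export
labelSegments <- function(rec, T = 1024L, step = T) {
  stopifnot(T >= 1L, step >= 1L, T <= nSamples(rec))
  fs <- sampleRate(rec)
  x <- recData(rec)
  starts <- seq(1L, nSamples(rec) - T + 1L, by = step)
  arr <- array(0, dim = c(nrow(x), T, length(starts)))
  for (i in seq_along(starts))
    arr[, , i] <- x[, starts[i]:(starts[i] + T - 1L)]
  startS <- (starts - 1L) / fs
  lab <- as.integer(anyIntervalOverlap(annotations(rec), startS, startS + T / fs))
  SegmentSet(arr, lab, startS, fs)
}

#' Patient-specific split plan
#'
#' @param trainEventIndices indices (into the recording's merged
#'   annotations) of the seizure events used for training.
#' @param nOver ictal oversampling rate (default 5).
#' @param calibrationDurationS length of the reserved seizure-free
#'   calibration span, seconds (default 1200 = 20 min).
#' @return a `splitPlan` list.
#' @export
splitPlan <- function(trainEventIndices, nOver = 5L, calibrationDurationS = 1200) {
  stopifnot(length(trainEventIndices) >= 1L, nOver >= 1L,
            calibrationDurationS > 0)
  structure(list(trainEventIndices = as.integer(trainEventIndices),
                 nOver = as.integer(nOver),
                 calibrationDurationS = calibrationDurationS),
            class = "splitPlan")
}

# sliding-window starts over a stream of n samples
windowStarts <- function(n, T, step) {
  if (n < T) integer(0) else seq(1L, n - T + 1L, by = step)
}

segmentStream <- function(x, T, step, label, fs) {
  starts <- windowStarts(ncol(x), T, step)
  if (length(starts) == 0L) stop("stream shorter than one window")
  arr <- array(0, dim = c(nrow(x), T, length(starts)))
  for (i in seq_along(starts))
    arr[, , i] <- x[, starts[i]:(starts[i] + T - 1L)]
  SegmentSet(arr, rep(label, length(starts)), (starts - 1L) / fs, fs)
}

#' Build the patient-specific training, calibration and test material
#'
#' @param rec an [EEGRecording-class] with seizure annotations (apply
#'   [filterRecording()] first if wavelet filtering is wanted; filtering is
#'   done on the continuous signal, not per window).
#' @param plan a [splitPlan()].
#' @param T window length in samples (default 1024).
#' @return a list with elements `train` (a [SegmentSet-class] of ictal and
#'   interictal windows), `calibration` (seizure-free
#'   [EEGRecording-class]), `test` (the remaining recording, chronological,
#'   with re-referenced annotations), and `info` (sample bookkeeping).
#' @export
buildTrainingSet <- function(rec, plan, T = 1024L) {
  stopifnot(is(rec, "EEGRecording"), inherits(plan, "splitPlan"))
  fs <- sampleRate(rec)
  ann <- annotations(rec)
  if (nrow(ann) == 0L) stop("recording has no seizure annotations")
  if (any(plan$trainEventIndices < 1L | plan$trainEventIndices > nrow(ann)))
    stop("train event indices out of range")
  x <- recData(rec)
  n <- ncol(x)

  evSpan <- function(i) {
    i0 <- floor(ann$onset_s[i] * fs) + 1L
    i1 <- min(n, floor(ann$offset_s[i] * fs))
    i0:i1
  }
  trainIdx <- sort(unique(unlist(lapply(plan$trainEventIndices, evSpan))))
  allEvIdx <- sort(unique(unlist(lapply(seq_len(nrow(ann)), evSpan))))

  # (a) ictal stream: concatenated training events, overlapped windows
  delta <- T %/% plan$nOver
  ictal <- segmentStream(x[, trainIdx, drop = FALSE], T, delta, 1L, fs)

  # (b) seizure-free sample pool
  freeMask <- rep(TRUE, n)
  freeMask[allEvIdx] <- FALSE

  # (c) calibration: earliest contiguous seizure-free span long enough
  calLen <- as.integer(round(plan$calibrationDurationS * fs))
  r <- rle(freeMask)
  ends <- cumsum(r$lengths)
  startsAt <- ends - r$lengths + 1L
  okRun <- which(r$values & r$lengths >= calLen)
  if (length(okRun) == 0L)
    stop("insufficient seizure-free material for the calibration span")
  calIdx <- startsAt[okRun[1]]:(startsAt[okRun[1]] + calLen - 1L)
  calibration <- EEGRecording(x[, calIdx, drop = FALSE], fs = fs,
                              channelLabels = channelLabels(rec))

  # (d) interictal chunks: 2*nOver chunks of length L_sz/2, uniformly
  # spaced over the remaining seizure-free samples (virtual concatenation)
  Lsz <- length(trainIdx)
  chunkLen <- Lsz %/% 2L
  pool <- which(freeMask)
  pool <- pool[!(pool %in% calIdx)]
  nChunks <- 2L * plan$nOver
  if (length(pool) < nChunks * chunkLen)
    stop("insufficient seizure-free material for interictal chunks")
  stratum <- length(pool) %/% nChunks
  if (stratum < chunkLen)
    stop("insufficient seizure-free material for interictal chunks")
  chunkIdx <- unlist(lapply(seq_len(nChunks) - 1L, function(s)
    pool[(s * stratum + 1L):(s * stratum + chunkLen)]))
  inter <- segmentStream(x[, chunkIdx, drop = FALSE], T, T, 0L, fs)

  # combined training set
  tr <- array(0, dim = c(nrow(x), T, nSegments(ictal) + nSegments(inter)))
  tr[, , seq_len(nSegments(ictal))] <- segData(ictal)
  tr[, , nSegments(ictal) + seq_len(nSegments(inter))] <- segData(inter)
  train <- SegmentSet(tr, c(segLabels(ictal), segLabels(inter)),
                      c(segStarts(ictal), segStarts(inter) + durationS(rec)),
                      fs)

  # (e) test = remainder in chronological order, annotations re-referenced
  keep <- rep(TRUE, n)
  keep[trainIdx] <- FALSE
  keep[calIdx] <- FALSE
  keep[chunkIdx] <- FALSE
  kept <- which(keep)
  cumKept <- cumsum(keep)
  testAnn <- ann[setdiff(seq_len(nrow(ann)), plan$trainEventIndices), ,
                 drop = FALSE]
  if (nrow(testAnn) > 0L) {
    onIdx <- pmin(n, floor(testAnn$onset_s * fs) + 1L)
    offIdx <- pmin(n, floor(testAnn$offset_s * fs))
    testAnn <- data.frame(onset_s = (cumKept[onIdx] - keep[onIdx]) / fs,
                          offset_s = cumKept[offIdx] / fs)
  }
  test <- EEGRecording(x[, kept, drop = FALSE], fs = fs,
                       channelLabels = channelLabels(rec),
                       annotations = testAnn)

  list(train = train, calibration = calibration, test = test,
       info = list(T = T, delta = delta, LszSamples = Lsz,
                   chunkLenSamples = chunkLen, nChunks = nChunks,
                   ictalSegments = nSegments(ictal),
                   interictalSegments = nSegments(inter),
                   trainSampleIdx = trainIdx, calSampleIdx = calIdx,
                   chunkSampleIdx = chunkIdx))
}
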