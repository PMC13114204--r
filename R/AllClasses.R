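#' @import methods
NULL

#' EEGRecording: a multichannel scalp EEG recording
#'
#' Holds a C x S signal matrix (microvolts), channel labels, the sampling
#' rate and the seizure annotations. Annotations are stored merged and
#' sorted; each must lie within the recording duration.
#'
#' @slot channelLabels character vector of length C.
#' @slot fs sampling rate in Hz.
#' @slot data numeric matrix, channels x samples.
#' @slot annotations `data.frame` with columns `onset_s`, `offset_s`.
#' @export
setClass("EEGRecording",
  representation(channelLabels = "character", fs = "numeric",
                 data = "matrix", annotations = "data.frame"),
  prototype(annotations = data.frame(onset_s = numeric(0),
                                     offset_s = numeric(0))))

setValidity("EEGRecording", function(object) {
  msgs <- character(0)
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msgs <- c(msgs, "fs must be a single positive number")
  if (nrow(object@data) != length(object@channelLabels))
    msgs <- c(msgs, "number of rows of data must equal number of channel labels")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msgs <- c(msgs, "all samples must be finite")
  ann <- object@annotations
  if (!all(c("onset_s", "offset_s") %in% names(ann))) {
    msgs <- c(msgs, "annotations need columns onset_s, offset_s")
  } else if (nrow(ann) > 0L) {
    if (any(ann$onset_s < 0) || any(ann$offset_s <= ann$onset_s))
      msgs <- c(msgs, "annotations must satisfy 0 <= onset < offset")
    dur <- ncol(object@data) / object@fs
    if (any(ann$offset_s > dur + 1e-9))
      msgs <- c(msgs, "annotations must lie within the recording")
    if (is.unsorted(ann$onset_s))
      msgs <- c(msgs, "annotations must be sorted by onset")
    if (nrow(ann) > 1L && any(ann$onset_s[-1] < ann$offset_s[-nrow(ann)]))
      msgs <- c(msgs, "annotations must be non-overlapping")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an EEGRecording
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate, Hz.
#' @param channelLabels channel names; defaults to `ch1..chC`.
#' @param annotations seizure annotation `data.frame` (merged/sorted on
#'   construction).
#' @return an [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(512), 2), fs = 256)
#' nChannels(rec); durationS(rec)
#' @export
EEGRecording <- function(data, fs, channelLabels = NULL, annotations = NULL) {
  data <- as.matrix(data)
  if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(nrow(data)))
  if (is.null(annotations)) annotations <- seizureIntervals()
  else annotations <- seizureIntervals(annotations$onset_s, annotations$offset_s)
  new("EEGRecording", channelLabels = as.character(channelLabels),
      fs = as.numeric(fs), data = data, annotations = annotations)
}

#' Accessors for EEGRecording
#' @param x an [EEGRecording-class].
#' @name recording-accessors
NULL

#' @rdname recording-accessors
#' @export
recData <- function(x) x@data
#' @rdname recording-accessors
#' @export
sampleRate <- function(x) x@fs
#' @rdname recording-accessors
#' @export
channelLabels <- function(x) x@channelLabels
#' @rdname recording-accessors
#' @export
annotations <- function(x) x@annotations
#' @rdname recording-accessors
#' @export
nChannels <- function(x) nrow(x@data)
#' @rdname recording-accessors
#' @export
nSamples <- function(x) ncol(x@data)
#' @rdname recording-accessors
#' @export
durationS <- function(x) ncol(x@data) / x@fs

#' @rdname recording-accessors
#' @param value replacement annotation `data.frame`.
#' @export
`annotations<-` <- function(x, value) {
  x@annotations <- seizureIntervals(value$onset_s, value$offset_s)
  validObject(x)
  x
}

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples (%.1f s at %g Hz)\n",
              nrow(object@data), ncol(object@data),
              ncol(object@data) / object@fs, object@fs))
  cat(sprintf("  seizure annotations: %d interval(s)\n", nrow(object@annotations)))
})

#' SegmentSet: windowed EEG samples with binary labels
#'
#' Segments are stored as a C x T x n array; `labels` is 0 (interictal) or 1
#' (ictal) per segment and `startS` gives the source timestamp of each
#' window start.
#'
#' @slot data numeric array, channels x samples-per-window x n segments.
#' @slot labels integer vector in \{0, 1\}.
#' @slot startS numeric vector of window start times, seconds.
#' @slot fs sampling rate, Hz.
#' @export
setClass("SegmentSet",
  representation(data = "array", labels = "integer", startS = "numeric",
                 fs = "numeric"))

setValidity("SegmentSet", function(object) {
  msgs <- character(0)
  d <- dim(object@data)
  if (length(d) != 3L) msgs <- c(msgs, "data must be a 3-D array (C x T x n)")
  else {
    if (d[3] != length(object@labels)) msgs <- c(msgs, "one label per segment")
    if (d[3] != length(object@startS)) msgs <- c(msgs, "one start time per segment")
  }
  if (!all(object@labels %in% c(0L, 1L))) msgs <- c(msgs, "labels must be 0/1")
  if (any(object@startS < 0)) msgs <- c(msgs, "start times must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SegmentSet
#' @param data C x T x n numeric array.
#' @param labels 0/1 vector, one per segment.
#' @param startS window start times in seconds.
#' @param fs sampling rate in Hz.
#' @export
SegmentSet <- function(data, labels, startS, fs) {
  new("SegmentSet", data = data, labels = as.integer(labels),
      startS = as.numeric(startS), fs = as.numeric(fs))
}

#' Accessors for SegmentSet
#' @param x a [SegmentSet-class].
#' @name segmentset-accessors
NULL

#' @rdname segmentset-accessors
#' @export
segData <- function(x) x@data
#' @rdname segmentset-accessors
#' @export
segLabels <- function(x) x@labels
#' @rdname segmentset-accessors
#' @export
segStarts <- function(x) x@startS
#' @rdname segmentset-accessors
#' @export
nSegments <- function(x) dim(x@data)[3]
#' @rdname segmentset-accessors
#' @export
segmentDurationS <- function(x) dim(x@data)[2] / x@fs

setMethod("show", "SegmentSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("SegmentSet: %d segments of %d channels x %d samples (%g s), %d ictal / %d interictal\n",
              d[3], d[1], d[2], d[2] / object@fs,
              sum(object@labels == 1L), sum(object@labels == 0L)))
})

#' ScoreSequence: per-segment seizure probability stream
#'
#' @slot scores numeric vector in \[0, 1\], one per consecutive segment.
#' @slot segmentDurationS duration of one segment in seconds (default 4).
#' @slot originS time of the first segment's start, seconds.
#' @export
setClass("ScoreSequence",
  representation(scores = "numeric", segmentDurationS = "numeric",
                 originS = "numeric"),
  prototype(segmentDurationS = 4, originS = 0))

setValidity("ScoreSequence", function(object) {
  msgs <- character(0)
  if (length(object@scores) < 1L) msgs <- c(msgs, "at least one score required")
  if (any(object@scores < -1e-9 | object@scores > 1 + 1e-9))
    msgs <- c(msgs, "scores must lie in [0, 1]")
  if (object@segmentDurationS <= 0) msgs <- c(msgs, "segment duration must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ScoreSequence
#' @param scores numeric scores in \[0, 1\].
#' @param segmentDurationS segment length in seconds.
#' @param originS start time of the first segment.
#' @export
ScoreSequence <- function(scores, segmentDurationS = 4, originS = 0) {
  new("ScoreSequence", scores = pmin(1, pmax(0, as.numeric(scores))),
      segmentDurationS = as.numeric(segmentDurationS), originS = as.numeric(originS))
}

#' @rdname ScoreSequence
#' @param x a [ScoreSequence-class].
#' @export
scores <- function(x) x@scores

setMethod("show", "ScoreSequence", function(object) {
  cat(sprintf("ScoreSequence: %d segments of %g s from t=%g s (mean score %.3f)\n",
              length(object@scores), object@segmentDurationS, object@originS,
              mean(object@scores)))
})

setMethod("length", "ScoreSequence", function(x) length(x@scores))
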