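#' Montages: referential and bipolar derivations
#'
#' A montage is a `data.frame` with columns `name`, `positive` and
#' `negative`. A bipolar derivation subtracts the negative electrode's
#' signal from the positive one's (`FP1-F7` means `FP1 - F7`); a referential
#' derivation (`negative = NA`) passes the electrode through unchanged.
#' Electrode labels are matched case-insensitively with surrounding
#' whitespace stripped, since EDF headers vary.
#'
#' @param derivations character vector; entries of the form `"POS-NEG"`
#'   become bipolar derivations, plain labels become referential.
#' @return a montage `data.frame`.
#' @examples
#' bipolarMontage(c("FP1-F7", "F7-T7"))
#' @export
bipolarMontage <- function(derivations) {
  parts <- strsplit(derivations, "-", fixed = TRUE)
  data.frame(
    name = derivations,
    positive = vapply(parts, function(p) trimws(p[[1]]), ""),
    negative = vapply(parts, function(p) if (length(p) > 1L) trimws(p[[2]]) else NA_character_, ""))
}

#' @rdname bipolarMontage
#' @details `standardLongitudinalMontage()` returns the 18 common bipolar
#'   derivations of the international 10-20 longitudinal ("double banana")
#'   layout shared by CHB-MIT-style recordings.
#' @export
standardLongitudinalMontage <- function() {
  bipolarMontage(c("FP1-F7", "F7-T7", "T7-P7", "P7-O1",
                   "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
                   "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
                   "FP2-F8", "F8-T8", "T8-P8", "P8-O2",
                   "FZ-CZ", "CZ-PZ"))
}

#' Apply a montage to a recording
#'
#' @param rec an [EEGRecording-class] of electrode (referential) signals.
#' @param montage a montage `data.frame` from [bipolarMontage()].
#' @return an [EEGRecording-class] with one row per derivation; sampling
#'   rate and annotations are unchanged.
#' @export
applyMontage <- function(rec, montage) {
  stopifnot(is(rec, "EEGRecording"),
            all(c("name", "positive", "negative") %in% names(montage)))
  have <- tolower(trimws(channelLabels(rec)))
  lookup <- function(lab) {
    i <- match(tolower(trimws(lab)), have)
    if (is.na(i)) stop("montage electrode not present in recording: ", lab)
    i
  }
  x <- recData(rec)
  out <- matrix(0, nrow(montage), ncol(x))
  for (r in seq_len(nrow(montage))) {
    pos <- lookup(montage$positive[r])
    if (is.na(montage$negative[r])) out[r, ] <- x[pos, ]
    else out[r, ] <- x[pos, ] - x[lookup(montage$negative[r]), ]
  }
  EEGRecording(out, fs = sampleRate(rec), channelLabels = montage$name,
               annotations = annotations(rec))
}

#' Extract a time slice of a recording
#'
#' Samples in the half-open interval `[start_s, end_s)` are kept (sample
#' index of time `t` is `floor(t * fs)`). Annotations are clipped to the
#' slice and re-referenced so the slice starts at time 0.
#'
#' @param rec an [EEGRecording-class].
#' @param start_s,end_s slice bounds in seconds, `0 <= start_s < end_s <=
#'   duration`.
#' @return an [EEGRecording-class].
#' @export
sliceRecording <- function(rec, start_s, end_s) {
  dur <- durationS(rec)
  if (start_s < 0 || start_s >= end_s || end_s > dur + 1e-9)
    stop("slice bounds out of range: [", start_s, ", ", end_s, ") of ", dur, " s")
  fs <- sampleRate(rec)
  i0 <- floor(start_s * fs) + 1L
  i1 <- floor(end_s * fs)
  EEGRecording(recData(rec)[, i0:i1, drop = FALSE], fs = fs,
               channelLabels = channelLabels(rec),
               annotations = clipIntervals(annotations(rec), start_s, end_s))
}
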