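# EDF (European Data Format) input/output.
#
# EDF stores a 256-byte ASCII header, 256 ASCII bytes per signal of
# per-channel metadata, then data records of little-endian int16 samples.
# Physical values are recovered by linear rescaling from the digital range,
# so a write/read round trip is exact only up to 16-bit quantization of the
# per-channel physical range.

edfField <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

padField <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = -n)  # left-justified, space padded
}

#' Read an EEG recording from an EDF file
#'
#' All requested channels must share one sampling rate. Annotations are not
#' read from the EDF container; load them separately with
#' [readAnnotations()].
#'
#' @param path EDF file path.
#' @param channels optional character vector of channel labels to keep
#'   (matched case-insensitively, whitespace stripped); default all.
#' @return an [EEGRecording-class] with empty annotations.
#' @seealso [writeEDF()], [readAnnotations()]
#' @export
readEDF <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edfField(con, 8)
  if (!identical(version, "0")) stop("not an EDF file (bad version field): ", path)
  edfField(con, 80); edfField(con, 80)            # patient, recording id
  edfField(con, 8); edfField(con, 8)              # start date, time
  headerBytes <- as.integer(edfField(con, 8))
  edfField(con, 44)                               # reserved
  nRecords <- as.integer(edfField(con, 8))
  recordDur <- as.numeric(edfField(con, 8))
  ns <- as.integer(edfField(con, 4))
  if (is.na(ns) || ns < 1L) stop("EDF header: invalid signal count")
  readFields <- function(n) vapply(seq_len(ns), function(i) edfField(con, n), "")
  labels <- readFields(16)
  readFields(80)                                  # transducer
  readFields(8)                                   # physical dimension
  physMin <- as.numeric(readFields(8))
  physMax <- as.numeric(readFields(8))
  digMin <- as.numeric(readFields(8))
  digMax <- as.numeric(readFields(8))
  readFields(80)                                  # prefilter
  spr <- as.integer(readFields(8))                # samples per record
  readFields(32)                                  # reserved
  if (any(is.na(c(physMin, physMax, digMin, digMax, spr))))
    stop("EDF header: unparsable numeric fields")
  stopifnot(headerBytes == 256L * (ns + 1L))

  sel <- seq_len(ns)
  if (!is.null(channels)) {
    want <- tolower(trimws(channels))
    have <- tolower(trimws(labels))
    idx <- match(want, have)
    if (anyNA(idx))
      stop("channel(s) not present in EDF: ",
           paste(channels[is.na(idx)], collapse = ", "))
    sel <- idx
  }
  fsAll <- spr / recordDur
  if (length(unique(fsAll[sel])) != 1L)
    stop("requested channels have heterogeneous sampling rates")
  fs <- fsAll[sel[1]]

  data <- matrix(0, length(sel), nRecords * spr[sel[1]])
  scale <- (physMax - physMin) / (digMax - digMin)
  recLen <- sum(spr)
  offsets <- c(0L, cumsum(spr))
  for (r in seq_len(nRecords)) {
    rec <- readBin(con, "integer", n = recLen, size = 2, endian = "little")
    if (length(rec) < recLen) stop("EDF file truncated at record ", r)
    for (j in seq_along(sel)) {
      s <- sel[j]
      dig <- rec[(offsets[s] + 1L):offsets[s + 1L]]
      data[j, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        (dig - digMin[s]) * scale[s] + physMin[s]
    }
  }
  EEGRecording(data, fs = fs, channelLabels = labels[sel])
}

#' Write an EEG recording to an EDF file
#'
#' Minimal writer intended for fixtures and synthetic data. Samples are
#' quantized to the 16-bit digital range over each channel's observed
#' physical range. The recording is padded with trailing zeros to a whole
#' number of 1-second data records.
#'
#' @param rec an [EEGRecording-class].
#' @param path output file path.
#' @return `path`, invisibly. Annotations are not embedded; write them with
#'   [writeAnnotations()].
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- sampleRate(rec)
  spr <- as.integer(round(fs))
  if (abs(spr - fs) > 1e-9) stop("writeEDF requires an integer sampling rate")
  x <- recData(rec)
  C <- nrow(x); S <- ncol(x)
  nRecords <- as.integer(ceiling(S / spr))
  if (nRecords * spr > S)
    x <- cbind(x, matrix(0, C, nRecords * spr - S))

  physMax <- apply(abs(x), 1, max)
  physMax <- ifelse(physMax > 0, signif(physMax * 1.0001, 6), 1)
  physMin <- -physMax
  digMin <- -32768; digMax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, n) writeBin(charToRaw(padField(s, n)), con)
  wr("0", 8); wr("synthetic", 80); wr("coseize fixture", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256L * (C + 1L), 8); wr("", 44)
  wr(nRecords, 8); wr("1", 8); wr(C, 4)
  for (lab in channelLabels(rec)) wr(lab, 16)
  for (i in seq_len(C)) wr("", 80)
  for (i in seq_len(C)) wr("uV", 8)
  for (v in physMin) wr(format(v, digits = 6, scientific = FALSE), 8)
  for (v in physMax) wr(format(v, digits = 6, scientific = FALSE), 8)
  for (i in seq_len(C)) wr(digMin, 8)
  for (i in seq_len(C)) wr(digMax, 8)
  for (i in seq_len(C)) wr("", 80)
  for (i in seq_len(C)) wr(spr, 8)
  for (i in seq_len(C)) wr("", 32)
  # re-read the formatted phys ranges so quantization matches the header
  pMin <- as.numeric(format(physMin, digits = 6, scientific = FALSE))
  pMax <- as.numeric(format(physMax, digits = 6, scientific = FALSE))
  for (r in seq_len(nRecords)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(C)) {
      dig <- round((x[i, cols] - pMin[i]) / (pMax[i] - pMin[i]) *
                     (digMax - digMin) + digMin)
      dig <- pmin(pmax(dig, digMin), digMax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
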