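# Multilevel discrete wavelet transform (Daubechies-4) with symmetric
# signal extension, plus sub-band filtering by reconstructing from a
# selected subset of coefficient bands.
#
# With a 5-level decomposition at 256 Hz the detail bands cover
# d1: 64-128 Hz, d2: 32-64, d3: 16-32, d4: 8-16, d5: 4-8, and a5: 0-4 Hz;
# keeping {d3, d4, d5} band-passes 4-32 Hz, the clinically relevant range
# for scalp seizure activity.

# Daubechies-4 decomposition low-pass filter (8 taps)
DB4_DEC_LO <- c(-0.010597401784997278, 0.032883011666982945,
                0.030841381835986965, -0.187034811718881140,
                -0.027983769416983850, 0.630880767929590400,
                0.714846570552541500, 0.230377813308855230)

dwtFilters <- function() {
  lo <- DB4_DEC_LO
  F <- length(lo)
  hi <- rev(lo) * (-1)^seq_len(F)         # quadrature mirror
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi))
}

# symmetric (half-sample) extension by m samples each side
symExtend <- function(x, m) {
  n <- length(x)
  left <- x[pmin(m:1, n)]
  right <- x[pmax(n - (1:m) + 1, 1)]
  c(left, x, right)
}

# full linear convolution via FFT-free filter() is slower; direct is fine here
convFull <- function(x, h) {
  n <- length(x); m <- length(h)
  y <- numeric(n + m - 1)
  for (k in seq_len(m)) y[k:(k + n - 1)] <- y[k:(k + n - 1)] + h[k] * x
  y
}

# one analysis step: returns approximation and detail coefficients,
# length floor((n + F - 1) / 2) each
dwtStep <- function(x, filt) {
  F <- length(filt$dec_lo)
  ext <- symExtend(x, F - 1L)
  lo <- convFull(ext, filt$dec_lo)
  hi <- convFull(ext, filt$dec_hi)
  keep <- seq(F + 1L, by = 2L, length.out = (length(x) + F - 1L) %/% 2L)
  list(a = lo[keep], d = hi[keep])
}

# one synthesis step: inverse of dwtStep, truncated to length nOut
idwtStep <- function(a, d, filt, nOut) {
  F <- length(filt$rec_lo)
  up <- function(c) { u <- numeric(2L * length(c)); u[seq(1, length(u), 2)] <- c; u }
  y <- convFull(up(a), filt$rec_lo) + convFull(up(d), filt$rec_hi)
  y[(F - 1L):(F - 2L + nOut)]             # drop extension transients
}

# multilevel decomposition: list(a = a_L, d = list(d1, d2, ..., d_L),
# lengths = per-level input lengths for reconstruction)
dwtDecompose <- function(x, levels) {
  filt <- dwtFilters()
  F <- length(filt$dec_lo)
  if (length(x) < 2^levels)
    stop("signal too short for a ", levels, "-level decomposition")
  d <- vector("list", levels)
  lens <- integer(levels)
  a <- x
  for (l in seq_len(levels)) {
    lens[l] <- length(a)
    if (length(a) < F)
      stop("signal shorter than the wavelet filter support at level ", l)
    s <- dwtStep(a, filt)
    a <- s$a
    d[[l]] <- s$d
  }
  list(a = a, d = d, lengths = lens)
}

dwtReconstruct <- function(dec) {
  filt <- dwtFilters()
  a <- dec$a
  for (l in rev(seq_along(dec$d)))
    a <- idwtStep(a, dec$d[[l]], filt, dec$lengths[l])
  a
}

#' Wavelet sub-band filter
#'
#' Decomposes a signal with a multilevel DWT, zeroes every coefficient band
#' not listed in `keep`, and reconstructs. Output length equals input
#' length. With the defaults (db4, 5 levels, keep d3/d4/d5) this retains
#' the 4-32 Hz range of a 256 Hz signal.
#'
#' @param x numeric vector (one channel), or a matrix whose rows are
#'   filtered independently.
#' @param levels decomposition depth (default 5).
#' @param keep character vector of bands to keep, from
#'   `"d1"..."d<levels>"` and `"a<levels>"`.
#' @param wavelet wavelet identifier; `"db4"` is the only one provided.
#' @return filtered signal, same shape as `x`.
#' @examples
#' t <- seq(0, 2, by = 1 / 256)
#' y <- dwtSubbandFilter(sin(2 * pi * 10 * t))  # 10 Hz passes
#' @export
dwtSubbandFilter <- function(x, levels = 5L, keep = c("d3", "d4", "d5"),
                             wavelet = "db4") {
  if (!identical(wavelet, "db4"))
    stop("only the Daubechies-4 (\"db4\") wavelet is provided")
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x))) out[i, ] <- dwtSubbandFilter(x[i, ], levels, keep)
    return(out)
  }
  dec <- dwtDecompose(x, levels)
  bands <- c(paste0("d", seq_len(levels)), paste0("a", levels))
  unknown <- setdiff(keep, bands)
  if (length(unknown)) stop("unknown band(s): ", paste(unknown, collapse = ", "))
  if (!(paste0("a", levels) %in% keep)) dec$a <- numeric(length(dec$a))
  for (l in seq_len(levels))
    if (!(paste0("d", l) %in% keep)) dec$d[[l]] <- numeric(length(dec$d[[l]]))
  dwtReconstruct(dec)
}

#' @rdname dwtSubbandFilter
#' @param rec an [EEGRecording-class]; each channel is filtered
#'   independently on the continuous signal (before any segmentation, so
#'   window edges carry no filter transients).
#' @export
filterRecording <- function(rec, levels = 5L, keep = c("d3", "d4", "d5")) {
  EEGRecording(dwtSubbandFilter(recData(rec), levels, keep),
               fs = sampleRate(rec), channelLabels = channelLabels(rec),
               annotations = annotations(rec))
}
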