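# Score post-processing: moving-average smoothing, thresholding, collar
# extension, and per-patient calibration of the three parameters.

#' Moving-average smoothing of a score sequence
#'
#' Interior points are the mean of the centred `(2N+1)`-sample window
#' `y_t = mean(x[(t-N):(t+N)])`; at the boundaries (where the full window
#' would leave the sequence) the mean is taken over the in-range samples
#' only, so the output keeps the input length.
#'
#' @param seq a [ScoreSequence-class] or numeric vector.
#' @param N half-window in segments (`>= 0`; window length `2N+1`).
#' @return same type as the input, smoothed; never exceeds the input range.
#' @export
mafSmooth <- function(seq, N) {
  stopifnot(N >= 0)
  x <- if (is(seq, "ScoreSequence")) scores(seq) else seq
  n <- length(x)
  if (N == 0L || n == 1L) y <- x
  else {
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - N, 1L)
    hi <- pmin(seq_len(n) + N, n)
    y <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  if (is(seq, "ScoreSequence"))
    ScoreSequence(y, seq@segmentDurationS, seq@originS)
  else y
}

#' Threshold smoothed scores into binary labels
#'
#' Strictly greater than: `label_t = 1` iff `y_t > Thr`.
#'
#' @param seq a [ScoreSequence-class] or numeric vector.
#' @param Thr decision threshold in (0, 1).
#' @return integer 0/1 vector.
#' @export
binarize <- function(seq, Thr) {
  stopifnot(Thr > 0, Thr < 1)
  x <- if (is(seq, "ScoreSequence")) scores(seq) else seq
  as.integer(x > Thr)
}

#' Collar extension of binary decisions
#'
#' Every maximal run of 1s grows by `K` positions on each side (clipped to
#' the sequence); runs that touch after extension merge. Equivalent to a
#' morphological dilation, so no positive is ever removed and the operation
#' is monotone in `K`.
#'
#' @param labels integer 0/1 vector.
#' @param K collar length in segments (`>= 0`).
#' @return extended 0/1 vector of the same length.
#' @export
collarExtend <- function(labels, K) {
  stopifnot(K >= 0)
  n <- length(labels)
  if (K == 0L || n == 0L || !any(labels == 1L)) return(as.integer(labels))
  pos <- which(labels == 1L)
  out <- integer(n)
  idx <- unique(pmin(pmax(rep(pos, each = 2L * K + 1L) + (-K):K, 1L), n))
  out[idx] <- 1L
  out
}

#' Convert binary segment labels to predicted events
#'
#' Each maximal run of positives `[i, j]` (1-based) becomes the interval
#' `[origin + (i-1)*d, origin + j*d)` in seconds.
#'
#' @param labels 0/1 vector.
#' @param segmentDurationS segment duration `d` in seconds.
#' @param originS time of the first segment's start.
#' @return annotation `data.frame` (`onset_s`, `offset_s`), sorted and
#'   non-overlapping.
#' @export
labelsToEvents <- function(labels, segmentDurationS = 4, originS = 0) {
  stopifnot(all(labels %in% c(0L, 1L)))
  if (!any(labels == 1L))
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  data.frame(onset_s = originS + (starts[keep] - 1L) * segmentDurationS,
             offset_s = originS + ends[keep] * segmentDurationS)
}

# run the full pipeline on a raw score vector
applyPostproc <- function(x, params, segmentDurationS = 4, originS = 0) {
  lab <- binarize(mafSmooth(x, params$N), params$Thr)
  lab <- collarExtend(lab, params$K)
  list(labels = lab,
       events = labelsToEvents(lab, segmentDurationS, originS))
}

#' Post-processing parameters
#'
#' @param N moving-average half-window, segments.
#' @param Thr decision threshold in (0, 1).
#' @param K collar extension, segments (4 s units at the default segment
#'   length).
#' @export
postprocParams <- function(N, Thr, K) {
  stopifnot(N >= 0, K >= 0, Thr > 0, Thr < 1)
  structure(list(N = as.integer(N), Thr = Thr, K = as.integer(K)),
            class = "postprocParams")
}

#' Calibrate post-processing parameters for one patient
#'
#' Grid search over `(N, Thr, K)`. A grid point is admissible if, applied
#' to the training-event score stream, the resulting events detect (by any
#' overlap) every training seizure. Among admissible points the one with
#' the fewest false-alarm events on the seizure-free calibration stream
#' wins; ties break by fewer alarms, smaller `K`, smaller `N`, then `Thr`
#' nearest 0.5. If no point detects all training events, a warning is
#' issued and the point maximizing detections (then minimizing alarms) is
#' returned.
#'
#' @param calScores [ScoreSequence-class] (or numeric) from the seizure-free
#'   calibration stream.
#' @param trainScores [ScoreSequence-class] (or numeric) from the
#'   training-event stream.
#' @param trainEvents annotation `data.frame` of the training seizures in
#'   the training-stream time base.
#' @param grid list with numeric vectors `N`, `Thr`, `K` (defaults
#'   `0:6`, `seq(0.1, 0.9, 0.1)`, `0:6`).
#' @param segmentDurationS segment duration, seconds.
#' @return a [postprocParams()].
#' @export
calibratePostproc <- function(calScores, trainScores, trainEvents,
                              grid = list(N = 0:6, Thr = seq(0.1, 0.9, by = 0.1),
                                          K = 0:6),
                              segmentDurationS = 4) {
  cal <- if (is(calScores, "ScoreSequence")) scores(calScores) else calScores
  trs <- if (is(trainScores, "ScoreSequence")) scores(trainScores) else trainScores
  stopifnot(length(grid$N) > 0, length(grid$Thr) > 0, length(grid$K) > 0)
  cand <- expand.grid(N = grid$N, Thr = grid$Thr, K = grid$K)
  nTrain <- nrow(trainEvents)
  res <- lapply(seq_len(nrow(cand)), function(i) {
    p <- postprocParams(cand$N[i], cand$Thr[i], cand$K[i])
    alarms <- nrow(applyPostproc(cal, p, segmentDurationS)$events)
    ev <- applyPostproc(trs, p, segmentDurationS)$events
    detected <- sum(anyIntervalOverlap(ev, trainEvents$onset_s,
                                       trainEvents$offset_s))
    list(p = p, alarms = alarms, detected = detected)
  })
  alarms <- vapply(res, `[[`, 0, "alarms")
  detected <- vapply(res, `[[`, 0, "detected")
  admissible <- detected == nTrain
  if (!any(admissible)) {
    warning("no grid point detects all training seizure events; ",
            "returning the best-detecting point")
    pool <- which(detected == max(detected))
  } else pool <- which(admissible)
  o <- order(alarms[pool], cand$K[pool], cand$N[pool],
             abs(cand$Thr[pool] - 0.5))
  res[[pool[o[1]]]]$p
}
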