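# Segment-based metrics, event-based metrics (event sensitivity and false
# detections per hour), AUROC under a fixed 24 s smoothing/collar setting,
# and the aggregation arithmetic for multi-patient summaries.

#' Segment-based classification metrics
#'
#' @param predicted,truth equal-length 0/1 vectors.
#' @return list with `sensitivity`, `specificity`, `accuracy` (percent).
#'   If a class is absent the corresponding rate is `NA` (not applicable).
#' @export
segmentMetrics <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  stopifnot(all(predicted %in% c(0L, 1L)), all(truth %in% c(0L, 1L)))
  tp <- sum(predicted == 1L & truth == 1L)
  tn <- sum(predicted == 0L & truth == 0L)
  fp <- sum(predicted == 1L & truth == 0L)
  fn <- sum(predicted == 0L & truth == 1L)
  list(sensitivity = if (tp + fn > 0L) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0L) 100 * tn / (tn + fp) else NA_real_,
       accuracy = 100 * (tp + tn) / length(truth))
}

#' Event-based metrics
#'
#' A true seizure counts as detected iff at least one predicted event
#' overlaps it (any overlap, half-open intervals); multiple predictions on
#' one seizure count once. A predicted event is false iff it overlaps no
#' true seizure; the false detection rate is false events per hour of test
#' recording.
#'
#' @param predicted annotation `data.frame` of predicted events.
#' @param truth annotation `data.frame` of expert-marked seizures.
#' @param testHours duration of the evaluated recording in hours (> 0).
#' @return list with `eventSensitivity` (percent, `NA` when no seizures
#'   are marked), `fdrPerHour`, `detected`, `marked`, `falseEvents`.
#' @export
eventMetrics <- function(predicted, truth, testHours) {
  stopifnot(testHours > 0)
  marked <- nrow(truth)
  detected <- sum(anyIntervalOverlap(predicted, truth$onset_s, truth$offset_s))
  falseEv <- sum(!anyIntervalOverlap(truth, predicted$onset_s,
                                     predicted$offset_s))
  list(eventSensitivity = if (marked > 0L) 100 * detected / marked else NA_real_,
       fdrPerHour = falseEv / testHours,
       detected = detected, marked = marked, falseEvents = falseEv)
}

# Mann-Whitney AUROC with midranks for ties
aurocRank <- function(score, label) {
  n1 <- sum(label == 1L); n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUROC undefined: only one class present")
  r <- rank(score)                        # midranks
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUROC under the fixed 24 s post-processing setting
#'
#' Scores are smoothed with a 24 s (6-segment) moving average — an
#' asymmetric centred window of 3 past samples, the current one, and 2
#' future ones, shrunk at the boundaries — and the reference labels are
#' dilated by 6 segments (a 24 s collar applied to the truth, since the
#' scores stay continuous). The AUROC is then the midrank Mann-Whitney
#' statistic of smoothed scores against dilated labels.
#'
#' @param seq a [ScoreSequence-class] or numeric score vector.
#' @param truth 0/1 vector, one label per segment.
#' @param windowS smoothing/collar length in seconds (default 24).
#' @return AUROC in \[0, 1\].
#' @export
aurocFixedPostproc <- function(seq, truth, windowS = 24) {
  x <- if (is(seq, "ScoreSequence")) scores(seq) else seq
  d <- if (is(seq, "ScoreSequence")) seq@segmentDurationS else 4
  if (length(x) != length(truth)) stop("scores and labels differ in length")
  if (length(unique(truth)) < 2L) stop("AUROC undefined: only one class present")
  w <- max(1L, as.integer(round(windowS / d)))
  nPast <- w %/% 2L                       # 3 past + current + 2 future at w = 6
  nFut <- w - nPast - 1L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - nPast, 1L)
  hi <- pmin(seq_len(n) + nFut, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  dil <- collarExtend(as.integer(truth), w)
  if (length(unique(dil)) < 2L)
    stop("AUROC undefined: collar dilation removed the negative class")
  aurocRank(sm, dil)
}

#' Macro average across patients
#'
#' Arithmetic mean and population standard deviation (n denominator — the
#' convention that reproduces published per-patient summary rows; the
#' sample-SD variant is available via `convention = "sample"`) of a
#' per-patient metric vector.
#'
#' @param values numeric vector, one value per patient.
#' @param convention `"population"` (default) or `"sample"`.
#' @return list with `mean` and `sd` (0 for a single value).
#' @export
macroAverage <- function(values, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  n <- length(values)
  if (n == 0L) stop("no values to average")
  s <- if (n > 1L) {
    if (convention == "population") stats::sd(values) * sqrt((n - 1) / n)
    else stats::sd(values)
  } else 0
  list(mean = mean(values), sd = s)
}

#' Pooled event sensitivity
#'
#' `100 * sum(detected) / sum(marked)` over patients — the aggregation
#' used for summary rows of event tables (distinct from the macro average
#' of per-patient percentages).
#'
#' @param detected,marked integer vectors per patient.
#' @return percentage.
#' @export
pooledEventSensitivity <- function(detected, marked) {
  stopifnot(length(detected) == length(marked), all(detected <= marked))
  if (sum(marked) == 0L) stop("no marked events")
  100 * sum(detected) / sum(marked)
}
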