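#' Seizure interval utilities
#'
#' Annotations are kept as a two-column `data.frame` with numeric columns
#' `onset_s` and `offset_s` (seconds from recording start). All intervals are
#' half-open `[onset, offset)`; two intervals overlap iff
#' `onset1 < offset2 && onset2 < offset1`. Touching intervals
#' (`offset1 == onset2`) are merged into one, matching the half-open
#' convention used for segment labelling.
#'
#' @param onset_s,offset_s numeric vectors of equal length, seconds.
#' @return `seizureIntervals()` returns a validated, sorted, merged
#'   annotation `data.frame`.
#' @examples
#' seizureIntervals(c(10, 15), c(20, 25))  # merges to [10, 25)
#' @export
seizureIntervals <- function(onset_s = numeric(0), offset_s = numeric(0)) {
  if (length(onset_s) != length(offset_s))
    stop("onset_s and offset_s must have equal length")
  df <- data.frame(onset_s = as.numeric(onset_s), offset_s = as.numeric(offset_s))
  validateIntervals(df)
  mergeIntervals(df)
}

validateIntervals <- function(df) {
  stopifnot(is.data.frame(df), all(c("onset_s", "offset_s") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(!is.finite(df$onset_s)) || any(!is.finite(df$offset_s)))
    stop("interval times must be finite")
  if (any(df$onset_s < 0)) stop("negative interval onset")
  if (any(df$offset_s <= df$onset_s)) stop("interval offset must exceed onset")
  invisible(df)
}

# sort by onset and merge overlapping / touching intervals
mergeIntervals <- function(df) {
  if (nrow(df) <= 1L) return(df[order(df$onset_s), , drop = FALSE])
  df <- df[order(df$onset_s, df$offset_s), , drop = FALSE]
  on <- df$onset_s; off <- df$offset_s
  keep_on <- on[1]; keep_off <- off[1]
  res_on <- numeric(0); res_off <- numeric(0)
  for (i in seq_len(nrow(df))[-1]) {
    if (on[i] <= keep_off) {            # overlap or touch: extend
      keep_off <- max(keep_off, off[i])
    } else {
      res_on <- c(res_on, keep_on); res_off <- c(res_off, keep_off)
      keep_on <- on[i]; keep_off <- off[i]
    }
  }
  data.frame(onset_s = c(res_on, keep_on), offset_s = c(res_off, keep_off))
}

# clip intervals to [start_s, end_s) and shift so start_s maps to 0
clipIntervals <- function(df, start_s, end_s) {
  if (nrow(df) == 0L) return(df)
  on <- pmax(df$onset_s, start_s)
  off <- pmin(df$offset_s, end_s)
  keep <- on < off
  data.frame(onset_s = on[keep] - start_s, offset_s = off[keep] - start_s)
}

# logical: does [a0, a1) overlap any row of df?
anyIntervalOverlap <- function(df, a0, a1) {
  if (nrow(df) == 0L) return(rep(FALSE, length(a0)))
  vapply(seq_along(a0), function(i)
    any(df$onset_s < a1[i] & a0[i] < df$offset_s), logical(1))
}

#' Read and write seizure annotations
#'
#' Annotation sidecar files are UTF-8 CSV with header `onset_s,offset_s`
#' (one interval per row); a JSON array of `{"onset_s":..,"offset_s":..}`
#' objects is accepted as well. Intervals are validated, sorted, and
#' overlapping rows are merged on read.
#'
#' @param path file path.
#' @return `readAnnotations()` returns an annotation `data.frame` (possibly
#'   zero-row); `writeAnnotations()` returns `path` invisibly.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path)
    if (length(x) == 0L) return(seizureIntervals())
    df <- as.data.frame(x)
  } else {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (length(first) == 0L) return(seizureIntervals())
    df <- utils::read.csv(path)
  }
  if (nrow(df) == 0L) return(seizureIntervals())
  if (!all(c("onset_s", "offset_s") %in% names(df)))
    stop("annotation file must have columns onset_s, offset_s")
  if (!is.numeric(df$onset_s) || !is.numeric(df$offset_s))
    stop("annotation columns must be numeric")
  seizureIntervals(df$onset_s, df$offset_s)
}

#' @rdname readAnnotations
#' @param intervals annotation `data.frame` (`onset_s`, `offset_s`).
#' @export
writeAnnotations <- function(intervals, path) {
  validateIntervals(intervals)
  utils::write.csv(intervals[, c("onset_s", "offset_s")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
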