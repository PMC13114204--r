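# Gradient class-activation maps (Grad-CAM) on the multiscale front end.
#
# The target score is the ictal-class logit (pre-softmax); gradients are
# taken with respect to the concatenated output of the multiscale module.
# Channel weights are the global average of the gradient over a (sub-)map;
# the map is the rectified, weighted sum of feature channels. Maps are
# normalized by their maximum (an all-zero map stays zero), since only
# relative attention is meaningful.

# raw rectified CAM over a channels x width feature block
camFromBlock <- function(feat, grad) {
  wts <- rowMeans(grad)                  # global-average gradient per channel
  pmax(colSums(feat * wts), 0)
}

#' Grad-CAM map of one segment
#'
#' @param model a trained (or initialized) `coseizeModel`.
#' @param segment numeric matrix, channels x T.
#' @param targetClass class whose logit is differentiated: `"ictal"`
#'   (default) or `"interictal"`.
#' @return list with the raw non-negative `map` over the concatenated
#'   feature width, plus the cached `feat` and `grad` arrays.
#' @export
gradcamMap <- function(model, segment, targetClass = c("ictal", "interictal")) {
  targetClass <- match.arg(targetClass)
  stopifnot(inherits(model, "coseizeModel"), is.matrix(segment))
  fw <- modelForward(model, segment, training = FALSE)
  dLogits <- matrix(0, 2, 1)
  dLogits[if (targetClass == "ictal") 2 else 1, 1] <- 1
  bw <- modelBackward(model, fw, dLogits)
  feat <- matrix(fw$concat[, , 1], dim(fw$concat)[1])
  grad <- matrix(bw$dConcat[, , 1], dim(bw$dConcat)[1])
  list(map = camFromBlock(feat, grad), feat = feat, grad = grad)
}

normalizeMap <- function(v) if (max(v) > 0) v / max(v) else v

resizeLinear <- function(v, nOut) {
  if (length(v) == 1L) return(rep(v, nOut))
  stats::approx(x = seq(0, 1, length.out = length(v)), y = v,
                xout = seq(0, 1, length.out = nOut))$y
}

#' Branch-wise and fused Grad-CAM heatmaps
#'
#' The concatenated multiscale feature map is split sequentially into three
#' contiguous equal-width blocks (`floor(W/3)`, remainder assigned to the
#' last), one per branch; one Grad-CAM is computed per block, resized to
#' the input sample axis by linear interpolation and max-normalized. The
#' fused map is the pointwise mean of the three resized maps, then
#' max-normalized.
#'
#' @param model a `coseizeModel` whose front end concatenates along time.
#' @param segment numeric matrix, channels x T.
#' @return list of heatmaps (`branch1..3`, `fused`), each a list with
#'   `values` (length T, in \[0, 1\]), `source`, and `binWidthSamples`
#'   (input samples per feature bin before resizing).
#' @export
branchMaps <- function(model, segment) {
  if (model$cfg$mcc$concatAxis != "time")
    stop("branch maps require time-axis concatenation")
  cam <- gradcamMap(model, segment)
  W <- ncol(cam$feat)
  nb <- 3L
  if (W < nb) stop("concatenated feature width ", W, " is too small to split")
  bw <- W %/% nb
  bounds <- c(rep(bw, nb - 1L), W - bw * (nb - 1L))
  T <- ncol(segment)
  off <- 0L
  maps <- vector("list", nb)
  for (b in seq_len(nb)) {
    cols <- (off + 1L):(off + bounds[b])
    raw <- camFromBlock(cam$feat[, cols, drop = FALSE],
                        cam$grad[, cols, drop = FALSE])
    maps[[b]] <- resizeLinear(raw, T)
    off <- off + bounds[b]
  }
  fusedRaw <- Reduce(`+`, maps) / nb
  out <- lapply(seq_len(nb), function(b)
    list(values = normalizeMap(maps[[b]]), source = paste0("branch", b),
         binWidthSamples = T / bounds[b]))
  names(out) <- paste0("branch", seq_len(nb))
  out$fused <- list(values = normalizeMap(fusedRaw), source = "fused",
                    binWidthSamples = NA_real_)
  out
}

#' Write a heatmap as CSV (bin, value)
#'
#' @param hm one heatmap from [branchMaps()].
#' @param path output CSV path.
#' @export
writeHeatmapCSV <- function(hm, path) {
  utils::write.csv(data.frame(bin = seq_along(hm$values), value = hm$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
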