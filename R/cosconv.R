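# Cosine-parameterized convolution kernels.
#
# A kernel of length k is generated from two learnable scalars, an
# amplitude A and an angular frequency omega (radians per sample):
#
#   K_m = A * cos(omega * (m - (k - 1) / 2)),   m = 0, ..., k - 1.
#
# The centring offset makes every kernel center-symmetric, so true
# convolution and cross-correlation coincide, and the learnable parameter
# count per kernel drops from k to 2 (a reduction ratio of (k - 2) / k).
# A and omega are initialized from a standard normal; omega is left
# unconstrained (values beyond pi alias, which training may exploit).

#' Generate the coefficients of a cosine-parameterized kernel
#'
#' @param A amplitude.
#' @param omega angular frequency in radians per sample.
#' @param k kernel length (`>= 1`).
#' @return numeric vector of length `k` with
#'   `K[m + 1] = A * cos(omega * (m - (k - 1) / 2))`. For `k = 1` the
#'   centring offset is 0, so the kernel is `[A]` whatever `omega` is.
#' @examples
#' cosineKernel(1, 0, 9)       # nine ones
#' cosineKernel(2, pi, 3)      # -2, 2, -2
#' @export
cosineKernel <- function(A, omega, k) {
  if (k < 1L) stop("kernel length k must be >= 1")
  stopifnot(is.finite(A), is.finite(omega))
  m <- 0:(k - 1L)
  A * cos(omega * (m - (k - 1) / 2))
}

#' Initialize cosine-kernel parameters
#'
#' Draws `2 * nKernels` independent standard-normal values (one amplitude
#' and one angular frequency per kernel), reproducibly for a given seed.
#'
#' @param nKernels number of kernels.
#' @param seed integer seed.
#' @return `data.frame` with columns `A` and `omega`.
#' @export
initCosineParams <- function(nKernels, seed = 1L) {
  stopifnot(nKernels >= 1L)
  withLocalSeed(seed, {
    z <- stats::rnorm(2L * nKernels)
    data.frame(A = z[seq_len(nKernels)], omega = z[nKernels + seq_len(nKernels)])
  })
}

#' Specification of a cosine convolution layer
#'
#' One independent `(A, omega)` pair per (out-channel, in-channel) slot.
#' Bias is off by default so the learnable count per kernel is exactly 2.
#'
#' @param inChannels,outChannels channel counts (`>= 1`).
#' @param k kernel length.
#' @param useBias add a per-output-channel bias (default `FALSE`).
#' @export
cosineConvSpec <- function(inChannels, outChannels, k, useBias = FALSE) {
  stopifnot(inChannels >= 1L, outChannels >= 1L, k >= 1L)
  structure(list(inChannels = as.integer(inChannels),
                 outChannels = as.integer(outChannels),
                 k = as.integer(k), useBias = isTRUE(useBias)),
            class = "cosineConvSpec")
}

# materialize the (Cout x Cin*k) weight matrix (im2col layout: row block m
# holds channel c at row (m * Cin + c)) from A, Omega matrices (Cout x Cin)
cosineWeightMatrix <- function(A, Omega, k) {
  cm <- (0:(k - 1L)) - (k - 1) / 2
  Cout <- nrow(A); Cin <- ncol(A)
  W <- matrix(0, Cout, Cin * k)
  for (m in seq_len(k))
    W[, ((m - 1L) * Cin + 1L):(m * Cin)] <- A * cos(Omega * cm[m])
  W
}

# gradients of the loss w.r.t. (A, Omega) given dW in the same layout
cosineWeightGrad <- function(dW, A, Omega, k) {
  cm <- (0:(k - 1L)) - (k - 1) / 2
  Cin <- ncol(A)
  dA <- 0 * A; dOmega <- 0 * Omega
  for (m in seq_len(k)) {
    blk <- dW[, ((m - 1L) * Cin + 1L):(m * Cin), drop = FALSE]
    dA <- dA + blk * cos(Omega * cm[m])
    dOmega <- dOmega - blk * A * cm[m] * sin(Omega * cm[m])
  }
  list(A = dA, omega = dOmega)
}

#' Forward pass of a cosine convolution layer
#'
#' Valid padding, stride 1: the output is numerically identical to a
#' standard cross-correlation whose explicit weights are [cosineKernel()]
#' of each (out, in) slot.
#'
#' @param input numeric matrix, in-channels x L.
#' @param spec a [cosineConvSpec()].
#' @param params list with matrices `A` and `omega` (out x in) and
#'   optionally `bias` (length out).
#' @return numeric matrix, out-channels x (L - k + 1).
#' @export
cosineConvForward <- function(input, spec, params) {
  stopifnot(inherits(spec, "cosineConvSpec"), is.matrix(input))
  if (!is.matrix(params$A) || !identical(dim(params$A), dim(params$omega)) ||
      nrow(params$A) != spec$outChannels || ncol(params$A) != spec$inChannels)
    stop("params A/omega must be ", spec$outChannels, " x ", spec$inChannels,
         " matrices")
  if (nrow(input) != spec$inChannels)
    stop("input has ", nrow(input), " channels; spec expects ", spec$inChannels)
  if (ncol(input) < spec$k) stop("input shorter than the kernel")
  W <- cosineWeightMatrix(params$A, params$omega, spec$k)
  X <- array(input, dim = c(nrow(input), ncol(input), 1L))
  Y <- conv1dForward(X, W, if (spec$useBias) params$bias else NULL, spec$k)
  matrix(Y$out, dim(Y$out)[1], dim(Y$out)[2])
}

#' Learnable parameter counts of convolution layers
#'
#' For a cosine layer the count is `2 * inChannels * outChannels` (plus
#' `outChannels` if biased); the standard layer of the same shape needs
#' `k * inChannels * outChannels` (plus bias), so swapping a standard
#' temporal layer for a cosine one saves `(k - 2)` parameters per kernel,
#' a relative reduction of `(k - 2) / k`.
#'
#' @param spec a [cosineConvSpec()].
#' @return integer count.
#' @export
parameterCount <- function(spec) {
  stopifnot(inherits(spec, "cosineConvSpec"))
  2L * spec$inChannels * spec$outChannels +
    if (spec$useBias) spec$outChannels else 0L
}

#' @rdname parameterCount
#' @export
standardParameterCount <- function(spec) {
  stopifnot(inherits(spec, "cosineConvSpec"))
  spec$k * spec$inChannels * spec$outChannels +
    if (spec$useBias) spec$outChannels else 0L
}
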