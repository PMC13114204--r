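# The multiscale cosine convolution (MCC) + heterogeneous two-stream
# (HTSCC) seizure classifier.
#
# Graph: input (C x T) ->
#   MCC: per branch b (kernel length k_b): temporal cosine conv (1 -> F
#   filters, shared across electrodes) -> standard spatial conv collapsing
#   the electrode axis -> batch norm -> ReLU -> dropout -> max pool;
#   branch outputs concatenated along the time axis ->
#   n x HTSCC: shallow stream (one conv, k = 3, no normalization or
#   regularization) and deep stream (conv -> layer norm -> ReLU -> spatial
#   dropout, twice), merged by channel concatenation (streams right-cropped
#   to the common width) ->
#   fully connected hidden layer -> 2-way softmax.
#
# Temporal and HTSCC convolutions use the cosine parameterization by
# default; the spatial convolution inside the MCC is always standard.

#' Configuration of the multiscale convolution front end
#'
#' @param branchKernelLengths kernel length per parallel branch (default
#'   `c(9, 5, 1)`: long kernels catch slow global trends, short ones local
#'   transients, length 1 performs channel mixing).
#' @param filtersPerBranch temporal filters per branch (default 32).
#' @param poolSize max-pooling window (= stride) on the time axis
#'   (default 12, bringing a 4 s window to ~85 output bins per branch).
#' @param dropoutRate element dropout after batch norm (default 0.5).
#' @param concatAxis `"time"` (default) or `"channel"`.
#' @export
mccConfig <- function(branchKernelLengths = c(9L, 5L, 1L),
                      filtersPerBranch = 32L, poolSize = 12L,
                      dropoutRate = 0.5, concatAxis = c("time", "channel")) {
  concatAxis <- match.arg(concatAxis)
  stopifnot(length(branchKernelLengths) >= 1L, all(branchKernelLengths >= 1L),
            filtersPerBranch >= 1L, poolSize >= 1L,
            dropoutRate >= 0, dropoutRate < 1)
  structure(list(branchKernelLengths = as.integer(branchKernelLengths),
                 filtersPerBranch = as.integer(filtersPerBranch),
                 poolSize = as.integer(poolSize),
                 dropoutRate = dropoutRate, concatAxis = concatAxis),
            class = "mccConfig")
}

#' Configuration of one heterogeneous two-stream module
#'
#' @param kernelLength convolution kernel length in both streams (default 3).
#' @param channels output channels of each stream's convolutions (default 32).
#' @param spatialDropoutRate whole-channel dropout rate in the deep stream
#'   (default 0.25).
#' @param merge `"concat_channels"` (default; streams cropped to the common
#'   width) or `"add"` (requires equal stream shapes).
#' @export
htsccConfig <- function(kernelLength = 3L, channels = 32L,
                        spatialDropoutRate = 0.25,
                        merge = c("concat_channels", "add")) {
  merge <- match.arg(merge)
  stopifnot(kernelLength >= 1L, channels >= 1L,
            spatialDropoutRate >= 0, spatialDropoutRate < 1)
  structure(list(kernelLength = as.integer(kernelLength),
                 channels = as.integer(channels),
                 spatialDropoutRate = spatialDropoutRate, merge = merge),
            class = "htsccConfig")
}

#' Full model configuration
#'
#' @param nChannels input EEG channels (default 18).
#' @param T input samples per segment (default 1024).
#' @param mcc an [mccConfig()].
#' @param nHtscc number of stacked two-stream modules (default 2; 0 feeds
#'   the front end straight into the classifier).
#' @param htscc an [htsccConfig()].
#' @param fcHidden hidden units of the classifier (default 64).
#' @param convFamily list with entries `mccTemporal` and `htscc`, each
#'   `"cosine"` or `"standard"`; the MCC spatial convolution is always
#'   standard.
#' @param seed seed for parameter initialization.
#' @export
modelConfig <- function(nChannels = 18L, T = 1024L, mcc = mccConfig(),
                        nHtscc = 2L, htscc = htsccConfig(), fcHidden = 64L,
                        convFamily = list(mccTemporal = "cosine",
                                          htscc = "cosine"),
                        seed = 1L) {
  stopifnot(inherits(mcc, "mccConfig"), inherits(htscc, "htsccConfig"),
            nHtscc >= 0L, fcHidden >= 1L, nChannels >= 1L, T >= 1L,
            convFamily$mccTemporal %in% c("cosine", "standard"),
            convFamily$htscc %in% c("cosine", "standard"))
  structure(list(nChannels = as.integer(nChannels), T = as.integer(T),
                 mcc = mcc, nHtscc = as.integer(nHtscc), htscc = htscc,
                 fcHidden = as.integer(fcHidden), convFamily = convFamily,
                 seed = as.integer(seed)),
            class = "modelConfig")
}

# shape bookkeeping shared by build / count / forward
modelShapes <- function(cfg) {
  F <- cfg$mcc$filtersPerBranch
  ks <- cfg$mcc$branchKernelLengths
  Lb <- cfg$T - ks + 1L
  if (any(Lb < 1L)) stop("segment shorter than a branch kernel")
  Pb <- Lb %/% cfg$mcc$poolSize
  if (any(Pb < 1L)) stop("pooled branch width would be empty")
  if (cfg$mcc$concatAxis == "time") {
    concatC <- F; concatW <- sum(Pb)
  } else {
    concatC <- F * length(ks); concatW <- min(Pb)
  }
  hk <- cfg$htscc$kernelLength
  ch <- cfg$htscc$channels
  widths <- integer(0); inC <- concatC; W <- concatW
  if (cfg$nHtscc > 0L) for (m in seq_len(cfg$nHtscc)) {
    Wsh <- W - hk + 1L
    Wdp <- W - 2L * (hk - 1L)
    if (cfg$htscc$merge == "add") {
      if (Wsh != Wdp) stop("merge = \"add\" requires equal stream shapes; ",
                           "shallow width ", Wsh, " != deep width ", Wdp)
      W <- Wsh; inC <- ch
    } else {
      W <- min(Wsh, Wdp); inC <- 2L * ch
    }
    if (W < 1L) stop("time axis exhausted in two-stream module ", m)
    widths[m] <- W
  }
  list(F = F, ks = ks, Lb = Lb, Pb = Pb, concatC = concatC, concatW = concatW,
       htsccInC = c(concatC, rep(if (cfg$htscc$merge == "add")
         cfg$htscc$channels else 2L * cfg$htscc$channels,
         max(0L, cfg$nHtscc - 1L))),
       htsccW = widths, flatDim = inC * W)
}

initStdConv <- function(Cout, CinK) {
  matrix(stats::rnorm(Cout * CinK, sd = sqrt(2 / CinK)), Cout, CinK)
}

initConvLayer <- function(family, Cin, Cout, k, bias = FALSE) {
  if (family == "cosine") {
    p <- list(A = matrix(stats::rnorm(Cout * Cin), Cout, Cin),
              omega = matrix(stats::rnorm(Cout * Cin), Cout, Cin))
  } else {
    p <- list(W = initStdConv(Cout, Cin * k))
  }
  if (bias) p$bias <- numeric(Cout)
  p
}

convLayerMatrix <- function(layer, k) {
  if (!is.null(layer$A)) cosineWeightMatrix(layer$A, layer$omega, k) else layer$W
}

#' Build the seizure-classification model
#'
#' @param cfg a [modelConfig()].
#' @return a `coseizeModel` list holding the configuration, all learnable
#'   parameters and the batch-norm running statistics.
#' @export
buildModel <- function(cfg) {
  stopifnot(inherits(cfg, "modelConfig"))
  sh <- modelShapes(cfg)
  withLocalSeed(cfg$seed, {
    F <- sh$F; C <- cfg$nChannels
    mcc <- lapply(seq_along(sh$ks), function(b) {
      k <- sh$ks[b]
      list(temporal = initConvLayer(cfg$convFamily$mccTemporal, 1L, F, k),
           spatial = list(W = initStdConv(F, F * C), bias = numeric(F)),
           bn = list(gamma = rep(1, F), beta = numeric(F)))
    })
    hk <- cfg$htscc$kernelLength; ch <- cfg$htscc$channels
    htscc <- if (cfg$nHtscc > 0L) lapply(seq_len(cfg$nHtscc), function(m) {
      Cin <- sh$htsccInC[m]
      list(shallow = initConvLayer(cfg$convFamily$htscc, Cin, ch, hk),
           deep1 = initConvLayer(cfg$convFamily$htscc, Cin, ch, hk),
           ln1 = list(gamma = rep(1, ch), beta = numeric(ch)),
           deep2 = initConvLayer(cfg$convFamily$htscc, ch, ch, hk),
           ln2 = list(gamma = rep(1, ch), beta = numeric(ch)))
    }) else list()
    params <- list(
      mcc = mcc, htscc = htscc,
      fc1 = list(W = initStdConv(cfg$fcHidden, sh$flatDim),
                 b = numeric(cfg$fcHidden)),
      fc2 = list(W = initStdConv(2L, cfg$fcHidden), b = numeric(2)))
    state <- list(bn = lapply(seq_along(sh$ks), function(b)
      list(mean = numeric(F), var = rep(1, F))))
    structure(list(cfg = cfg, shapes = sh, params = params, state = state),
              class = "coseizeModel")
  })
}

#' @export
print.coseizeModel <- function(x, ...) {
  pc <- countParameters(x)
  cat(sprintf("coseize model: %d branches (k = %s), %d two-stream modules, %s trainable parameters\n",
              length(x$cfg$mcc$branchKernelLengths),
              paste(x$cfg$mcc$branchKernelLengths, collapse = "/"),
              x$cfg$nHtscc, format(pc$total, big.mark = ",")))
  invisible(x)
}

# forward through one conv layer (cosine or standard); X: (Cin, L, B)
convLayerForward <- function(X, layer, k) {
  W <- convLayerMatrix(layer, k)
  r <- conv1dForward(X, W, layer$bias, k)
  r$W <- W
  r
}

convLayerBackward <- function(dY, r, X, layer, k, needInputGrad = TRUE) {
  g <- conv1dBackward(dY, r, X, r$W, k, needInputGrad)
  if (!is.null(layer$A)) {
    cg <- cosineWeightGrad(g$dW, layer$A, layer$omega, k)
    out <- list(A = cg$A, omega = cg$omega)
  } else {
    out <- list(W = g$dW)
  }
  if (!is.null(layer$bias)) out$bias <- g$dB
  list(grads = out, dX = g$dX)
}

#' Forward pass
#'
#' @param model a `coseizeModel` from [buildModel()].
#' @param X input array (channels x T x batch) or a single (channels x T)
#'   matrix.
#' @param training logical; enables dropout and batch statistics. In
#'   evaluation mode the forward pass is a pure function of input and
#'   parameters.
#' @return list with `probs` (2 x batch; rows interictal, ictal — columns
#'   sum to 1), `logits`, the MCC `concat` feature map, and `caches` for
#'   the backward pass. The model (with updated batch-norm running
#'   statistics when training) is returned as `$model`.
#' @export
modelForward <- function(model, X, training = FALSE) {
  cfg <- model$cfg; sh <- model$shapes
  if (is.matrix(X)) X <- array(X, dim = c(dim(X), 1L))
  stopifnot(dim(X)[1] == cfg$nChannels, dim(X)[2] == cfg$T)
  B <- dim(X)[3]; C <- cfg$nChannels; F <- sh$F
  caches <- list(mcc = list(), htscc = list())

  branchOuts <- vector("list", length(sh$ks))
  for (b in seq_along(sh$ks)) {
    k <- sh$ks[b]; Lb <- sh$Lb[b]
    p <- model$params$mcc[[b]]
    cc <- list()
    # temporal conv applied per electrode: (1, T, C*B)
    Xp <- aperm(X, c(2, 1, 3)); dim(Xp) <- c(1L, cfg$T, C * B)
    cc$Xp <- Xp
    cc$temporal <- convLayerForward(Xp, p$temporal, k)
    Yt <- cc$temporal$out                       # (F, Lb, C*B)
    cc$temporal$out <- NULL                     # not needed by backward
    dim(Yt) <- c(F, Lb, C, B)
    Yt <- aperm(Yt, c(1, 3, 2, 4))              # (F, C, Lb, B)
    cc$spatialInDim <- dim(Yt)
    cc$spatial <- spatialConvForward(Yt, p$spatial$W, p$spatial$bias)
    rm(Yt)
    cc$bn <- bnForward(cc$spatial$out, p$bn$gamma, p$bn$beta,
                       model$state$bn[[b]], training)
    model$state$bn[[b]] <- cc$bn$running
    cc$relu <- reluForward(cc$bn$out)
    cc$drop <- dropoutForward(cc$relu$out, cfg$mcc$dropoutRate, training)
    cc$pool <- maxPoolForward(cc$drop$out, cfg$mcc$poolSize)
    branchOuts[[b]] <- cc$pool$out              # (F, Pb, B)
    caches$mcc[[b]] <- cc
  }
  if (cfg$mcc$concatAxis == "time") {
    concat <- array(0, dim = c(F, sh$concatW, B))
    off <- 0L
    for (b in seq_along(branchOuts)) {
      w <- sh$Pb[b]
      concat[, (off + 1L):(off + w), ] <- branchOuts[[b]]
      off <- off + w
    }
  } else {
    wmin <- sh$concatW
    concat <- array(0, dim = c(sh$concatC, wmin, B))
    for (b in seq_along(branchOuts))
      concat[((b - 1L) * F + 1L):(b * F), , ] <-
        branchOuts[[b]][, seq_len(wmin), , drop = FALSE]
  }
  caches$concat <- concat

  Z <- concat
  hk <- cfg$htscc$kernelLength; ch <- cfg$htscc$channels
  if (cfg$nHtscc > 0L) for (m in seq_len(cfg$nHtscc)) {
    p <- model$params$htscc[[m]]
    cc <- list(Zin = Z)
    cc$shallow <- convLayerForward(Z, p$shallow, hk)
    cc$shallowRelu <- reluForward(cc$shallow$out)
    cc$deep1 <- convLayerForward(Z, p$deep1, hk)
    cc$ln1 <- lnForward(cc$deep1$out, p$ln1$gamma, p$ln1$beta)
    cc$relu1 <- reluForward(cc$ln1$out)
    cc$sdrop1 <- dropoutForward(cc$relu1$out, cfg$htscc$spatialDropoutRate,
                                training, spatial = TRUE)
    cc$deep2 <- convLayerForward(cc$sdrop1$out, p$deep2, hk)
    cc$ln2 <- lnForward(cc$deep2$out, p$ln2$gamma, p$ln2$beta)
    cc$relu2 <- reluForward(cc$ln2$out)
    cc$sdrop2 <- dropoutForward(cc$relu2$out, cfg$htscc$spatialDropoutRate,
                                training, spatial = TRUE)
    W <- model$shapes$htsccW[m]
    if (cfg$htscc$merge == "add") {
      Z <- cc$shallowRelu$out + cc$sdrop2$out
    } else {
      Z <- array(0, dim = c(2L * ch, W, B))
      Z[seq_len(ch), , ] <- cc$shallowRelu$out[, seq_len(W), , drop = FALSE]
      Z[ch + seq_len(ch), , ] <- cc$sdrop2$out[, seq_len(W), , drop = FALSE]
    }
    cc$shallowW <- dim(cc$shallowRelu$out)[2]
    cc$deepW <- dim(cc$sdrop2$out)[2]
    caches$htscc[[m]] <- cc
  }

  flat <- matrix(Z, sh$flatDim, B)
  caches$flatDims <- dim(Z)
  caches$fc1 <- fcForward(flat, model$params$fc1$W, model$params$fc1$b)
  caches$fc1relu <- reluForward(caches$fc1$out)
  caches$fc2 <- fcForward(caches$fc1relu$out, model$params$fc2$W,
                          model$params$fc2$b)
  logits <- caches$fc2$out
  list(probs = softmaxProbs(logits), logits = logits, concat = concat,
       caches = caches, model = model)
}

# backward pass: returns gradient tree mirroring model$params, plus the
# gradient at the MCC concat map (used by Grad-CAM)
modelBackward <- function(model, fw, dLogits, needInputGrad = FALSE) {
  cfg <- model$cfg; sh <- model$shapes
  caches <- fw$caches
  grads <- list(mcc = list(), htscc = list())

  g2 <- fcBackward(dLogits, caches$fc2, model$params$fc2$W)
  grads$fc2 <- list(W = g2$dW, b = g2$dB)
  d1 <- reluBackward(g2$dX, caches$fc1relu)
  g1 <- fcBackward(d1, caches$fc1, model$params$fc1$W)
  grads$fc1 <- list(W = g1$dW, b = g1$dB)
  dZ <- g1$dX
  dim(dZ) <- caches$flatDims

  hk <- cfg$htscc$kernelLength; ch <- cfg$htscc$channels
  if (cfg$nHtscc > 0L) for (m in rev(seq_len(cfg$nHtscc))) {
    cc <- caches$htscc[[m]]
    p <- model$params$htscc[[m]]
    W <- sh$htsccW[m]
    if (cfg$htscc$merge == "add") {
      dShallow <- dZ; dDeep <- dZ
    } else {
      dShallow <- array(0, dim = c(ch, cc$shallowW, dim(dZ)[3]))
      dShallow[, seq_len(W), ] <- dZ[seq_len(ch), , , drop = FALSE]
      dDeep <- array(0, dim = c(ch, cc$deepW, dim(dZ)[3]))
      dDeep[, seq_len(W), ] <- dZ[ch + seq_len(ch), , , drop = FALSE]
    }
    gm <- list()
    dsh <- reluBackward(dShallow, cc$shallowRelu)
    bsh <- convLayerBackward(dsh, cc$shallow, cc$Zin, p$shallow, hk)
    gm$shallow <- bsh$grads
    dd <- dropoutBackward(dDeep, cc$sdrop2)
    dd <- reluBackward(dd, cc$relu2)
    l2 <- lnBackward(dd, cc$ln2, p$ln2$gamma)
    gm$ln2 <- list(gamma = l2$dgamma, beta = l2$dbeta)
    b2 <- convLayerBackward(l2$dX, cc$deep2, cc$sdrop1$out, p$deep2, hk)
    gm$deep2 <- b2$grads
    dd <- dropoutBackward(b2$dX, cc$sdrop1)
    dd <- reluBackward(dd, cc$relu1)
    l1 <- lnBackward(dd, cc$ln1, p$ln1$gamma)
    gm$ln1 <- list(gamma = l1$dgamma, beta = l1$dbeta)
    b1 <- convLayerBackward(l1$dX, cc$deep1, cc$Zin, p$deep1, hk)
    gm$deep1 <- b1$grads
    grads$htscc[[m]] <- gm
    dZ <- bsh$dX + b1$dX
  }
  dConcat <- dZ

  F <- sh$F; C <- cfg$nChannels
  for (b in seq_along(sh$ks)) {
    cc <- caches$mcc[[b]]
    p <- model$params$mcc[[b]]
    k <- sh$ks[b]; Lb <- sh$Lb[b]
    B <- dim(dConcat)[3]
    if (cfg$mcc$concatAxis == "time") {
      off <- if (b == 1L) 0L else sum(sh$Pb[seq_len(b - 1L)])
      dPool <- dConcat[, (off + 1L):(off + sh$Pb[b]), , drop = FALSE]
    } else {
      dPool <- array(0, dim = c(F, sh$Pb[b], B))
      dPool[, seq_len(sh$concatW), ] <-
        dConcat[((b - 1L) * F + 1L):(b * F), , , drop = FALSE]
    }
    dDrop <- maxPoolBackward(dPool, cc$pool)
    dRelu <- dropoutBackward(dDrop, cc$drop)
    dBnOut <- reluBackward(dRelu, cc$relu)
    bn <- bnBackward(dBnOut, cc$bn, p$bn$gamma)
    gb <- list(bn = list(gamma = bn$dgamma, beta = bn$dbeta))
    sp <- spatialConvBackward(bn$dX, cc$spatial, p$spatial$W,
                              cc$spatialInDim)
    gb$spatial <- list(W = sp$dW, bias = sp$dB)
    dYt <- aperm(sp$dX, c(1, 3, 2, 4))          # back to (F, Lb, C, B)
    dim(dYt) <- c(F, Lb, C * B)
    bt <- convLayerBackward(dYt, cc$temporal, cc$Xp, p$temporal, k,
                            needInputGrad = needInputGrad)
    gb$temporal <- bt$grads
    grads$mcc[[b]] <- gb
  }
  list(grads = grads, dConcat = dConcat)
}

#' Count trainable parameters
#'
#' @param model a `coseizeModel`.
#' @return list with `total` and a `breakdown` data.frame (layer, family,
#'   count). The total always equals the sum of the breakdown.
#' @export
countParameters <- function(model) {
  stopifnot(inherits(model, "coseizeModel"))
  rows <- list()
  add <- function(layer, family, count)
    rows[[length(rows) + 1L]] <<- data.frame(layer = layer, family = family,
                                             count = as.integer(count))
  cfg <- model$cfg
  countConv <- function(l, k) {
    if (!is.null(l$A)) 2L * length(l$A) + length(l$bias)
    else length(l$W) + length(l$bias)
  }
  fam <- function(l) if (!is.null(l$A)) "cosine" else "standard"
  for (b in seq_along(model$params$mcc)) {
    p <- model$params$mcc[[b]]
    add(paste0("mcc", b, ".temporal"), fam(p$temporal),
        countConv(p$temporal))
    add(paste0("mcc", b, ".spatial"), "standard",
        length(p$spatial$W) + length(p$spatial$bias))
    add(paste0("mcc", b, ".bn"), "norm", 2L * length(p$bn$gamma))
  }
  for (m in seq_along(model$params$htscc)) {
    p <- model$params$htscc[[m]]
    add(paste0("htscc", m, ".shallow"), fam(p$shallow), countConv(p$shallow))
    add(paste0("htscc", m, ".deep1"), fam(p$deep1), countConv(p$deep1))
    add(paste0("htscc", m, ".ln1"), "norm", 2L * length(p$ln1$gamma))
    add(paste0("htscc", m, ".deep2"), fam(p$deep2), countConv(p$deep2))
    add(paste0("htscc", m, ".ln2"), "norm", 2L * length(p$ln2$gamma))
  }
  add("fc1", "dense", length(model$params$fc1$W) + length(model$params$fc1$b))
  add("fc2", "dense", length(model$params$fc2$W) + length(model$params$fc2$b))
  breakdown <- do.call(rbind, rows)
  list(total = sum(breakdown$count), breakdown = breakdown)
}

#' Per-segment seizure probabilities
#'
#' Runs the model in evaluation mode over a [SegmentSet-class] and returns
#' the ictal-class softmax score of each segment.
#'
#' @param model a `coseizeModel`.
#' @param segs a [SegmentSet-class].
#' @param batchSize forward batch size (default 64).
#' @return a [ScoreSequence-class] (origin and duration from the segment
#'   set; segments are assumed consecutive).
#' @export
predictScores <- function(model, segs, batchSize = 64L) {
  n <- nSegments(segs)
  out <- numeric(n)
  x <- segData(segs)
  for (i0 in seq(1L, n, by = batchSize)) {
    i1 <- min(n, i0 + batchSize - 1L)
    fw <- modelForward(model, x[, , i0:i1, drop = FALSE], training = FALSE)
    out[i0:i1] <- fw$probs[2L, ]
  }
  ScoreSequence(out, segmentDurationS = segmentDurationS(segs),
                originS = segStarts(segs)[1])
}
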