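# Supervised training: cross-entropy loss, Adam, and a stepped learning
# rate decayed by a fixed factor every 20 epochs with a floor.
#
# The published schedule multiplies by ~0.89125 every 20 epochs from
# 2e-4 and reports a final rate of 2e-5; 0.89125^20 ~= 0.1, so the floor
# clamps the rate at 2e-5 from epoch 400 onward, honouring both printed
# endpoints over a 500-epoch run.

#' Training configuration
#'
#' @param initialLr initial learning rate (default 2e-4).
#' @param decayFactor multiplicative decay (default 0.89125).
#' @param decayEveryEpochs epochs between decays (default 20).
#' @param lrFloor lower clamp on the learning rate (default 2e-5).
#' @param epochs number of epochs (default 500; no early stopping).
#' @param batchSize mini-batch size (default 128).
#' @param shuffleEachEpoch reshuffle sample order every epoch.
#' @param seed RNG seed for shuffling and dropout.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @export
trainConfig <- function(initialLr = 2e-4, decayFactor = 0.89125,
                        decayEveryEpochs = 20L, lrFloor = 2e-5,
                        epochs = 500L, batchSize = 128L,
                        shuffleEachEpoch = TRUE, seed = 1L,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopifnot(decayFactor > 0, decayFactor < 1, lrFloor <= initialLr,
            epochs >= 1L, batchSize >= 1L, decayEveryEpochs >= 1L)
  structure(list(initialLr = initialLr, decayFactor = decayFactor,
                 decayEveryEpochs = as.integer(decayEveryEpochs),
                 lrFloor = lrFloor, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 shuffleEachEpoch = isTRUE(shuffleEachEpoch),
                 seed = as.integer(seed), beta1 = beta1, beta2 = beta2,
                 eps = eps),
            class = "trainConfig")
}

#' Learning rate at a given epoch
#'
#' `max(lrFloor, initialLr * decayFactor^floor(epoch / decayEveryEpochs))`;
#' non-increasing in `epoch` and bounded in `[lrFloor, initialLr]`.
#'
#' @param cfg a [trainConfig()].
#' @param epoch 0-based epoch index.
#' @return learning rate.
#' @examples
#' lrAtEpoch(trainConfig(), 0)    # 2e-4
#' lrAtEpoch(trainConfig(), 400)  # clamped at 2e-5
#' @export
lrAtEpoch <- function(cfg, epoch) {
  stopifnot(epoch >= 0)
  pmax(cfg$lrFloor,
       cfg$initialLr * cfg$decayFactor^floor(epoch / cfg$decayEveryEpochs))
}

# a + w * b over gradient trees (same shape, matched by name/position)
treeAxpy <- function(a, b, w) {
  if (is.list(a)) {
    nms <- names(a)
    for (i in seq_along(a)) {
      bi <- if (!is.null(nms) && nzchar(nms[i])) b[[nms[i]]] else b[[i]]
      a[[i]] <- treeAxpy(a[[i]], bi, w)
    }
    a
  } else a + w * b
}

# recursive Adam update over the parameter tree; gradients are matched to
# parameters by name where names exist, by position otherwise
adamStep <- function(p, g, m, v, lr, cfg, t) {
  if (is.list(p)) {
    nms <- names(p)
    for (i in seq_along(p)) {
      gi <- if (!is.null(nms) && nzchar(nms[i])) g[[nms[i]]] else g[[i]]
      r <- adamStep(p[[i]], gi, m[[i]], v[[i]], lr, cfg, t)
      p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- cfg$beta1 * m + (1 - cfg$beta1) * g
  v <- cfg$beta2 * v + (1 - cfg$beta2) * g^2
  mh <- m / (1 - cfg$beta1^t)
  vh <- v / (1 - cfg$beta2^t)
  list(p = p - lr * mh / (sqrt(vh) + cfg$eps), m = m, v = v)
}

#' Train the model
#'
#' Fixed epoch count (no early stopping); per-epoch mean loss, learning
#' rate and training accuracy are recorded in the history. With a fixed
#' seed the run is fully reproducible on one machine.
#'
#' @param model a `coseizeModel`.
#' @param trainSet a [SegmentSet-class] containing both classes.
#' @param cfg a [trainConfig()].
#' @param verbose print per-epoch progress.
#' @param microBatch forward/backward chunk size for gradient accumulation
#'   (default 32). Each optimizer step still uses the full mini-batch
#'   gradient; smaller chunks only bound peak memory (batch-norm statistics
#'   are computed per chunk).
#' @return list with `model` (trained) and `history` (data.frame epoch,
#'   loss, lr, accuracy).
#' @export
trainModel <- function(model, trainSet, cfg = trainConfig(), verbose = FALSE,
                       microBatch = 32L) {
  stopifnot(inherits(model, "coseizeModel"), inherits(cfg, "trainConfig"))
  y <- segLabels(trainSet)
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes")
  x <- segData(trainSet)
  n <- length(y)
  m <- rapply(model$params, function(z) z * 0, how = "replace")
  v <- m
  t <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0),
                     accuracy = numeric(0))
  withLocalSeed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      lr <- lrAtEpoch(cfg, ep - 1L)
      ord <- if (cfg$shuffleEachEpoch) sample.int(n) else seq_len(n)
      losses <- numeric(0); ncorr <- 0L
      for (i0 in seq(1L, n, by = cfg$batchSize)) {
        idx <- ord[i0:min(n, i0 + cfg$batchSize - 1L)]
        nb <- length(idx)
        acc <- NULL
        batchLoss <- 0
        for (j0 in seq(1L, nb, by = microBatch)) {
          sub <- idx[j0:min(nb, j0 + microBatch - 1L)]
          xb <- x[, , sub, drop = FALSE]
          yb <- y[sub]
          fw <- modelForward(model, xb, training = TRUE)
          model <- fw$model                     # updated BN running stats
          batchLoss <- batchLoss + crossEntropy(fw$probs, yb) * length(sub) / nb
          ncorr <- ncorr + sum((fw$probs[2L, ] > 0.5) == (yb == 1L))
          bw <- modelBackward(model, fw,
                              crossEntropyGrad(fw$probs, yb))
          w <- length(sub) / nb
          acc <- if (is.null(acc)) rapply(bw$grads, function(z) z * w,
                                          how = "replace")
                 else treeAxpy(acc, bw$grads, w)
        }
        losses <- c(losses, batchLoss)
        t <- t + 1L
        r <- adamStep(model$params, acc, m, v, lr, cfg, t)
        model$params <- r$p; m <- r$m; v <- r$v
      }
      hist[ep, ] <- list(ep - 1L, mean(losses), lr, ncorr / n)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  lr %.2e",
                        ep - 1L, mean(losses), ncorr / n, lr))
    }
  })
  list(model = model, history = hist)
}
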