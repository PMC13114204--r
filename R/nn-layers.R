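# Minimal reverse-mode layer engine for the fixed seizure-detection graph.
#
# All heavy operations are expressed as BLAS matrix products over im2col
# unrollings; backward passes are hand-derived per layer. Tensors use the
# layout (channels, time, batch). No general autograd is attempted: the
# model's computational graph is fixed, so explicit caches per layer are
# simpler and faster.

.im2colCache <- new.env(parent = emptyenv())

# linear-index matrix such that col <- matrix(X[idx], Cin*k, Lp*B)
# gives col[(m-1)*Cin + c, (b-1)*Lp + t] = X[c, t+m-1, b]
im2colIndex <- function(Cin, L, B, k) {
  key <- paste(Cin, L, B, k, sep = "x")
  if (!is.null(.im2colCache[[key]])) return(.im2colCache[[key]])
  Lp <- L - k + 1L
  rowPart <- rep(seq_len(Cin), times = k) +
    rep(0:(k - 1L), each = Cin) * Cin            # c + m*Cin
  colPart <- rep((seq_len(Lp) - 1L) * Cin, times = B) +
    rep((seq_len(B) - 1L) * Cin * L, each = Lp)
  idx <- outer(rowPart, colPart, "+")
  if (length(idx) <= 3e7) .im2colCache[[key]] <- idx
  idx
}

# X: (Cin, L, B) array; W: (Cout x Cin*k); bias NULL or length Cout
conv1dForward <- function(X, W, bias, k) {
  d <- dim(X); Cin <- d[1]; L <- d[2]; B <- d[3]
  Lp <- L - k + 1L
  col <- matrix(X[im2colIndex(Cin, L, B, k)], Cin * k, Lp * B)
  Y <- W %*% col
  if (!is.null(bias)) Y <- Y + bias
  dim(Y) <- c(nrow(W), Lp, B)
  list(out = Y, col = col)
}

conv1dBackward <- function(dY, cache, X, W, k, needInputGrad = TRUE) {
  d <- dim(X); Cin <- d[1]; L <- d[2]; B <- d[3]
  Cout <- dim(dY)[1]; Lp <- dim(dY)[2]
  dYmat <- matrix(dY, Cout, Lp * B)
  dW <- tcrossprod(dYmat, cache$col)               # (Cout x Cin*k)
  dB <- rowSums(dYmat)
  dX <- NULL
  if (needInputGrad) {
    dcol <- crossprod(W, dYmat)                    # (Cin*k x Lp*B)
    dim(dcol) <- c(Cin, k, Lp, B)
    dX <- array(0, dim = d)
    for (m in seq_len(k))
      dX[, m:(Lp + m - 1L), ] <- dX[, m:(Lp + m - 1L), , drop = FALSE] +
        array(dcol[, m, , ], dim = c(Cin, Lp, B))
    dim(dX) <- d
  }
  list(dW = dW, dB = dB, dX = dX)
}

# spatial (electrode-collapsing) convolution: consumes (F, C, L, B) as a
# pure matrix product with weights (Cout x F*C)
spatialConvForward <- function(X4, W, bias) {
  d <- dim(X4)                                     # (F, C, L, B)
  Xmat <- matrix(X4, d[1] * d[2], d[3] * d[4])
  Y <- W %*% Xmat + bias
  dim(Y) <- c(nrow(W), d[3], d[4])
  list(out = Y, Xmat = Xmat)
}

spatialConvBackward <- function(dY, cache, W, dIn) {
  dd <- dim(dY)
  dYmat <- matrix(dY, dd[1], dd[2] * dd[3])
  dW <- tcrossprod(dYmat, cache$Xmat)
  dB <- rowSums(dYmat)
  dX <- crossprod(W, dYmat)
  dim(dX) <- dIn                                   # back to (F, C, L, B)
  list(dW = dW, dB = dB, dX = dX)
}

reluForward <- function(X) {
  mask <- X > 0
  list(out = X * mask, mask = mask)
}
reluBackward <- function(dY, cache) dY * cache$mask

# batch normalization per feature channel over (time, batch)
bnForward <- function(X, gamma, beta, running, training,
                      momentum = 0.1, eps = 1e-5) {
  d <- dim(X); C <- d[1]
  Xm <- matrix(X, C)                               # C x (L*B)
  if (training) {
    mu <- rowMeans(Xm)
    v <- rowMeans(Xm^2) - mu^2
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean; v <- running$var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (Xm - mu) * istd
  Y <- gamma * xhat + beta
  dim(Y) <- d
  list(out = Y, xhat = xhat, istd = istd, running = running, dims = d,
       training = training)
}

bnBackward <- function(dY, cache, gamma) {
  d <- cache$dims; C <- d[1]
  dYm <- matrix(dY, C)
  dgamma <- rowSums(dYm * cache$xhat)
  dbeta <- rowSums(dYm)
  dxhat <- dYm * gamma
  dX <- if (cache$training) {
    # batch statistics depend on the input
    cache$istd * (dxhat - rowMeans(dxhat) -
                    cache$xhat * rowMeans(dxhat * cache$xhat))
  } else {
    dxhat * cache$istd          # running statistics are constants
  }
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# layer normalization per sample over (channels, time); affine per channel
lnForward <- function(X, gamma, beta, eps = 1e-5) {
  d <- dim(X); N <- d[1] * d[2]; B <- d[3]
  Xm <- matrix(X, N, B)
  mu <- colMeans(Xm)
  v <- colMeans(Xm^2) - mu^2
  istd <- 1 / sqrt(v + eps)
  xhat <- (Xm - rep(mu, each = N)) * rep(istd, each = N)
  dim(xhat) <- d
  Y <- xhat * gamma + beta                         # gamma, beta: length C, recycled
  list(out = Y, xhat = xhat, istd = istd, dims = d)
}

lnBackward <- function(dY, cache, gamma) {
  d <- cache$dims; N <- d[1] * d[2]; B <- d[3]
  dgamma <- rowSums(matrix(dY * cache$xhat, d[1]))
  dbeta <- rowSums(matrix(dY, d[1]))
  dxhat <- dY * gamma
  dxm <- matrix(dxhat, N, B)
  xh <- matrix(cache$xhat, N, B)
  dX <- rep(cache$istd, each = N) *
    (dxm - rep(colMeans(dxm), each = N) - xh * rep(colMeans(dxm * xh), each = N))
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

dropoutForward <- function(X, rate, training, spatial = FALSE) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  d <- dim(X)
  if (spatial) {                                   # drop whole channels
    m <- matrix(stats::runif(d[1] * d[3]) >= rate, d[1], d[3])
    mask <- aperm(array(m, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  } else {
    mask <- array(stats::runif(length(X)) >= rate, dim = d)
  }
  list(out = X * mask / (1 - rate), mask = mask, rate = rate)
}

dropoutBackward <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask / (1 - cache$rate)
}

maxPoolForward <- function(X, p) {
  d <- dim(X); C <- d[1]; L <- d[2]; B <- d[3]
  L2 <- L %/% p
  if (L2 < 1L) stop("time axis shorter than the pooling window")
  y <- array(X[, seq(1L, by = p, length.out = L2), , drop = FALSE],
             dim = c(C, L2, B))
  arg <- array(1L, dim = c(C, L2, B))
  if (p > 1L) for (j in 2:p) {
    s <- array(X[, seq(j, by = p, length.out = L2), , drop = FALSE],
               dim = c(C, L2, B))
    upd <- s > y
    y[upd] <- s[upd]
    arg[upd] <- j
  }
  list(out = y, arg = arg, dims = d, p = p)
}

maxPoolBackward <- function(dY, cache) {
  d <- cache$dims; C <- d[1]; L <- d[2]; B <- d[3]
  L2 <- dim(dY)[2]; p <- cache$p
  l2 <- rep(rep(seq_len(L2) - 1L, each = C), times = B)
  cidx <- rep(seq_len(C), times = L2 * B)
  bidx <- rep(seq_len(B) - 1L, each = C * L2)
  pos <- cidx + (l2 * p + as.vector(cache$arg) - 1L) * C + bidx * C * L
  dX <- numeric(C * L * B)
  dX[pos] <- as.vector(dY)
  dim(dX) <- d
  dX
}

fcForward <- function(X, W, b) list(out = W %*% X + b, X = X)

fcBackward <- function(dY, cache, W) {
  list(dW = tcrossprod(dY, cache$X), dB = rowSums(dY), dX = crossprod(W, dY))
}

# softmax over 2 classes with cross-entropy; labels are 0/1
softmaxProbs <- function(logits) {
  z <- logits - rep(apply(logits, 2, max), each = nrow(logits))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(logits))
}

crossEntropy <- function(probs, labels) {
  p <- probs[cbind(labels + 1L, seq_along(labels))]
  -mean(log(pmax(p, 1e-12)))
}

crossEntropyGrad <- function(probs, labels) {
  G <- probs
  G[cbind(labels + 1L, seq_along(labels))] <-
    G[cbind(labels + 1L, seq_along(labels))] - 1
  G / length(labels)
}
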