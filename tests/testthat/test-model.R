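test_that("the default front end yields the expected branch geometry", {
  cfg <- modelConfig()
  sh <- coseize:::modelShapes(cfg)
  expect_equal(sh$F, 32L)
  expect_equal(sh$Lb, c(1016L, 1020L, 1024L))
  expect_equal(sh$Pb, c(84L, 85L, 85L))   # ~85 bins per branch after pooling
  model <- buildModel(modelConfig(mcc = mccConfig(filtersPerBranch = 4L),
                                  htscc = htsccConfig(channels = 4L),
                                  fcHidden = 8L))
  expect_s3_class(model, "coseizeModel")
})

test_that("forward produces a probability pair and is deterministic in eval mode", {
  model <- buildModel(tinyModelConfig())
  set.seed(20)
  X <- array(rnorm(4 * 256 * 3), c(4, 256, 3))
  f1 <- modelForward(model, X, training = FALSE)
  f2 <- modelForward(model, X, training = FALSE)
  expect_equal(colSums(f1$probs), rep(1, 3), tolerance = 1e-6)
  expect_identical(f1$probs, f2$probs)
  # training mode with dropout is stochastic
  set.seed(1); g1 <- modelForward(model, X, training = TRUE)$probs
  set.seed(2); g2 <- modelForward(model, X, training = TRUE)$probs
  expect_false(identical(g1, g2))
})

test_that("ablation axes build and run: branch counts, no-HTSCC, merge modes", {
  set.seed(21)
  X <- array(rnorm(4 * 256 * 2), c(4, 256, 2))
  for (nb in 1:5) {
    cfg <- modelConfig(nChannels = 4L, T = 256L,
                       mcc = mccConfig(branchKernelLengths = rep(9L, nb),
                                       filtersPerBranch = 3L, poolSize = 8L),
                       nHtscc = 2L, htscc = htsccConfig(channels = 3L),
                       fcHidden = 8L, seed = nb)
    fw <- modelForward(buildModel(cfg), X)
    expect_equal(dim(fw$probs), c(2L, 2L))
  }
  # no two-stream module: front end feeds the classifier directly
  cfg0 <- tinyModelConfig(); cfg0$nHtscc <- 0L
  fw0 <- modelForward(buildModel(cfg0), X)
  expect_equal(colSums(fw0$probs), rep(1, 2), tolerance = 1e-6)
  # merge = "add" requires equal stream shapes (valid padding makes them differ)
  expect_error(buildModel(modelConfig(nChannels = 4L, T = 256L,
                                      htscc = htsccConfig(merge = "add"))),
               "equal stream shapes")
})

test_that("single-branch concat is the identity on that branch's output", {
  cfg <- modelConfig(nChannels = 3L, T = 128L,
                     mcc = mccConfig(branchKernelLengths = 9L,
                                     filtersPerBranch = 3L, poolSize = 4L),
                     nHtscc = 0L, fcHidden = 4L, seed = 2)
  model <- buildModel(cfg)
  set.seed(3)
  X <- array(rnorm(3 * 128), c(3, 128, 1))
  fw <- modelForward(model, X)
  expect_equal(dim(fw$concat), c(3L, (128L - 9L + 1L) %/% 4L, 1L))
})

test_that("parameter totals equal the breakdown sum and follow the swap law", {
  set.seed(22)
  for (i in 1:20) {
    nb <- sample(1:3, 1)
    ks <- sample(c(1L, 3L, 5L, 9L, 13L), nb, replace = TRUE)
    nc <- sample(2:6, 1); Fb <- sample(2:5, 1); nh <- sample(0:2, 1)
    chh <- sample(2:5, 1); fch <- sample(4:10, 1)
    cfg <- function(famT, famH)
      modelConfig(nChannels = nc, T = 256L,
                  mcc = mccConfig(branchKernelLengths = ks,
                                  filtersPerBranch = Fb,
                                  poolSize = 8L),
                  nHtscc = nh,
                  htscc = htsccConfig(kernelLength = 3L,
                                      channels = chh),
                  fcHidden = fch,
                  convFamily = list(mccTemporal = famT, htscc = famH),
                  seed = i)
    base <- cfg("cosine", "cosine")
    mcos <- buildModel(base)
    mstd <- buildModel(cfg("standard", "standard"))
    pcCos <- countParameters(mcos)
    pcStd <- countParameters(mstd)
    expect_equal(pcCos$total, sum(pcCos$breakdown$count))
    # family-swap law: difference = sum over swapped layers of (k-2)*slots
    F <- base$mcc$filtersPerBranch; ch <- base$htscc$channels
    slotsT <- sum((ks - 2L) * F * 1L)
    inC <- c(2L * ch, 2L * ch)[seq_len(max(0, base$nHtscc - 1))]
    htIn <- c(F, inC)[seq_len(base$nHtscc)]
    slotsH <- if (base$nHtscc > 0)
      sum((3L - 2L) * (htIn * ch + htIn * ch + ch * ch)) else 0L
    expect_equal(pcStd$total - pcCos$total, slotsT + slotsH)
  }
})

test_that("swapping one layer family changes only that layer's count", {
  mkCfg <- function(fam)
    modelConfig(nChannels = 3L, T = 128L,
                mcc = mccConfig(branchKernelLengths = c(9L, 5L),
                                filtersPerBranch = 3L, poolSize = 4L),
                nHtscc = 1L, htscc = htsccConfig(channels = 3L),
                fcHidden = 4L,
                convFamily = list(mccTemporal = fam, htscc = "cosine"),
                seed = 1)
  bCos <- countParameters(buildModel(mkCfg("cosine")))$breakdown
  bStd <- countParameters(buildModel(mkCfg("standard")))$breakdown
  diffRows <- which(bCos$count != bStd$count)
  expect_equal(bCos$layer[diffRows], c("mcc1.temporal", "mcc2.temporal"))
  # per layer: k*slots vs 2*slots
  expect_equal(bStd$count[diffRows] / c(9, 5) * 2, bCos$count[diffRows])
})

test_that("a lone cosine kernel registers exactly two parameters", {
  cfg <- modelConfig(nChannels = 1L, T = 32L,
                     mcc = mccConfig(branchKernelLengths = 9L,
                                     filtersPerBranch = 1L, poolSize = 2L),
                     nHtscc = 0L, fcHidden = 1L, seed = 1)
  bd <- countParameters(buildModel(cfg))$breakdown
  expect_equal(bd$count[bd$layer == "mcc1.temporal"], 2L)
})

test_that("permuting branch order preserves the parameter count", {
  mk <- function(ks) countParameters(buildModel(
    modelConfig(nChannels = 3L, T = 128L,
                mcc = mccConfig(branchKernelLengths = ks,
                                filtersPerBranch = 3L, poolSize = 4L),
                nHtscc = 1L, htscc = htsccConfig(channels = 3L),
                fcHidden = 4L, seed = 1)))$total
  expect_equal(mk(c(9L, 5L, 1L)), mk(c(1L, 9L, 5L)))
})
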