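# Shared fixtures. Everything is generated in code; the expensive
# end-to-end synthetic-patient run is trained once per session and reused
# by the end-to-end, interpretability and acceptance tests.

.shared <- new.env(parent = emptyenv())

# small model configuration used by unit tests (fast to train on CPU)
tinyModelConfig <- function(nChannels = 4L, T = 256L, seed = 3L) {
  modelConfig(nChannels = nChannels, T = T,
              mcc = mccConfig(branchKernelLengths = c(9L, 5L, 1L),
                              filtersPerBranch = 4L, poolSize = 8L),
              nHtscc = 2L, htscc = htsccConfig(channels = 4L),
              fcHidden = 8L, seed = seed)
}

# a small, easily separable training task: spike-wave segments at high
# gain vs pure background
separableSegments <- function(nPerClass = 100L, nChannels = 6L, T = 512L,
                              fs = 256, gain = 8, seed = 42L) {
  arr <- array(0, dim = c(nChannels, T, 2L * nPerClass))
  tpl <- makeTemplate("spike_wave", T / fs, fs)
  for (i in seq_len(2L * nPerClass)) {
    cfg <- synthConfig(durationS = T / fs, nChannels = nChannels, fs = fs,
                       seed = seed + i)
    x <- recData(generateRecording(cfg))
    if (i > nPerClass) x <- x + 20 * gain * rep(tpl, each = nChannels)
    arr[, , i] <- x
  }
  SegmentSet(arr, rep(c(0L, 1L), each = nPerClass),
             seq(0, by = T / fs, length.out = 2L * nPerClass), fs)
}

# desk-scale configuration of the full pipeline study conditions
deskModelConfig <- function(seed = 5L) {
  modelConfig(nChannels = 18L, T = 1024L,
              mcc = mccConfig(filtersPerBranch = 16L),
              htscc = htsccConfig(channels = 16L), seed = seed)
}

deskTrainConfig <- function() trainConfig(epochs = 12L, seed = 7L)

# end-to-end run on the reference synthetic patient (cached)
getSyntheticRun <- function() {
  if (!is.null(.shared$run)) return(.shared$run)
  rec <- generateRecording(syntheticPatientConfig(gain = 6, seed = 11L))
  .shared$run <- runPatient(rec, splitPlan(1:2), deskModelConfig(),
                            deskTrainConfig())
  .shared$run
}

# brute-force interval overlap: does [a0, a1) intersect any truth row?
bruteOverlap <- function(df, a0, a1) {
  if (nrow(df) == 0L) return(rep(FALSE, length(a0)))
  sapply(seq_along(a0), function(i)
    any(a0[i] < df$offset_s & df$onset_s < a1[i]))
}

randomIntervals <- function(n, tMax = 1000, maxLen = 30) {
  on <- runif(n, 0, tMax)
  data.frame(onset_s = on, offset_s = on + runif(n, 0.1, maxLen))
}
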