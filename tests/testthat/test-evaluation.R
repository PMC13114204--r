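test_that("segment metrics reproduce confusion-matrix arithmetic", {
  perfect <- segmentMetrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(perfect), c(sensitivity = 100, specificity = 100,
                                  accuracy = 100))
  half <- segmentMetrics(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(half), c(sensitivity = 50, specificity = 50,
                               accuracy = 50))
  expect_true(is.na(segmentMetrics(c(0, 1), c(0, 0))$sensitivity))
  expect_error(segmentMetrics(c(0, 1), c(0)), "equal length")
  set.seed(40)
  for (rep in 1:20) {
    p <- rbinom(100, 1, 0.4); t <- rbinom(100, 1, 0.3)
    m <- segmentMetrics(p, t)
    tp <- sum(p & t); tn <- sum(!p & !t); fp <- sum(p & !t); fn <- sum(!p & t)
    expect_equal(m$sensitivity, 100 * tp / (tp + fn))
    expect_equal(m$specificity, 100 * tn / (tn + fp))
    expect_equal(m$accuracy, 100 * (tp + tn) / 100)
  }
})

test_that("event metrics follow the any-overlap rule", {
  truth <- data.frame(onset_s = c(10, 50), offset_s = c(20, 60))
  exact <- eventMetrics(truth, truth, testHours = 1)
  expect_equal(exact$eventSensitivity, 100)
  expect_equal(exact$fdrPerHour, 0)
  # one long prediction over two seizures: both detected, none false
  span <- data.frame(onset_s = 5, offset_s = 65)
  m <- eventMetrics(span, truth, testHours = 2)
  expect_equal(m$detected, 2L)
  expect_equal(m$falseEvents, 0L)
  # multiple predictions on one seizure count once
  multi <- data.frame(onset_s = c(10, 15), offset_s = c(12, 18))
  expect_equal(eventMetrics(multi, truth, 1)$detected, 1L)
  # random interval sets vs a brute-force pairwise-overlap oracle
  set.seed(41)
  for (rep in 1:200) {
    pred <- randomIntervals(sample(0:8, 1))
    tru <- randomIntervals(sample(1:6, 1))
    m <- eventMetrics(pred, tru, testHours = 0.5)
    det <- sum(vapply(seq_len(nrow(tru)), function(i)
      any(pred$onset_s < tru$offset_s[i] & tru$onset_s[i] < pred$offset_s),
      logical(1)))
    fals <- sum(vapply(seq_len(nrow(pred)), function(j)
      !any(tru$onset_s < pred$offset_s[j] & pred$onset_s[j] < tru$offset_s),
      logical(1)))
    expect_equal(m$detected, det)
    expect_equal(m$fdrPerHour, fals / 0.5)
    expect_lte(m$detected, m$marked)
  }
})

test_that("event metrics are monotone under added predictions", {
  set.seed(42)
  tru <- randomIntervals(4)
  pred <- randomIntervals(3)
  base <- eventMetrics(pred, tru, 1)
  more <- eventMetrics(rbind(pred, randomIntervals(3)), tru, 1)
  expect_gte(more$detected, base$detected)
})

test_that("fixed-window AUROC hits the analytic extremes and the null", {
  # positives at the sequence end; scores high over exactly the dilated
  # span, so the smoothed scores separate the collared classes perfectly
  n <- 200
  truth <- integer(n); truth[151:200] <- 1L
  sc <- as.numeric(seq_len(n) >= 145)
  expect_equal(aurocFixedPostproc(sc, truth), 1)
  expect_equal(aurocFixedPostproc(1 - sc, truth), 0)
  expect_error(aurocFixedPostproc(sc, rep(1L, n)), "one class")
  # permutation null: labels independent of scores average to chance
  set.seed(43)
  scorePerm <- runif(2000)
  vals <- replicate(10, {
    lab <- integer(2000); lab[sample(2000, 100)] <- 1L
    aurocFixedPostproc(scorePerm, lab)
  })
  expect_equal(mean(vals), 0.5, tolerance = 0.05)
})

test_that("the rank AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  score <- runif(300)
  lab <- rbinom(300, 1, 0.3)
  ours <- coseize:::aurocRank(score, lab)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, score, direction = "<",
                                        quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
  # invariant under strictly monotone transforms
  expect_equal(coseize:::aurocRank(qlogis(score * 0.98 + 0.01), lab), ours)
})

test_that("macro averages and pooled ratios reproduce published summary rows", {
  bench <- read.csv(system.file("extdata", "benchmark_chbmit_segment.csv",
                                package = "coseize"))
  m <- macroAverage(bench$sensitivity)
  expect_equal(round(m$mean, 2), 97.98)
  expect_equal(round(m$sd, 2), 4.60)
  s <- macroAverage(bench$specificity)
  expect_equal(round(s$mean, 2), 98.53)
  expect_equal(round(s$sd, 2), 2.01)
  ev <- read.csv(system.file("extdata", "benchmark_chbmit_event.csv",
                             package = "coseize"))
  expect_equal(sum(ev$marked), 144L)
  expect_equal(sum(ev$detected), 142L)
  expect_equal(round(pooledEventSensitivity(ev$detected, ev$marked), 2), 98.61)
  seg10 <- read.csv(system.file("extdata", "benchmark_shsdu_segment.csv",
                                package = "coseize"))
  expect_equal(round(macroAverage(seg10$sensitivity)$mean, 2), 88.09)
  # degenerate cases
  expect_equal(macroAverage(5)$sd, 0)
  expect_equal(pooledEventSensitivity(c(2, 3), c(2, 3)), 100)
  set.seed(45)
  d <- rbinom(10, 5, 0.8); k <- d + rbinom(10, 2, 0.5)
  expect_equal(pooledEventSensitivity(d, k), 100 * sum(d) / sum(k))
})
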