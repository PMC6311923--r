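test_that("length bins tile the range and assignment follows the boundary rule", {
  b <- lengthBins(200)
  expect_equal(b$target, c(400L, 600L, 800L))
  expect_equal(b$low, c(200L, 400L, 600L))
  expect_equal(nrow(lengthBins(100)), 6L)
  expect_error(lengthBins(250), "must divide")

  asg <- assignLengthBins(c(200L, 400L, 401L, 800L), 200L)
  expect_equal(asg$binOf, c(1L, 1L, 2L, 3L))   # low < L <= high; min closed
  expect_error(assignLengthBins(c(300L, 900L), 200L), "outside")
})

test_that("extension reaches the target, contains the origin, stays in bounds", {
  g <- toyGenome(2000L)
  iv <- gr("chr1", 500, 799, "positive")      # 300 bp
  ext <- extendToTarget(iv, 400L, g, splitPolicy = "centered")
  expect_equal(GenomicRanges::width(ext), 400L)
  expect_equal(GenomicRanges::start(ext), 450L)   # 50 bp each side
  expect_lte(GenomicRanges::start(ext), 500L)
  expect_gte(GenomicRanges::end(ext), 799L)
  # already at target -> identity
  same <- extendToTarget(gr("chr1", 101, 500), 400L, g)
  expect_equal(GenomicRanges::start(same), 101L)
  # random splits are deterministic given the seed
  r1 <- extendToTarget(iv, 400L, g, seed = 5)
  r2 <- extendToTarget(iv, 400L, g, seed = 5)
  expect_identical(GenomicRanges::start(r1), GenomicRanges::start(r2))
  # interval at chromosome start pads rightward only
  edge <- extendToTarget(gr("chr1", 1, 300), 400L, g)
  expect_equal(GenomicRanges::start(edge), 1L)
  expect_error(extendToTarget(gr("chr1", 1, 300), 3000L, g), "too short")
})

test_that("extension containment holds over random draws (property)", {
  g <- toyGenome(5000L)
  set.seed(17)
  for (i in 1:20) {
    len <- sample(200:390, 1)
    s <- sample(4000, 1)
    iv <- gr("chr1", s, s + len - 1L)
    ext <- extendToTarget(iv, 400L, g, seed = i)
    expect_equal(GenomicRanges::width(ext), 400L)
    expect_lte(GenomicRanges::start(ext), s)
    expect_gte(GenomicRanges::end(ext), s + len - 1L)
    expect_gte(GenomicRanges::start(ext), 1L)
    expect_lte(GenomicRanges::end(ext), 5000L)
  }
})

test_that("amplification enumerates distinct padding splits", {
  g <- toyGenome(2000L)
  iv <- gr("chr1", 801, 1100, "positive")     # 300 bp, roomy flanks
  v <- amplifyInterval(iv, 400L, 3L, g)
  expect_length(v, 3L)
  expect_equal(GenomicRanges::start(v), c(801L, 751L, 701L))
  expect_true(all(GenomicRanges::width(v) == 400L))
  # nVariants = 1 behaves like plain extension
  v1 <- amplifyInterval(iv, 400L, 1L, g)
  expect_length(v1, 1L)
  # cramped flanks yield fewer variants with a warning
  edge <- gr("chr1", 1, 300)
  expect_warning(ve <- amplifyInterval(edge, 400L, 5L, g), "distinct padding")
  expect_lt(length(ve), 5L)
  expect_true(all(GenomicRanges::start(ve) >= 1L))
})

test_that("multi-scale datasets are per-bin fixed-length with ~1:1 classes", {
  fx <- generateFixture(smallFixtureSpec())
  corpus <- buildCorpus(fx$genome, fx$positives, fx$excluded, seed = 2, k = 3,
                        identityThreshold = NULL)
  all <- c(corpus$positives, corpus$negatives)
  msd <- buildMultiScaleDataset(fx$genome, all, intervalWidth = 200L, seed = 2)
  expect_s4_class(msd, "MultiScaleDataset")
  for (b in seq_len(nrow(msd@bins))) {
    a <- msd@samples[[b]]
    y <- msd@labels[[b]]
    expect_equal(dim(a)[2], msd@bins$target[b])
    expect_equal(dim(a)[3], length(y))
    if (length(y) >= 20) {      # ratio check only where counts are stable
      ratio <- sum(y == 1) / sum(y == 0)
      expect_gt(ratio, 0.9); expect_lt(ratio, 1.11)
    }
    if (length(y))   # every encoded position is a unit row
      expect_true(all(abs(apply(a, c(2, 3), sum) - 1) < 1e-12))
  }
})

test_that("amplified datasets contain the requested number of variants", {
  g <- toyGenome(20000L)
  iv <- c(gr("chr1", 5001, 5300, "positive"), gr("chr1", 9001, 9300, "negative"))
  msd <- buildMultiScaleDataset(g, iv, intervalWidth = 200L,
                                amplification = 3L, seed = 1)
  expect_equal(length(msd@labels[[1]]), 6L)
  expect_equal(sum(msd@labels[[1]]), 3L)
})

test_that("the training schedule cycles bins in ascending target order", {
  g <- toyGenome(20000L)
  set.seed(30)
  starts <- seq(1000L, 16000L, by = 1500L)
  lens <- rep(c(250L, 450L, 650L), length.out = length(starts))
  iv <- gr("chr1", starts, starts + lens - 1L,
           rep(c("positive", "negative"), length.out = length(starts)))
  msd <- buildMultiScaleDataset(g, iv, intervalWidth = 200L, seed = 3)
  m <- buildModel(modelConfig(stageChannels = c(8L, 8L, 8L, 8L, 8L),
                              fcWidths = c(12L, 8L)), seed = 1)
  tc <- trainConfig(iterations = 2L, batchSize = 4L, seed = 11L)
  tr <- trainModel(m, msd, tc)
  expect_equal(tr$history$binTarget, rep(c(400, 600, 800), 2))
  expect_equal(tr$history$epoch, 1:6)
  # learning rate decays exponentially per epoch
  expect_equal(tr$history$lr, 0.002 * 0.97^(0:5))
  # reproducibility: identical seed, identical history and parameters
  tr2 <- trainModel(m, msd, tc)
  expect_identical(tr$history, tr2$history)
  expect_identical(tr$model@params, tr2$model@params)
  # parameter dimensionality unchanged by bin switching
  expect_identical(countParameters(tr$model), countParameters(m))
})

test_that("training skips empty bins with a warning", {
  g <- toyGenome(20000L)
  iv <- gr("chr1", c(1000L, 3000L), c(1249L, 3249L),
           c("positive", "negative"))
  msd <- buildMultiScaleDataset(g, iv, intervalWidth = 200L, seed = 1)
  m <- buildModel(modelConfig(stageChannels = c(8L, 8L, 8L, 8L, 8L),
                              fcWidths = c(12L, 8L)), seed = 1)
  w <- capture_warnings(
    tr <- trainModel(m, msd, trainConfig(iterations = 1L, batchSize = 2L)))
  expect_length(w, 2L)                       # 600 and 800 bp bins are empty
  expect_match(w, "empty bin", all = TRUE)
  expect_equal(tr$history$binTarget, 400)
})
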