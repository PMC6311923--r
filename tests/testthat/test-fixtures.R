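test_that("fixtures plant the motif in every positive, deterministically", {
  spec <- smallFixtureSpec()
  fx <- generateFixture(spec)
  expect_length(fx$positives, 60L)
  # non-overlapping
  expect_true(all(GenomicRanges::countOverlaps(fx$positives,
                                               fx$positives) == 1L))
  # every positive contains at least one exact motif copy
  frags <- extractFragments(fx$genome, fx$positives)
  expect_true(all(grepl(spec@motif, frags, fixed = TRUE)))
  # byte-identical regeneration under the same seed
  fx2 <- generateFixture(spec)
  expect_identical(as.character(fx$genome), as.character(fx2$genome))
  expect_identical(GenomicRanges::start(fx$positives),
                   GenomicRanges::start(fx2$positives))
})

test_that("fixture files are written with provenance", {
  dir <- tempfile()
  fx <- generateFixture(smallFixtureSpec(nPositives = 10L), dir = dir)
  expect_true(file.exists(file.path(dir, "genome.fa")))
  g <- readGenome(file.path(dir, "genome.fa"))
  expect_identical(as.character(g), as.character(fx$genome))
  pos <- readBedIntervals(file.path(dir, "positives.bed"), "positive")
  expect_identical(GenomicRanges::start(pos),
                   GenomicRanges::start(fx$positives))
  meta <- jsonlite::read_json(file.path(dir, "fixture.json"))
  expect_equal(meta$motif, "GATTACGC")
  expect_equal(meta$seed, 7L)
})

test_that("fragment lengths follow the decreasing length distribution", {
  spec <- fixtureSpec(nChromosomes = 2L, chromLength = 1500000L,
                      nPositives = 2000L, seed = 3L)
  fx <- generateFixture(spec)
  lens <- GenomicRanges::width(fx$positives)
  probs <- DHScan:::.length_probs(spec)
  # chi-squared goodness of fit over coarse bins
  brk <- seq(200L, 800L, by = 100L)
  obs <- table(cut(lens, brk, include.lowest = TRUE))
  lensAll <- spec@minLen:spec@maxLen
  expProb <- vapply(seq_len(length(brk) - 1L), function(i) {
    lo <- brk[i]; hi <- brk[i + 1L]
    inBin <- if (i == 1L) lensAll >= lo & lensAll <= hi
             else lensAll > lo & lensAll <= hi
    sum(probs[inBin])
  }, numeric(1))
  p <- stats::chisq.test(as.numeric(obs), p = expProb)$p.value
  expect_gt(p, 0.01)
  # monotone decreasing histogram across the coarse bins
  expect_true(all(diff(as.numeric(obs)) < 0))
})

test_that("difficulty summary matches the closed-form chance-hit rate", {
  spec <- smallFixtureSpec()
  d <- fixtureDifficulty(spec, fragmentLength = 400L)
  expect_equal(d$chanceHitRate, 1 - (1 - 4^-8)^393)
  expect_equal(d$informationBits, 16)   # 8-mer, uniform background
  # motif matching an enriched background is likelier by chance
  richA <- fixtureSpec(motif = "AAAAAAAA",
                       background = c(0.7, 0.1, 0.1, 0.1))
  expect_gt(fixtureDifficulty(richA, 400L)$chanceHitRate,
            fixtureDifficulty(spec, 400L)$chanceHitRate)
  expect_error(fixtureDifficulty(spec, fragmentLength = 4L), "shorter")
})

test_that("the trivial motif-matching classifier separates the fixture", {
  fx <- generateFixture(smallFixtureSpec(seed = 8L))
  corpus <- buildCorpus(fx$genome, fx$positives, fx$excluded, seed = 8,
                        k = 3, identityThreshold = NULL)
  all <- c(corpus$positives, corpus$negatives)
  frags <- extractFragments(fx$genome, all)
  y <- as.integer(S4Vectors::mcols(all)$label == "positive")
  auc <- rocAuc(motifMatchScore(frags, "GATTACGC"), y)
  expect_gte(auc, 0.99)
  # negatives carry the motif only at roughly the background chance rate
  negHit <- mean(motifMatchScore(frags[y == 0], "GATTACGC"))
  lens <- GenomicRanges::width(corpus$negatives)
  expRate <- mean(1 - (1 - 4^-8)^(lens - 7))
  expect_lt(abs(negHit - expRate),
            3 * sqrt(expRate * (1 - expRate) / sum(y == 0)) + 0.01)
})

test_that("fixture specs validate their fields", {
  expect_error(fixtureSpec(motif = "ACGTX"), "A/C/G/T")
  expect_error(fixtureSpec(motif = strrep("A", 300)), "shorter than")
  expect_error(fixtureSpec(background = c(0.5, 0.5, 0.5, 0.5)), "summing to 1")
  expect_error(fixtureSpec(maxLen = 100L), "minLen")
})
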