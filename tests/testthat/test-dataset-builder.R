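test_that("length filtering keeps the inclusive 200-800 window", {
  iv <- gr("chr1", c(1, 1, 1, 1, 1), c(150, 200, 500, 800, 801))
  kept <- filterByLength(iv)
  expect_equal(GenomicRanges::width(kept), c(200L, 500L, 800L))
  # all in range -> identity
  expect_length(filterByLength(gr("chr1", 1:3, 300:302)), 3L)
})

test_that("length filtering retains ~600/800 of lengths uniform on 100-900", {
  set.seed(13)
  lens <- sample(100:900, 4000, replace = TRUE)
  iv <- gr("chr1", rep(1L, 4000), lens)
  frac <- length(filterByLength(iv)) / 4000
  expect_equal(frac, 601 / 801, tolerance = 0.05)
})

test_that("negative sampling matches lengths and avoids excluded regions", {
  g <- toyGenome(20000L)
  set.seed(3)
  pos <- gr("chr1", c(1000, 5000, 9000), c(1299, 5599, 9799), "positive")
  neg <- sampleNegatives(g, pos, seed = 42)
  expect_length(neg, 3L)
  # identical length multiset, same chromosomes
  expect_identical(sort(GenomicRanges::width(neg)),
                   sort(GenomicRanges::width(pos)))
  expect_equal(as.character(GenomicRanges::seqnames(neg)),
               as.character(GenomicRanges::seqnames(pos)))
  expect_true(all(GenomicRanges::countOverlaps(neg, pos) == 0L))
  # mutually non-overlapping
  expect_true(all(GenomicRanges::countOverlaps(neg, neg) == 1L))
  # deterministic given seed
  neg2 <- sampleNegatives(g, pos, seed = 42)
  expect_identical(GenomicRanges::start(neg), GenomicRanges::start(neg2))
})

test_that("negative sampling fails loudly on a fully covered chromosome", {
  g <- Biostrings::DNAStringSet(c(chr1 = randomSeq(400, seed = 2)))
  pos <- gr("chr1", 1, 400, "positive")
  expect_error(sampleNegatives(g, pos, maxAttempts = 50L),
               "no disjoint placement")
})

test_that("redundancy removal drops duplicates and keeps dissimilar sets", {
  a <- randomSeq(200, seed = 31)
  b <- randomSeq(200, seed = 32)
  expect_equal(removeRedundant(c(a, a)), c(TRUE, FALSE))
  expect_equal(removeRedundant(c(a, b)), c(TRUE, TRUE))
  # near-identical (3 mismatches in 200) is dropped at 0.9
  a2 <- a
  substr(a2, 50, 50) <- "A"; substr(a2, 120, 120) <- "C"
  expect_equal(sum(removeRedundant(c(a, a2), 0.9)), 1L)
})

test_that("redundancy removal agrees with brute force on a mixed corpus", {
  set.seed(33)
  seqs <- vapply(1:10, function(i) randomSeq(200), character(1))
  withDups <- c(seqs, seqs[c(2, 5, 9)])
  keep <- removeRedundant(withDups, 0.9)
  expect_equal(sum(keep), 10L)
  # brute-force check: kept set has no pair above threshold
  kept <- withDups[keep]
  codes <- lapply(kept, DHScan:::.seq_codes)
  for (i in seq_along(kept)) for (j in seq_len(i - 1L)) {
    best <- max(vapply(-40:40, function(off)
      DHScan:::.offset_identity(codes[[i]], codes[[j]], off), numeric(1)))
    expect_lt(best, 0.9)
  }
})

test_that("redundancy removal is idempotent", {
  set.seed(34)
  seqs <- c(vapply(1:8, function(i) randomSeq(150), character(1)))
  seqs <- c(seqs, seqs[3], seqs[7])
  kept1 <- seqs[removeRedundant(seqs)]
  kept2 <- kept1[removeRedundant(kept1)]
  expect_identical(kept1, kept2)
})

test_that("corpus statistics report counts, ratio and composition", {
  g <- toyGenome(5000L)
  pos <- gr("chr1", seq(1, 901, by = 100), seq(50, 950, by = 100), "positive")
  neg <- gr("chr2", seq(1, 701, by = 100), seq(50, 750, by = 100), "negative")
  st <- corpusStats(pos, neg, g)
  expect_equal(st@nPositive, 10L)
  expect_equal(st@nNegative, 8L)
  expect_equal(st@ratio, 1.25)
  expect_equal(sum(st@lengthHistogram), 18L)
  expect_equal(sum(st@monoFreq["positive", ]), 1)
  # an all-A corpus has mononucleotide frequency A = 1
  gA <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 100)))
  stA <- corpusStats(gr("chr1", 1, 50, "positive"),
                     gr("chr1", 51, 100, "negative"), gA)
  expect_equal(unname(stA@monoFreq["positive", "A"]), 1)
})

test_that("fold assignment is stratified, balanced and seeded", {
  lab <- rep(c("positive", "negative"), each = 25)
  f <- makeFolds(lab, k = 5, seed = 9)
  sz <- tabulate(f@foldOf, 5)
  expect_equal(sz, rep(10L, 5))
  # per-fold class balance within +/- 1
  for (i in 1:5) {
    inFold <- lab[f@foldOf == i]
    expect_lte(abs(sum(inFold == "positive") - sum(inFold == "negative")), 1L)
  }
  # n = 11, k = 5 -> sizes {3,2,2,2,2}
  f2 <- makeFolds(rep("positive", 11), k = 5, seed = 1)
  expect_equal(sort(tabulate(f2@foldOf, 5), decreasing = TRUE),
               c(3L, 2L, 2L, 2L, 2L))
  expect_identical(makeFolds(lab, 5, 7)@foldOf, makeFolds(lab, 5, 7)@foldOf)
  expect_error(makeFolds(rep("positive", 3), k = 5), "exceeds sample count")
})

test_that("corpus construction asserts its invariants and is reproducible", {
  fx <- generateFixture(smallFixtureSpec())
  c1 <- buildCorpus(fx$genome, fx$positives, fx$excluded, seed = 4, k = 3)
  expect_identical(sort(GenomicRanges::width(c1$negatives)),
                   sort(GenomicRanges::width(c1$positives)))
  expect_true(all(GenomicRanges::countOverlaps(c1$negatives,
                                               fx$excluded) == 0L))
  # same seed -> byte-identical manifest
  c2 <- buildCorpus(fx$genome, fx$positives, fx$excluded, seed = 4, k = 3)
  expect_identical(c1$manifest, c2$manifest)
  # manifest round-trips through the TSV exchange format
  path <- tempfile(fileext = ".tsv")
  writeManifest(c1$manifest, path)
  expect_equal(readManifest(path), c1$manifest)
})
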