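test_that("confusion counting thresholds at 0.5 with ties positive", {
  cc <- confusionCounts(c(0.9, 0.1), c(1, 0))
  expect_equal(c(cc@tp, cc@tn, cc@fp, cc@fn), c(1L, 1L, 0L, 0L))
  # score exactly at the threshold predicts positive
  cc2 <- confusionCounts(0.5, 0)
  expect_equal(cc2@fp, 1L)
  # counts always partition the sample set
  set.seed(12)
  s <- runif(100); y <- rbinom(100, 1, 0.5)
  cc3 <- confusionCounts(s, y)
  expect_equal(cc3@tp + cc3@fn + cc3@tn + cc3@fp, 100L)
  expect_error(confusionCounts(numeric(0), integer(0)), "no samples")
})

test_that("metrics reproduce closed-form substitutions", {
  # perfect classifier
  perfect <- classificationMetrics(
    new("ConfusionCounts", tp = 5L, fn = 0L, tn = 7L, fp = 0L))
  expect_equal(c(perfect@sn, perfect@sp, perfect@acc, perfect@mcc),
               c(1, 1, 1, 1))
  # hand-computed example
  r <- classificationMetrics(
    new("ConfusionCounts", tp = 9L, fn = 1L, tn = 8L, fp = 2L))
  expect_equal(r@sn, 0.9)
  expect_equal(r@sp, 0.8)
  expect_equal(r@acc, 0.85)
  expect_equal(r@mcc, 70 / sqrt(9900))
  expect_equal(r@mcc, 0.7035, tolerance = 1e-4)
  # degenerate predictions: MCC falls back to 0
  allPos <- classificationMetrics(
    new("ConfusionCounts", tp = 5L, fn = 0L, tn = 0L, fp = 5L))
  expect_equal(allPos@mcc, 0)
  expect_error(classificationMetrics(
    new("ConfusionCounts", tp = 0L, fn = 0L, tn = 5L, fp = 5L)),
    "sensitivity undefined")
})

test_that("metrics are invariant under scaling counts and swap symmetry", {
  base <- new("ConfusionCounts", tp = 9L, fn = 1L, tn = 8L, fp = 2L)
  scaled <- new("ConfusionCounts", tp = 27L, fn = 3L, tn = 24L, fp = 6L)
  r1 <- classificationMetrics(base); r2 <- classificationMetrics(scaled)
  expect_equal(c(r1@sn, r1@sp, r1@acc, r1@mcc),
               c(r2@sn, r2@sp, r2@acc, r2@mcc))
  # swapping classes and predictions maps Sn <-> Sp, leaves MCC unchanged
  swapped <- classificationMetrics(
    new("ConfusionCounts", tp = 8L, fn = 2L, tn = 9L, fp = 1L))
  expect_equal(swapped@sn, r1@sp)
  expect_equal(swapped@sp, r1@sn)
  expect_equal(swapped@mcc, r1@mcc)
})

test_that("random coin predictions give near-zero MCC", {
  set.seed(77)
  y <- rep(0:1, 500)
  s <- runif(1000)
  r <- classificationMetrics(s, y)
  expect_lt(abs(r@mcc), 0.2)
})

test_that("AUC matches the worked example and its edge conventions", {
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(rocAuc(rep(0.5, 10), rep(0:1, 5)), 0.5)   # all ties
  expect_error(rocAuc(c(0.2, 0.8), c(1, 1)), "both classes")
})

test_that("AUC equals exhaustive pairwise concordance (oracle, exact)", {
  set.seed(19)
  for (trial in 1:20) {
    n <- sample(4:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))     # both classes present
    s <- round(runif(n), 2)                 # rounded scores force ties
    expect_identical(rocAuc(s, y), naiveAuc(s, y))
  }
})

test_that("AUC complement identity holds", {
  set.seed(20)
  s <- runif(50); y <- c(0, 1, rbinom(48, 1, 0.4))
  expect_equal(rocAuc(s, y) + rocAuc(1 - s, y), 1)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  s <- runif(60); y <- c(0, 1, rbinom(58, 1, 0.5))
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rocAuc(s, y), ref, tolerance = 1e-12)
})

test_that("ROC curve points run from (0,0) to (1,1) monotonically", {
  set.seed(24)
  s <- runif(30); y <- c(0, 1, rbinom(28, 1, 0.5))
  rc <- rocCurve(s, y)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
})

test_that("model evaluation over variable-length fragments produces a report", {
  g <- toyGenome(20000L)
  set.seed(25)
  starts <- seq(1000L, 15000L, by = 1000L)
  lens <- sample(200:400, length(starts), replace = TRUE)
  iv <- gr("chr1", starts, starts + lens - 1L,
           rep(c("positive", "negative"), length.out = length(starts)))
  m <- buildModel(modelConfig(stageChannels = c(8L, 8L, 8L, 8L, 8L),
                              fcWidths = c(12L, 8L)), seed = 6)
  rep <- evaluateModel(m, g, iv)
  expect_s4_class(rep, "MetricsReport")
  expect_true(rep@auc >= 0 && rep@auc <= 1)
  expect_true(rep@acc >= min(rep@sn, rep@sp) &&
              rep@acc <= max(rep@sn, rep@sp))
  sc <- scoreFragments(m, g, iv)
  expect_length(sc, length(iv))
  expect_true(all(sc >= 0 & sc <= 1))
})
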