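test_that("leaky rectifier follows its closed form and is monotone", {
  expect_equal(leakyReLU(5, 100), 5)
  expect_equal(leakyReLU(0, 100), 0)
  expect_equal(leakyReLU(-100, 100), -1)
  x <- seq(-2, 2, length.out = 401)
  y <- leakyReLU(x, 100)
  expect_true(all(diff(y) >= 0))                 # monotone non-decreasing
  expect_equal(leakyReLU(-1e-9, 100), -1e-11)    # continuous at 0
  # shape preserved for matrices/arrays
  m <- matrix(c(-100, 2, 0, -1), 2)
  expect_equal(leakyReLU(m, 100), matrix(c(-1, 2, 0, -0.01), 2))
})

test_that("gated convolution matches closed forms at degenerate weights", {
  set.seed(4)
  w <- gatedConvWeights(1, 1, 3)
  x <- matrix(rnorm(7), 1, 7)
  # zero gate -> sigmoid(0) = 0.5 times the linear convolution
  w0 <- w; w0$Wg[] <- 0; w0$bg[] <- 0
  expect_equal(gatedConv(x, w0), 0.5 * naiveConv(x, w$Wl, w$bl, 3),
               tolerance = 1e-12)
  # zero linear branch -> identically zero output
  wz <- w; wz$Wl[] <- 0; wz$bl[] <- 0
  expect_equal(gatedConv(x, wz), matrix(0, 1, 7))
})

test_that("gated convolution equals the brute-force oracle on short inputs", {
  set.seed(5)
  for (trial in 1:10) {
    C <- sample(1:3, 1); O <- sample(1:4, 1)
    k <- sample(c(1L, 3L, 5L, 7L), 1)
    L <- sample(k:10, 1)
    w <- gatedConvWeights(C, O, k)
    x <- matrix(rnorm(C * L), C, L)
    expect_equal(gatedConv(x, w), naiveGatedConv(x, w), tolerance = 1e-6)
  }
})

test_that("gated convolution validates channel agreement", {
  w <- gatedConvWeights(2, 3, 3)
  expect_error(gatedConv(matrix(0, 4, 10), w), "channel mismatch")
})

test_that("inception block concatenates branch outputs and preserves length", {
  set.seed(6)
  x <- matrix(rnorm(4 * 20), 4, 20)
  bw <- inceptionBlockWeights("A", 4, 32)
  y <- gatedInceptionBlock(x, bw)
  expect_equal(dim(y), c(32L, 20L))
  # branch-by-branch equality with standalone gated conv + activation
  manual <- do.call(rbind, lapply(bw, function(br)
    leakyReLU(gatedConv(x, br$convs[[1]]), 100)))
  expect_equal(y, manual, tolerance = 1e-12)
  # constant-zero input with zero biases -> zero output
  bz <- inceptionBlockWeights("A", 4, 16)
  expect_equal(gatedInceptionBlock(matrix(0, 4, 9), bz),
               matrix(0, 16, 9))
})

test_that("variant B and C blocks run their bottleneck branches", {
  set.seed(7)
  x <- matrix(rnorm(8 * 16), 8, 16)
  for (v in c("B", "C")) {
    bw <- inceptionBlockWeights(v, 8, 16)
    y <- gatedInceptionBlock(x, bw)
    expect_equal(dim(y), c(16L, 16L))
    expect_length(bw, 4L)
    expect_true(bw[[4]]$pool)
  }
})

test_that("SPP pooling gives the worked example and a fixed-size output", {
  expect_equal(sppPool(matrix(1:4, 1, 4)),
               matrix(c(2.5, 1.5, 3.5, 1, 2, 3, 4), 1, 7))
  # constant input -> every pooled value equals the constant
  expect_equal(sppPool(matrix(3, 2, 11)), matrix(3, 2, 7))
  # output width independent of input length
  for (L in c(4, 5, 17, 200, 801))
    expect_equal(dim(sppPool(matrix(rnorm(3 * L), 3, L))), c(3L, 7L))
  expect_error(sppPool(matrix(1, 1, 3)), "shorter than the largest")
})

test_that("SPP level 1 is the exact global mean and parts differ by <= 1", {
  set.seed(8)
  for (L in c(4, 7, 13, 100)) {
    x <- matrix(rnorm(2 * L), 2, L)
    expect_equal(sppPool(x)[, 1], rowMeans(x))
    for (k in c(2L, 4L)) {
      b <- DHScan:::.spp_bounds(L, k)
      w <- b[, "end"] - b[, "start"] + 1L
      expect_lte(diff(range(w)), 1L)
      expect_equal(sum(w), L)
    }
  }
})

test_that("full backward pass matches numerical gradients", {
  set.seed(42)
  cfg <- modelConfig(stageChannels = c(8L, 8L, 8L, 8L, 8L),
                     fcWidths = c(10L, 6L), dropoutRate = 0,
                     minInputLen = 64L, maxInputLen = 128L)
  m <- buildModel(cfg, seed = 3)
  arch <- DHScan:::.modelArch(cfg)
  n <- 4L; L <- 64L
  X <- array(runif(4 * L * n), c(4, L, n))
  y <- c(1, 0, 1, 0)
  lossAt <- function(P) {
    fw <- DHScan:::.model_fwd(P, arch, cfg, m@state, X, train = TRUE)
    -mean(log(pmax(fw$probs[cbind(y + 1L, seq_len(n))], 1e-12)))
  }
  st <- DHScan:::.model_step(m@params, arch, cfg, m@state, X, y)
  eps <- 1e-6
  # check weight entries (smooth almost surely); a handful per layer type
  set.seed(9)
  for (nm in c("s1.b2.c1.Wl", "s3.b3.c2.Wg", "s5.b4.c1.Wl",
               "fc1.W", "bn1.gamma", "fc3.W")) {
    g <- st$grads[[nm]]
    for (ii in sample(length(g), 2)) {
      P2 <- m@params; P2[[nm]][ii] <- P2[[nm]][ii] + eps
      P3 <- m@params; P3[[nm]][ii] <- P3[[nm]][ii] - eps
      num <- (lossAt(P2) - lossAt(P3)) / (2 * eps)
      expect_equal(g[ii], num, tolerance = 1e-3)
    }
  }
})
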