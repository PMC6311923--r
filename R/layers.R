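# Numerical core of the network: 1-D convolution (im2col + BLAS matmul),
# gated convolution, inception blocks, max pooling, spatial pyramid pooling,
# batch normalisation and dense layers, each with a matching backward pass.
# Batched feature maps are arrays of dim [channels, length, n].

# ---- activation ------------------------------------------------------------

#' Leaky rectified linear unit
#'
#' \code{y = x} for \code{x >= 0} and \code{y = x / a} otherwise, applied
#' elementwise. The large divisor (default 100) keeps a small negative slope
#' so gradients do not vanish in the deep stack while the positive branch is
#' the identity.
#'
#' @param x numeric vector, matrix or array.
#' @param a positive divisor of the negative branch.
#' @return object of the same shape as \code{x}.
#' @examples
#' leakyReLU(c(-100, 0, 5))   # -1 0 5
#' @export
leakyReLU <- function(x, a = 100) {
  stopifnot(a > 0)
  cpp_leaky(x, a)
}

.leaky_bwd <- function(dY, x, a) cpp_leaky_bwd(dY, x, a)

# ---- convolution -----------------------------------------------------------

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Gated convolution: linear conv modulated elementwise by a sigmoid gate conv,
# two independent weight sets. Fully compiled (shift-and-GEMM, no im2col);
# the backward pass needs the layer input as its cache.
.gconv_fwd <- function(X, w, keep.cache = TRUE) {
  cpp_gconv_fwd(X, w$Wl, w$bl, w$Wg, w$bg, w$k, keep.cache)
}

.gconv_bwd <- function(dY, w, cache) {
  cpp_gconv_bwd(dY, cache$X, cache$lin, cache$sig, w$Wl, w$Wg, w$k)
}

#' Create gated-convolution weights
#'
#' Allocates the two independent kernel/bias pairs (linear and gate) of a
#' gated convolution. Kernels use He-scaled normal initialisation with the
#' scale doubled to compensate for the sigmoid gate's attenuation (a random
#' gate multiplies the signal variance by roughly 1/4), so activation
#' magnitudes are stable through the deep stack; biases start at zero.
#'
#' @param inChannels,outChannels channel counts.
#' @param kernelSize odd kernel width.
#' @return list with elements \code{Wl}, \code{bl}, \code{Wg}, \code{bg},
#'   \code{k}; weight matrices have dim \code{outChannels x
#'   (inChannels*kernelSize)}.
#' @export
gatedConvWeights <- function(inChannels, outChannels, kernelSize) {
  stopifnot(kernelSize %% 2 == 1, inChannels >= 1, outChannels >= 1)
  fan <- inChannels * kernelSize
  sdw <- sqrt(8 / fan)   # He scale x2: offsets the sigmoid gate attenuation
  list(Wl = matrix(rnorm(outChannels * fan, sd = sdw), outChannels, fan),
       bl = numeric(outChannels),
       Wg = matrix(rnorm(outChannels * fan, sd = sdw), outChannels, fan),
       bg = numeric(outChannels),
       k  = as.integer(kernelSize))
}

#' Gated convolution of a feature map
#'
#' Same-padded 1-D convolution whose linear output is multiplied elementwise
#' by a sigmoid-activated second convolution of the same input (GLU-style
#' gating): \code{out = conv_l(x) * sigmoid(conv_g(x))}. Output length equals
#' input length.
#'
#' @param x feature map: a \code{channels x length} matrix or a
#'   \code{channels x length x n} batch array.
#' @param weights a weight list from \code{\link{gatedConvWeights}}.
#' @return feature map of the same form as \code{x} with
#'   \code{nrow(weights$Wl)} channels.
#' @examples
#' w <- gatedConvWeights(1, 1, 3)
#' w$Wg[] <- 0; w$bg[] <- 0           # gate = sigmoid(0) = 0.5
#' x <- matrix(1:5, 1, 5)
#' gatedConv(x, w)                    # 0.5 * linear convolution
#' @export
gatedConv <- function(x, weights) {
  was.mat <- is.matrix(x)
  if (was.mat) dim(x) <- c(dim(x), 1L)
  if (dim(x)[1] * weights$k != ncol(weights$Wl))
    stop("channel mismatch: input has ", dim(x)[1], " channels but weights expect ",
         ncol(weights$Wl) %/% weights$k, call. = FALSE)
  out <- .gconv_fwd(x, weights, keep.cache = FALSE)$Y
  if (was.mat) out <- matrix(out, dim(out)[1], dim(out)[2])
  out
}

# ---- inception blocks ------------------------------------------------------

# Branch layouts per variant, as lists of conv descriptors. Q = outCh/4.
# A: four parallel gated convs, kernels from `kernels`.
# B: 1x / 1x->3x / 1x->3x->3x / maxpool3->1x (bottleneck width Q).
# C: as B with kernel-7 convolutions.
.block_layout <- function(variant, inCh, outCh, kernels = c(1L, 3L, 5L, 7L)) {
  Q <- outCh %/% 4L
  if (variant == "A") {
    lapply(kernels, function(k)
      list(pool = FALSE, convs = list(c(inCh, Q, k))))
  } else {
    kk <- if (variant == "B") 3L else 7L
    list(
      list(pool = FALSE, convs = list(c(inCh, Q, 1L))),
      list(pool = FALSE, convs = list(c(inCh, Q, 1L), c(Q, Q, kk))),
      list(pool = FALSE, convs = list(c(inCh, Q, 1L), c(Q, Q, kk), c(Q, Q, kk))),
      list(pool = TRUE,  convs = list(c(inCh, Q, 1L)))
    )
  }
}

#' Create the weights of a gated-inception block
#'
#' @param variant \code{"A"}, \code{"B"} or \code{"C"}. Variant A runs four
#'   parallel gated convolutions with kernel sizes 1, 3, 5 and 7; variants B
#'   and C use bottlenecked branches (1x1, 1x1 -> kxk, 1x1 -> kxk -> kxk, and
#'   max-pool -> 1x1) with k = 3 (B) or k = 7 (C).
#' @param inChannels,outChannels channel counts; \code{outChannels} must be a
#'   multiple of 4 (one quarter per branch).
#' @param kernels kernel sizes of the variant-A branches.
#' @return nested list of branch weights, each branch a list of
#'   \code{\link{gatedConvWeights}}.
#' @export
inceptionBlockWeights <- function(variant, inChannels, outChannels,
                                  kernels = c(1L, 3L, 5L, 7L)) {
  stopifnot(outChannels %% 4 == 0)
  layout <- .block_layout(variant, inChannels, outChannels, kernels)
  lapply(layout, function(br) {
    list(pool = br$pool,
         convs = lapply(br$convs, function(d) gatedConvWeights(d[1], d[2], d[3])))
  })
}

#' Apply a gated-inception block
#'
#' Runs the parallel branches of the block on a feature map and concatenates
#' their outputs along the channel dimension; every gated convolution is
#' followed by the leaky rectifier. Length is preserved.
#'
#' @param x feature map (\code{channels x length} matrix or
#'   \code{channels x length x n} array).
#' @param weights from \code{\link{inceptionBlockWeights}}.
#' @param leakyDivisor divisor of the leaky rectifier.
#' @return feature map with the block's output channels.
#' @export
gatedInceptionBlock <- function(x, weights, leakyDivisor = 100) {
  was.mat <- is.matrix(x)
  if (was.mat) dim(x) <- c(dim(x), 1L)
  out <- .block_fwd(x, weights, leakyDivisor, keep.cache = FALSE)$Y
  if (was.mat) out <- matrix(out, dim(out)[1], dim(out)[2])
  out
}

.block_fwd <- function(X, bw, a, keep.cache = TRUE) {
  d <- dim(X)
  outs <- vector("list", length(bw))
  caches <- vector("list", length(bw))
  for (i in seq_along(bw)) {
    br <- bw[[i]]
    H <- X
    bc <- list(pool = NULL, convs = vector("list", length(br$convs)),
               pre = vector("list", length(br$convs)))
    if (isTRUE(br$pool)) {
      mp <- .maxpool3same_fwd(H, keep.cache)
      H <- mp$Y
      bc$pool <- mp$cache
    }
    for (j in seq_along(br$convs)) {
      g <- .gconv_fwd(H, br$convs[[j]], keep.cache)
      if (keep.cache) {
        bc$convs[[j]] <- list(lin = g$lin, sig = g$sig, X = H)
        bc$pre[[j]] <- g$Y            # pre-activation, for leaky backward
      }
      H <- leakyReLU(g$Y, a)
    }
    outs[[i]] <- H
    caches[[i]] <- bc
  }
  chans <- vapply(outs, function(o) dim(o)[1], integer(1))
  Y <- array(0, c(sum(chans), d[2], d[3]))
  at <- 0L
  for (i in seq_along(outs)) {
    Y[(at + 1L):(at + chans[i]), , ] <- outs[[i]]
    at <- at + chans[i]
  }
  list(Y = Y, caches = caches, chans = chans, inDim = d)
}

.block_bwd <- function(dY, bw, fw, a) {
  d <- fw$inDim
  dX <- array(0, d)
  grads <- vector("list", length(bw))
  at <- 0L
  for (i in seq_along(bw)) {
    br <- bw[[i]]
    bc <- fw$caches[[i]]
    dH <- dY[(at + 1L):(at + fw$chans[i]), , , drop = FALSE]
    at <- at + fw$chans[i]
    gbr <- vector("list", length(br$convs))
    for (j in rev(seq_along(br$convs))) {
      dH <- .leaky_bwd(dH, bc$pre[[j]], a)
      g <- .gconv_bwd(dH, br$convs[[j]], bc$convs[[j]])
      gbr[[j]] <- g[c("dWl", "dbl", "dWg", "dbg")]
      dH <- g$dX
    }
    if (isTRUE(br$pool)) dH <- .maxpool3same_bwd(dH, bc$pool)
    dX <- dX + dH
    grads[[i]] <- gbr
  }
  list(dX = dX, grads = grads)
}

# ---- pooling ---------------------------------------------------------------

# Non-overlapping max pool, kernel = stride = s. Drops a trailing remainder.
# Ties take the first position (compiled kernels).
.maxpool_fwd <- function(X, s = 2L) {
  r <- cpp_maxpool(X, s)
  list(Y = r$Y, idx = r$idx, inLen = dim(X)[2], s = s)
}

.maxpool_bwd <- function(dY, cache)
  cpp_maxpool_bwd(dY, cache$idx, cache$inLen, cache$s)

# Same-length max pool, kernel 3, stride 1 (the inception pool branch).
# Tie-break priority: centre, then left, then right.
.maxpool3same_fwd <- function(X, keep.cache = TRUE) {
  r <- cpp_maxpool3(X)
  list(Y = r$Y, cache = if (keep.cache) list(pick = r$pick) else NULL)
}

.maxpool3same_bwd <- function(dY, cache) cpp_maxpool3_bwd(dY, cache$pick)

# ---- spatial pyramid pooling ----------------------------------------------

# Part boundaries for adaptive partition of L positions into k parts,
# sizes differing by at most 1.
.spp_bounds <- function(L, k) {
  cut <- floor(seq_len(k) * L / k)
  start <- c(0L, cut[-k]) + 1L
  cbind(start = start, end = as.integer(cut))
}

#' Spatial pyramid pooling of a 1-D feature map
#'
#' For each pyramid level k the positions are partitioned into k contiguous
#' parts (sizes differing by at most one when k does not divide the length)
#' and each part is mean-pooled per channel. The level outputs are
#' concatenated in order, so levels (1, 2, 4) yield 7 values per channel
#' regardless of input length: a fixed-size descriptor from variable-length
#' input.
#'
#' @param x feature map (\code{channels x length} matrix or
#'   \code{channels x length x n} array).
#' @param levels strictly increasing pyramid levels.
#' @return \code{channels x sum(levels)} matrix (or
#'   \code{channels x sum(levels) x n} array for batched input).
#' @examples
#' sppPool(matrix(1:4, 1, 4))   # 2.5 | 1.5 3.5 | 1 2 3 4
#' @export
sppPool <- function(x, levels = c(1L, 2L, 4L)) {
  was.mat <- is.matrix(x)
  if (was.mat) dim(x) <- c(dim(x), 1L)
  if (dim(x)[2] < max(levels))
    stop("input length ", dim(x)[2], " is shorter than the largest SPP level ",
         max(levels), call. = FALSE)
  out <- .spp_fwd(x, levels)$Y
  if (was.mat) out <- matrix(out, dim(out)[1], dim(out)[2])
  out
}

.spp_fwd <- function(X, levels) {
  d <- dim(X)
  nb <- sum(levels)
  Y <- array(0, c(d[1], nb, d[3]))
  widths <- integer(nb)
  bounds <- matrix(0L, nb, 2L)
  at <- 0L
  for (k in levels) {
    b <- .spp_bounds(d[2], k)
    for (i in seq_len(k)) {
      at <- at + 1L
      s <- b[i, 1L]; e <- b[i, 2L]
      w <- e - s + 1L
      widths[at] <- w
      bounds[at, ] <- c(s, e)
      slab <- X[, s:e, , drop = FALSE]               # [C, w, n]
      Y[, at, ] <- colSums(aperm(slab, c(2L, 1L, 3L))) / w
    }
  }
  list(Y = Y, widths = widths, bounds = bounds, inDim = d)
}

.spp_bwd <- function(dY, cache) {
  d <- cache$inDim
  dX <- array(0, d)
  for (at in seq_along(cache$widths)) {
    s <- cache$bounds[at, 1L]; e <- cache$bounds[at, 2L]
    g <- dY[, at, , drop = FALSE] / cache$widths[at]   # [C, 1, n]
    dX[, s:e, ] <- dX[, s:e, , drop = FALSE] +
      g[, rep(1L, e - s + 1L), , drop = FALSE]
  }
  dX
}

# ---- dense / batch norm / dropout / softmax --------------------------------

.dense_fwd <- function(X, W, b) W %*% X + b          # X: [in, n]

.dense_bwd <- function(dY, W, X) {
  list(dW = dY %*% t(X), db = rowSums(dY), dX = crossprod(W, dY))
}

.bn_eps <- 1e-5

.bn_fwd_train <- function(X, gamma, beta) {
  n <- ncol(X)
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + .bn_eps)
  xhat <- xc * inv
  list(Y = gamma * xhat + beta, xhat = xhat, inv = inv, mu = mu, var = v)
}

.bn_fwd_eval <- function(X, gamma, beta, rmean, rvar) {
  gamma * ((X - rmean) / sqrt(rvar + .bn_eps)) + beta
}

.bn_bwd <- function(dY, gamma, cache) {
  n <- ncol(dY)
  xhat <- cache$xhat
  dgamma <- rowSums(dY * xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * gamma
  dX <- (cache$inv / n) *
    (n * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

.dropout_fwd <- function(X, rate) {
  if (rate <= 0) return(list(Y = X, mask = NULL))
  keep <- 1 - rate
  mask <- array((runif(length(X)) < keep) / keep, dim(X))
  list(Y = X * mask, mask = mask)
}

.dropout_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

.softmax <- function(Z) {                           # Z: [classes, n]
  Z <- Z - matrix(apply(Z, 2, max), nrow(Z), ncol(Z), byrow = TRUE)
  E <- exp(Z)
  E / matrix(colSums(E), nrow(Z), ncol(Z), byrow = TRUE)
}
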