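# Model assembly: translates a ModelConfig into a flat parameter list, runs
# the full forward pass (5 inception stages / 4 max pools / SPP / 3 FC), and
# the matching backward pass used by the trainer.

# Architecture descriptor derived deterministically from the config.
.modelArch <- function(cfg) {
  inCh <- 4L
  stages <- vector("list", 5L)
  for (i in 1:5) {
    outCh <- cfg@stageChannels[i]
    stages[[i]] <- list(
      variant = cfg@stageVariants[i],
      inCh = inCh, outCh = outCh,
      layout = .block_layout(cfg@stageVariants[i], inCh, outCh,
                             cfg@inceptionAKernels))
    inCh <- outCh
  }
  fcIn <- cfg@stageChannels[5] * sum(cfg@sppLevels)
  list(stages = stages,
       fc = c(fcIn, cfg@fcWidths, 2L))
}

.pname <- function(s, b, c, part) sprintf("s%d.b%d.c%d.%s", s, b, c, part)

#' Build a gated-inception DHS classifier
#'
#' Allocates and initialises all trainable parameters for the given
#' configuration: five gated-inception stages interleaved with four max-pool
#' layers, the SPP head, and three fully connected layers (the two hidden
#' ones batch-normalised). Kernels use He-scaled normal initialisation.
#'
#' @param config a \linkS4class{ModelConfig}.
#' @param seed RNG seed for weight initialisation.
#' @param normalizeInit rescale each stage's output to unit variance on a
#'   random probe batch (LSUV-style). The sigmoid gates make the activation
#'   scale respond superlinearly to the weight scale, so a purely analytic
#'   initialisation either vanishes or explodes over five stages; the
#'   data-driven correction is exact because the leaky rectifier is
#'   positively homogeneous.
#' @return a \linkS4class{DHSModel}.
#' @examples
#' m <- buildModel(demoModelConfig(), seed = 1)
#' countParameters(m)
#' @export
buildModel <- function(config = modelConfig(), seed = 1L,
                       normalizeInit = TRUE) {
  validObject(config)
  set.seed(seed)
  arch <- .modelArch(config)
  P <- list()
  for (i in 1:5) {
    st <- arch$stages[[i]]
    for (j in seq_along(st$layout)) {
      br <- st$layout[[j]]
      for (m in seq_along(br$convs)) {
        d <- br$convs[[m]]
        w <- gatedConvWeights(d[1], d[2], d[3])
        for (part in c("Wl", "bl", "Wg", "bg"))
          P[[.pname(i, j, m, part)]] <- w[[part]]
      }
    }
  }
  fc <- arch$fc
  state <- list()
  for (l in 1:3) {
    fanIn <- fc[l]; fanOut <- fc[l + 1L]
    P[[sprintf("fc%d.W", l)]] <-
      matrix(rnorm(fanOut * fanIn, sd = sqrt(2 / fanIn)), fanOut, fanIn)
    P[[sprintf("fc%d.b", l)]] <- numeric(fanOut)
    if (l < 3L) {
      P[[sprintf("bn%d.gamma", l)]] <- rep(1, fanOut)
      P[[sprintf("bn%d.beta", l)]] <- numeric(fanOut)
      state[[sprintf("bn%d.mean", l)]] <- numeric(fanOut)
      state[[sprintf("bn%d.var", l)]] <- rep(1, fanOut)
    }
  }
  if (normalizeInit) P <- .normalize_init(P, arch, config)
  new("DHSModel", config = config, params = P, state = state)
}

# Rescale the final conv of every branch so each stage's output has unit
# standard deviation on a random one-hot probe batch. Scaling the linear
# kernel scales the gated-conv output linearly, and leaky ReLU is positively
# homogeneous, so the correction is exact per stage.
.normalize_init <- function(P, arch, cfg, probeN = 8L) {
  L <- as.integer((cfg@minInputLen + cfg@maxInputLen) / 2)
  X <- array(0, c(4L, L, probeN))
  base <- sample.int(4L, L * probeN, replace = TRUE)
  X[cbind(base, rep(seq_len(L), probeN),
          rep(seq_len(probeN), each = L))] <- 1
  for (i in 1:5) {
    bw <- .stage_weights(P, arch, i)
    H <- .block_fwd(X, bw, cfg@leakyDivisor, keep.cache = FALSE)$Y
    s <- stats::sd(H)
    if (s > 0 && is.finite(s)) {
      for (j in seq_along(arch$stages[[i]]$layout)) {
        m <- length(arch$stages[[i]]$layout[[j]]$convs)
        P[[.pname(i, j, m, "Wl")]] <- P[[.pname(i, j, m, "Wl")]] / s
      }
      H <- H / s
    }
    X <- if (i < 5L) .maxpool_fwd(H, cfg@poolSize)$Y else H
  }
  P
}

# Nested weight view of one stage, referencing the flat parameter list.
.stage_weights <- function(P, arch, i) {
  st <- arch$stages[[i]]
  lapply(seq_along(st$layout), function(j) {
    br <- st$layout[[j]]
    list(pool = br$pool,
         convs = lapply(seq_along(br$convs), function(m) {
           d <- br$convs[[m]]
           list(Wl = P[[.pname(i, j, m, "Wl")]],
                bl = P[[.pname(i, j, m, "bl")]],
                Wg = P[[.pname(i, j, m, "Wg")]],
                bg = P[[.pname(i, j, m, "bg")]],
                k = d[3])
         }))
  })
}

#' Count trainable parameters
#'
#' Sum of the sizes of every trainable array: linear and gate convolution
#' kernels and biases, fully connected weights and biases, and batch-norm
#' scale/shift. Batch-norm running statistics are state, not parameters, and
#' are excluded. The default configuration totals exactly 3,077,382.
#'
#' @param model a \linkS4class{DHSModel}.
#' @return integer parameter count.
#' @export
countParameters <- function(model) {
  stopifnot(is(model, "DHSModel"))
  sum(vapply(model@params, length, integer(1)))
}

# Full forward pass. X: [4, L, n]. Returns probs [2, n] plus caches/state.
.model_fwd <- function(P, arch, cfg, state, X, train = FALSE,
                       keep.cache = FALSE) {
  a <- cfg@leakyDivisor
  drop <- if (train) cfg@dropoutRate else 0
  stageCaches <- vector("list", 5L)
  for (i in 1:5) {
    bw <- .stage_weights(P, arch, i)
    bf <- .block_fwd(X, bw, a, keep.cache)
    X <- bf$Y
    dp <- .dropout_fwd(X, drop)
    X <- dp$Y
    mp <- NULL
    if (i < 5L) {
      mp <- .maxpool_fwd(X, cfg@poolSize)
      X <- mp$Y
    }
    if (keep.cache)
      stageCaches[[i]] <- list(block = bf, dropMask = dp$mask, pool = mp)
  }
  spp <- .spp_fwd(X, cfg@sppLevels)
  n <- dim(X)[3]
  F0 <- matrix(spp$Y, arch$fc[1], n)
  fcCache <- list()
  H <- F0
  for (l in 1:2) {
    Z <- .dense_fwd(H, P[[sprintf("fc%d.W", l)]], P[[sprintf("fc%d.b", l)]])
    if (train) {
      bn <- .bn_fwd_train(Z, P[[sprintf("bn%d.gamma", l)]],
                          P[[sprintf("bn%d.beta", l)]])
      mom <- cfg@bnMomentum
      nb <- ncol(Z)
      ub <- if (nb > 1) nb / (nb - 1) else 1   # unbiased running variance
      state[[sprintf("bn%d.mean", l)]] <-
        (1 - mom) * state[[sprintf("bn%d.mean", l)]] + mom * bn$mu
      state[[sprintf("bn%d.var", l)]] <-
        (1 - mom) * state[[sprintf("bn%d.var", l)]] + mom * bn$var * ub
      Zn <- bn$Y
    } else {
      bn <- NULL
      Zn <- .bn_fwd_eval(Z, P[[sprintf("bn%d.gamma", l)]],
                         P[[sprintf("bn%d.beta", l)]],
                         state[[sprintf("bn%d.mean", l)]],
                         state[[sprintf("bn%d.var", l)]])
    }
    A <- leakyReLU(Zn, a)
    dp <- .dropout_fwd(A, drop)
    if (keep.cache)
      fcCache[[l]] <- list(input = H, bn = bn, pre = Zn, dropMask = dp$mask)
    H <- dp$Y
  }
  logits <- .dense_fwd(H, P[["fc3.W"]], P[["fc3.b"]])
  probs <- .softmax(logits)
  list(probs = probs, state = state,
       cache = if (keep.cache)
         list(stages = stageCaches, spp = spp, F0 = F0, fc = fcCache,
              fc3in = H) else NULL)
}

# One training step: forward with caches, cross-entropy loss, full backward.
# y: integer 0/1 labels. Returns loss, flat gradient list, updated BN state.
.model_step <- function(P, arch, cfg, state, X, y) {
  fw <- .model_fwd(P, arch, cfg, state, X, train = TRUE, keep.cache = TRUE)
  n <- length(y)
  probs <- fw$probs
  Y <- rbind(1 - y, y)
  loss <- -mean(log(pmax(probs[cbind(y + 1L, seq_len(n))], 1e-12)))
  G <- list()
  a <- cfg@leakyDivisor
  cache <- fw$cache

  dZ <- (probs - Y) / n
  d3 <- .dense_bwd(dZ, P[["fc3.W"]], cache$fc3in)
  G[["fc3.W"]] <- d3$dW; G[["fc3.b"]] <- d3$db
  dH <- d3$dX
  for (l in 2:1) {
    fcc <- cache$fc[[l]]
    dH <- .dropout_bwd(dH, fcc$dropMask)
    dH <- .leaky_bwd(dH, fcc$pre, a)
    bb <- .bn_bwd(dH, P[[sprintf("bn%d.gamma", l)]], fcc$bn)
    G[[sprintf("bn%d.gamma", l)]] <- bb$dgamma
    G[[sprintf("bn%d.beta", l)]] <- bb$dbeta
    dd <- .dense_bwd(bb$dX, P[[sprintf("fc%d.W", l)]], fcc$input)
    G[[sprintf("fc%d.W", l)]] <- dd$dW; G[[sprintf("fc%d.b", l)]] <- dd$db
    dH <- dd$dX
  }
  dSpp <- array(dH, dim(cache$spp$Y))
  dX <- .spp_bwd(dSpp, cache$spp)
  for (i in 5:1) {
    sc <- cache$stages[[i]]
    if (!is.null(sc$pool)) dX <- .maxpool_bwd(dX, sc$pool)
    dX <- .dropout_bwd(dX, sc$dropMask)
    bw <- .stage_weights(P, arch, i)
    bb <- .block_bwd(dX, bw, sc$block, a)
    for (j in seq_along(bb$grads))
      for (m in seq_along(bb$grads[[j]])) {
        g <- bb$grads[[j]][[m]]
        G[[.pname(i, j, m, "Wl")]] <- g$dWl
        G[[.pname(i, j, m, "bl")]] <- g$dbl
        G[[.pname(i, j, m, "Wg")]] <- g$dWg
        G[[.pname(i, j, m, "bg")]] <- g$dbg
      }
    dX <- bb$dX
  }
  list(loss = loss, grads = G, state = fw$state)
}

# Coerce predict() input into a [4, L, n] batch array.
.as_batch <- function(x) {
  if (is.list(x)) {
    lens <- vapply(x, nrow, integer(1))
    if (length(unique(lens)) != 1L)
      stop("all samples in a batch must have equal length; got lengths ",
           paste(unique(lens), collapse = ", "), call. = FALSE)
    L <- lens[1]
    X <- array(0, c(4L, L, length(x)))
    for (i in seq_along(x)) X[, , i] <- t(x[[i]])
    X
  } else if (is.matrix(x)) {
    array(t(x), c(4L, nrow(x), 1L))
  } else if (is.array(x) && length(dim(x)) == 3L && dim(x)[1] == 4L) {
    x
  } else stop("cannot interpret input as a batch of one-hot matrices",
              call. = FALSE)
}

#' @describeIn DHSModel-class Score a batch of one-hot encoded fragments.
#'   \code{newdata} is a single one-hot matrix (positions x 4), a list of
#'   such matrices of equal length, or a 4 x length x n array. Returns an
#'   n x 2 matrix of class probabilities (columns \code{nonDHS}, \code{DHS})
#'   summing to 1 per row; evaluation mode, so deterministic.
#' @param object a \code{DHSModel}.
#' @param newdata input batch (see above).
#' @param ... ignored.
#' @export
setMethod("predict", "DHSModel", function(object, newdata, ...) {
  X <- .as_batch(newdata)
  cfg <- object@config
  L <- dim(X)[2]
  if (L < cfg@minInputLen || L > cfg@maxInputLen)
    stop("input length ", L, " outside supported range [",
         cfg@minInputLen, ", ", cfg@maxInputLen, "]", call. = FALSE)
  arch <- .modelArch(cfg)
  fw <- .model_fwd(object@params, arch, cfg, object@state, X, train = FALSE)
  out <- t(fw$probs)
  colnames(out) <- c("nonDHS", "DHS")
  out
})

setMethod("show", "DHSModel", function(object) {
  cat("DHSModel with", format(countParameters(object), big.mark = ","),
      "trainable parameters\n")
  show(object@config)
})

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the configuration, all parameter
#' arrays and the batch-norm running statistics.
#'
#' @param model a \linkS4class{DHSModel}.
#' @param path checkpoint file path.
#' @return \code{loadModel} returns the restored \linkS4class{DHSModel};
#'   \code{saveModel} returns \code{path} invisibly.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "DHSModel"))
  saveRDS(list(format = "DHScan-checkpoint-1",
               config = .configAsList(model@config),
               params = model@params, state = model@state), path)
  invisible(path)
}

.configAsList <- function(cfg) {
  nms <- slotNames("ModelConfig")
  setNames(lapply(nms, function(s) slot(cfg, s)), nms)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "DHScan-checkpoint-1"))
    stop("not a DHScan checkpoint: ", path, call. = FALSE)
  cfg <- do.call(modelConfig, x$config)
  new("DHSModel", config = cfg, params = x$params, state = x$state)
}
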