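# Multi-scale training: length binning, on-chromosome extension of fragments
# to their bin's target length, optional amplification through distinct
# padding splits, and the bin-cycling SGD schedule.

#' Define length bins
#'
#' Tiles \code{[minLen, maxLen]} with bins of \code{intervalWidth} bp; each
#' bin's target length is its inclusive upper bound. A fragment of length L
#' belongs to the unique bin with \code{low < L <= high} (the first bin is
#' closed at its lower bound so \code{L == minLen} is assigned).
#'
#' @param intervalWidth bin width (bp); must divide \code{maxLen - minLen}.
#' @param minLen,maxLen supported length range (bp).
#' @return data.frame with columns \code{low}, \code{high}, \code{target}.
#' @examples
#' lengthBins(200)   # (200,400] (400,600] (600,800]
#' @export
lengthBins <- function(intervalWidth, minLen = 200L, maxLen = 800L) {
  stopifnot(intervalWidth >= 1L, maxLen > minLen)
  if ((maxLen - minLen) %% intervalWidth != 0L)
    stop("intervalWidth must divide maxLen - minLen", call. = FALSE)
  high <- seq(minLen + intervalWidth, maxLen, by = intervalWidth)
  data.frame(low = high - intervalWidth, high = high, target = high)
}

#' Assign fragments to length bins
#'
#' @param lengths integer vector of fragment lengths (bp), or a
#'   \code{GRanges} whose widths are used.
#' @param intervalWidth bin width (bp).
#' @param minLen,maxLen supported range; lengths outside it are an error.
#' @return list with \code{bins} (see \code{\link{lengthBins}}) and
#'   \code{binOf} (integer bin index per fragment).
#' @export
assignLengthBins <- function(lengths, intervalWidth = 200L,
                             minLen = 200L, maxLen = 800L) {
  if (is(lengths, "GRanges")) lengths <- width(lengths)
  bins <- lengthBins(intervalWidth, minLen, maxLen)
  out <- which(lengths < minLen | lengths > maxLen)
  if (length(out))
    stop("fragment ", out[1], " has length ", lengths[out[1]],
         " outside [", minLen, ", ", maxLen, "]", call. = FALSE)
  binOf <- pmax(1L, as.integer(ceiling((lengths - minLen) / intervalWidth)))
  list(bins = bins, binOf = binOf)
}

# Feasible left-padding range for extending an interval to targetLength
# within its chromosome. Returns c(min, max) possible left pad.
.pad_range <- function(s, e, targetLength, chromLen) {
  pad <- targetLength - (e - s + 1L)
  roomLeft <- s - 1L
  roomRight <- chromLen - e
  lo <- max(0L, pad - roomRight)
  hi <- min(pad, roomLeft)
  if (lo > hi)
    stop("chromosome too short to extend interval to ", targetLength, " bp",
         call. = FALSE)
  c(lo, hi)
}

#' Extend an interval to a target length
#'
#' Pads the interval with flanking chromosome sequence on both ends until it
#' reaches exactly \code{targetLength} bp, keeping the original span fully
#' contained and staying within chromosome bounds. The left/right split of
#' the padding is chosen by \code{splitPolicy}: \code{"random"} (uniform,
#' seeded) or \code{"centered"} (as even as bounds allow).
#'
#' @param intervals a \code{GRanges} (metadata columns are carried over).
#' @param targetLength target length (bp); per-interval vector allowed.
#' @param genome a \code{DNAStringSet}.
#' @param splitPolicy \code{"random"} or \code{"centered"}.
#' @param seed RNG seed (random policy).
#' @return a \code{GRanges} of extended intervals, parallel to the input.
#' @export
extendToTarget <- function(intervals, targetLength, genome,
                           splitPolicy = c("random", "centered"),
                           seed = 1L) {
  splitPolicy <- match.arg(splitPolicy)
  if (splitPolicy == "random") set.seed(seed)
  chromLen <- setNames(nchar(as.character(genome)), names(genome))
  n <- length(intervals)
  targetLength <- rep_len(as.integer(targetLength), n)
  if (any(width(intervals) > targetLength))
    stop("interval longer than its target length", call. = FALSE)
  s <- start(intervals); e <- end(intervals)
  chroms <- as.character(seqnames(intervals))
  newS <- integer(n)
  for (i in seq_len(n)) {
    cl <- chromLen[[chroms[i]]]
    if (is.null(cl)) stop("unknown chromosome '", chroms[i], "'", call. = FALSE)
    if (cl < targetLength[i])
      stop("chromosome ", chroms[i], " (length ", cl,
           ") too short for target ", targetLength[i], call. = FALSE)
    pr <- .pad_range(s[i], e[i], targetLength[i], cl)
    left <- switch(splitPolicy,
      random = pr[1] + sample.int(pr[2] - pr[1] + 1L, 1L) - 1L,
      centered = pmin(pr[2], pmax(pr[1],
        (targetLength[i] - (e[i] - s[i] + 1L)) %/% 2L)))
    newS[i] <- s[i] - left
  }
  out <- GRanges(chroms, IRanges(newS, width = targetLength))
  mcols(out) <- mcols(intervals)
  out
}

#' Amplify an interval into distinct padding variants
#'
#' Produces up to \code{nVariants} extensions of one interval to
#' \code{targetLength}, each with a different (left, right) padding split,
#' evenly spaced over the feasible range. Fewer variants are returned (with
#' a warning) when the flanks do not admit enough distinct splits.
#'
#' @param interval a length-1 \code{GRanges}.
#' @param targetLength target length (bp).
#' @param nVariants requested number of distinct variants.
#' @param genome a \code{DNAStringSet}.
#' @return a \code{GRanges} of variants, each containing the original span.
#' @export
amplifyInterval <- function(interval, targetLength, nVariants, genome) {
  stopifnot(length(interval) == 1L, nVariants >= 1L)
  chromLen <- nchar(as.character(genome))[[
    match(as.character(seqnames(interval)), names(genome))]]
  pr <- .pad_range(start(interval), end(interval), targetLength, chromLen)
  lefts <- unique(round(seq(pr[1], pr[2], length.out = nVariants)))
  if (length(lefts) < nVariants)
    warning("only ", length(lefts), " distinct padding splits available (",
            nVariants, " requested)", call. = FALSE)
  out <- GRanges(rep(as.character(seqnames(interval)), length(lefts)),
                 IRanges(start(interval) - lefts, width = targetLength))
  mcols(out) <- mcols(interval)[rep(1L, length(lefts)), , drop = FALSE]
  out
}

#' Build a length-binned multi-scale dataset
#'
#' Assigns every fragment to its length bin, extends it on-chromosome to the
#' bin's target length (positives and negatives alike, so every positive
#' sample still contains a complete DHS), optionally amplifies each fragment
#' into several distinct padding variants, extracts and one-hot encodes the
#' sequences, and stacks them per bin.
#'
#' @param genome a \code{DNAStringSet}.
#' @param intervals a \code{GRanges} with a \code{label} metadata column
#'   ("positive"/"negative").
#' @param intervalWidth bin width (bp).
#' @param minLen,maxLen supported length range (bp).
#' @param amplification padding variants per fragment (1 = none).
#' @param splitPolicy padding split policy, see \code{\link{extendToTarget}}.
#' @param seed RNG seed for random padding splits.
#' @return a \linkS4class{MultiScaleDataset}.
#' @export
buildMultiScaleDataset <- function(genome, intervals, intervalWidth = 200L,
                                   minLen = 200L, maxLen = 800L,
                                   amplification = 1L,
                                   splitPolicy = "random", seed = 1L) {
  stopifnot(amplification >= 1L)
  lab <- mcols(intervals)$label
  if (is.null(lab)) stop("intervals need a 'label' metadata column",
                         call. = FALSE)
  asg <- assignLengthBins(width(intervals), intervalWidth, minLen, maxLen)
  bins <- asg$bins
  set.seed(seed)
  samples <- vector("list", nrow(bins))
  labels <- vector("list", nrow(bins))
  for (b in seq_len(nrow(bins))) {
    idx <- which(asg$binOf == b)
    if (length(idx) == 0L) {
      samples[[b]] <- array(0, c(4L, bins$target[b], 0L))
      labels[[b]] <- integer(0)
      next
    }
    target <- bins$target[b]
    if (amplification == 1L) {
      ext <- extendToTarget(intervals[idx], target, genome,
                            splitPolicy = splitPolicy,
                            seed = sample.int(.Machine$integer.max %/% 2L, 1L))
      y <- as.integer(lab[idx] == "positive")
    } else {
      extList <- lapply(idx, function(i)
        suppressWarnings(amplifyInterval(intervals[i], target,
                                         amplification, genome)))
      ext <- do.call(c, extList)
      y <- as.integer(rep(lab[idx],
                          vapply(extList, length, integer(1))) == "positive")
    }
    seqs <- extractFragments(genome, ext)
    arr <- array(0, c(4L, target, length(seqs)))
    for (i in seq_along(seqs)) arr[, , i] <- t(oneHotEncode(seqs[i]))
    samples[[b]] <- arr
    labels[[b]] <- y
  }
  new("MultiScaleDataset", bins = bins, samples = samples, labels = labels,
      amplification = as.integer(amplification))
}

setMethod("show", "MultiScaleDataset", function(object) {
  ns <- vapply(object@labels, length, integer(1))
  cat("MultiScaleDataset:", nrow(object@bins), "bins,", sum(ns),
      "samples (amplification", paste0(object@amplification, ")\n"))
  for (b in seq_len(nrow(object@bins)))
    cat(sprintf("  (%d,%d] -> %d bp: %d samples (%d positive)\n",
                object@bins$low[b], object@bins$high[b],
                object@bins$target[b], ns[b], sum(object@labels[[b]])))
})

#' Train a model with the multi-scale schedule
#'
#' One iteration trains one full epoch on every length bin in ascending
#' target-length order, all bins updating a single shared parameter set (the
#' SPP head keeps the parameter dimensionality identical across bins). The
#' learning rate is multiplied by \code{lrDecay} after every epoch. Sample
#' order is reshuffled per epoch; empty bins are skipped with a warning
#' record in the history. The optimizer is SGD with classical momentum and
#' softmax cross-entropy loss. Deterministic given \code{config@seed}.
#'
#' @param model a \linkS4class{DHSModel}.
#' @param dataset a \linkS4class{MultiScaleDataset}.
#' @param config a \linkS4class{TrainConfig}.
#' @param verbose print per-epoch loss.
#' @param monitor optional callback \code{function(model, iteration,
#'   history)} run after every iteration; returning \code{TRUE} stops
#'   training early (e.g. once a held-out metric is reached).
#' @return list with \code{model} (trained) and \code{history} (data.frame:
#'   iteration, epoch, binTarget, lr, loss, nBatches).
#' @export
trainModel <- function(model, dataset, config = trainConfig(),
                       verbose = FALSE, monitor = NULL) {
  stopifnot(is(model, "DHSModel"), is(dataset, "MultiScaleDataset"))
  validObject(config)
  cfg <- model@config
  arch <- .modelArch(cfg)
  if (max(dataset@bins$target) > cfg@maxInputLen ||
      min(dataset@bins$target) < cfg@minInputLen)
    stop("dataset bin targets outside the model's supported input range",
         call. = FALSE)
  set.seed(config@seed)
  P <- model@params
  state <- model@state
  V <- lapply(P, function(p) p * 0)
  lr <- config@learningRate
  mom <- config@momentum
  binOrder <- order(dataset@bins$target)
  hist <- list()
  epoch <- 0L
  for (it in seq_len(config@iterations)) {
    for (b in binOrder) {
      y <- dataset@labels[[b]]
      if (length(y) == 0L) {
        warning("iteration ", it, ": empty bin (target ",
                dataset@bins$target[b], " bp) skipped", call. = FALSE)
        next
      }
      epoch <- epoch + 1L
      X <- dataset@samples[[b]]
      ord <- sample.int(length(y))
      nb <- 0L
      lossSum <- 0
      for (bs in split(ord, ceiling(seq_along(ord) / config@batchSize))) {
        st <- .model_step(P, arch, cfg, state,
                          X[, , bs, drop = FALSE], y[bs])
        state <- st$state
        for (nm in names(st$grads)) {
          V[[nm]] <- mom * V[[nm]] - lr * st$grads[[nm]]
          P[[nm]] <- P[[nm]] + V[[nm]]
        }
        lossSum <- lossSum + st$loss
        nb <- nb + 1L
      }
      hist[[length(hist) + 1L]] <- data.frame(
        iteration = it, epoch = epoch, binTarget = dataset@bins$target[b],
        lr = lr, loss = lossSum / nb, nBatches = nb)
      if (verbose)
        message(sprintf("iter %d bin %d bp: loss %.4f (lr %.5f)",
                        it, dataset@bins$target[b], lossSum / nb, lr))
      if (config@lrDecayPer == "epoch") lr <- lr * config@lrDecay
    }
    if (config@lrDecayPer == "iteration") lr <- lr * config@lrDecay
    if (!is.null(monitor)) {
      model@params <- P
      model@state <- state
      if (isTRUE(monitor(model, it, do.call(rbind, hist)))) break
    }
  }
  model@params <- P
  model@state <- state
  list(model = model, history = do.call(rbind, hist))
}
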