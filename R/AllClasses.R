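#' @import methods
#' @importFrom stats predict rnorm runif setNames
NULL

#' Network architecture configuration
#'
#' Describes the gated-inception convolutional network: five inception stages
#' interleaved with four max-pooling layers, a spatial-pyramid-pooling (SPP)
#' head, and three fully connected layers. The SPP head makes the number of
#' trainable parameters independent of input length, so one parameter set
#' serves every fragment length in \code{[minInputLen, maxInputLen]}.
#'
#' @slot stageVariants character(5), inception variant per conv stage
#'   (\code{"A"}, \code{"B"} or \code{"C"}).
#' @slot stageChannels integer(5), output channels per stage (each divisible
#'   by 4, one quarter per branch); the final entry feeds the SPP head.
#' @slot inceptionAKernels integer, kernel sizes of the parallel branches of
#'   variant A.
#' @slot fcWidths integer(2), widths of the two hidden fully connected layers.
#' @slot sppLevels integer, pyramid levels; each level k splits the final
#'   feature map into k contiguous parts and mean-pools each part.
#' @slot leakyDivisor numeric, divisor a of the leaky rectifier
#'   (y = x for x >= 0, x/a otherwise).
#' @slot dropoutRate numeric in [0,1), dropout probability (training only).
#' @slot bnMomentum numeric, update weight of the batch-norm running
#'   statistics.
#' @slot poolSize integer, kernel and stride of the max-pool stages.
#' @slot minInputLen,maxInputLen integer, supported fragment length range (bp).
#'
#' @seealso \code{\link{modelConfig}}, \code{\link{buildModel}}
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(
    stageVariants    = "character",
    stageChannels    = "integer",
    inceptionAKernels = "integer",
    fcWidths         = "integer",
    sppLevels        = "integer",
    leakyDivisor     = "numeric",
    dropoutRate      = "numeric",
    bnMomentum       = "numeric",
    poolSize         = "integer",
    minInputLen      = "integer",
    maxInputLen      = "integer"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (length(object@stageVariants) != 5L ||
      !all(object@stageVariants %in% c("A", "B", "C")))
    msg <- c(msg, "stageVariants must be five of 'A', 'B', 'C'")
  if (length(object@stageChannels) != 5L || any(object@stageChannels %% 4L != 0L) ||
      any(object@stageChannels < 4L))
    msg <- c(msg, "stageChannels must be five positive multiples of 4")
  if (length(object@fcWidths) != 2L || any(object@fcWidths < 1L))
    msg <- c(msg, "fcWidths must be two positive integers")
  lv <- object@sppLevels
  if (length(lv) == 0L || lv[1] != 1L || any(diff(lv) <= 0))
    msg <- c(msg, "sppLevels must start at 1 and be strictly increasing")
  if (object@leakyDivisor <= 0)
    msg <- c(msg, "leakyDivisor must be positive")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (object@minInputLen < 1L || object@maxInputLen < object@minInputLen)
    msg <- c(msg, "need 1 <= minInputLen <= maxInputLen")
  # four pools of stride poolSize must leave at least max(sppLevels) positions
  shortest <- object@minInputLen
  for (i in 1:4) shortest <- shortest %/% object@poolSize
  if (shortest < max(lv))
    msg <- c(msg, sprintf(
      "minInputLen %d leaves %d positions after 4 pools; need >= %d for SPP",
      object@minInputLen, shortest, max(lv)))
  if (length(msg)) msg else TRUE
})

#' Training schedule configuration
#'
#' Optimizer and schedule settings for multi-scale training: stochastic
#' gradient descent with classical momentum, an exponentially decayed learning
#' rate (one decay per epoch, i.e. per length bin pass), and a fixed
#' mini-batch size. One "iteration" trains one full epoch on every length bin
#' in ascending target-length order.
#'
#' @slot momentum numeric, momentum coefficient.
#' @slot learningRate numeric, initial learning rate.
#' @slot lrDecay numeric in (0,1], multiplicative learning-rate decay.
#' @slot lrDecayPer \code{"epoch"} (decay after every per-bin epoch, the
#'   default) or \code{"iteration"} (decay once per complete pass over all
#'   bins). With many length bins the per-epoch reading compounds the decay
#'   per iteration; per-iteration decay keeps the schedule comparable across
#'   bin counts.
#' @slot batchSize integer, mini-batch size.
#' @slot iterations integer, number of complete passes over all bins.
#' @slot seed integer, RNG seed governing shuffling, dropout and any random
#'   padding splits.
#'
#' @seealso \code{\link{trainConfig}}, \code{\link{trainModel}}
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(
    momentum     = "numeric",
    learningRate = "numeric",
    lrDecay      = "numeric",
    lrDecayPer   = "character",
    batchSize    = "integer",
    iterations   = "integer",
    seed         = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@lrDecay <= 0 || object@lrDecay > 1)
    msg <- c(msg, "lrDecay must be in (0, 1]")
  if (!object@lrDecayPer %in% c("epoch", "iteration"))
    msg <- c(msg, "lrDecayPer must be 'epoch' or 'iteration'")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@iterations < 1L) msg <- c(msg, "iterations must be >= 1")
  if (object@momentum < 0 || object@momentum >= 1)
    msg <- c(msg, "momentum must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' A gated-inception DHS classifier
#'
#' Holds the architecture configuration, the flat named list of trainable
#' parameter arrays, and the batch-normalisation running statistics. Build
#' with \code{\link{buildModel}}; train with \code{\link{trainModel}}; score
#' fragments with \code{predict}.
#'
#' @slot config a \linkS4class{ModelConfig}.
#' @slot params named list of numeric arrays (weights and biases).
#' @slot state named list of non-trainable state (batch-norm running
#'   mean/variance).
#'
#' @exportClass DHSModel
setClass("DHSModel",
  representation(
    config = "ModelConfig",
    params = "list",
    state  = "list"
  )
)

#' Length-binned multi-scale dataset
#'
#' Fragments grouped by length bin, each extended on-chromosome to its bin's
#' target length and one-hot encoded, so that all samples within a bin share
#' one fixed length (the parallel-compute contract) while the bins span the
#' full supported range.
#'
#' @slot bins data.frame with columns \code{low}, \code{high}, \code{target}
#'   (bp); bins tile the configured length range, upper bounds inclusive.
#' @slot samples list of 4 x target x n arrays, one per bin (may be empty).
#' @slot labels list of integer vectors (1 = DHS, 0 = non-DHS), parallel to
#'   \code{samples}.
#' @slot amplification integer, number of distinct padding variants generated
#'   per source fragment.
#'
#' @seealso \code{\link{buildMultiScaleDataset}}
#' @exportClass MultiScaleDataset
setClass("MultiScaleDataset",
  representation(
    bins          = "data.frame",
    samples       = "list",
    labels        = "list",
    amplification = "integer"
  )
)

setValidity("MultiScaleDataset", function(object) {
  msg <- character()
  nb <- nrow(object@bins)
  if (length(object@samples) != nb || length(object@labels) != nb)
    msg <- c(msg, "samples and labels must have one entry per bin")
  for (i in seq_len(nb)) {
    a <- object@samples[[i]]
    if (is.null(a)) next
    if (length(dim(a)) != 3L || dim(a)[1] != 4L ||
        dim(a)[2] != object@bins$target[i])
      msg <- c(msg, sprintf("bin %d: sample array must be 4 x %d x n",
                            i, object@bins$target[i]))
    if (!is.null(a) && dim(a)[3] != length(object@labels[[i]]))
      msg <- c(msg, sprintf("bin %d: labels do not match sample count", i))
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic planted-motif fixture specification
#'
#' Describes a desk-scale synthetic benchmark: random background chromosomes
#' with non-overlapping "DHS" intervals whose sequences each carry at least
#' one exact copy of a short motif, with fragment lengths drawn from a
#' truncated-geometric (decreasing) distribution, emulating the empirical
#' pattern that DHS counts fall with increasing length.
#'
#' @slot nChromosomes integer, chromosome count.
#' @slot chromLength integer, length of each chromosome (bp).
#' @slot nPositives integer, number of planted DHS intervals.
#' @slot motif character, planted motif (alphabet A/C/G/T).
#' @slot motifCopies integer, exact copies planted per positive.
#' @slot minLen,maxLen integer, fragment length range (bp).
#' @slot lengthDecay numeric in (0,1], per-bp geometric decay of the length
#'   distribution (1 = uniform).
#' @slot background numeric(4), background base probabilities (A,C,G,T).
#' @slot seed integer, RNG seed.
#'
#' @seealso \code{\link{fixtureSpec}}, \code{\link{generateFixture}}
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  representation(
    nChromosomes = "integer",
    chromLength  = "integer",
    nPositives   = "integer",
    motif        = "character",
    motifCopies  = "integer",
    minLen       = "integer",
    maxLen       = "integer",
    lengthDecay  = "numeric",
    background   = "numeric",
    seed         = "integer"
  )
)

setValidity("FixtureSpec", function(object) {
  msg <- character()
  if (object@nChromosomes < 1L) msg <- c(msg, "need >= 1 chromosome")
  if (!grepl("^[ACGT]+$", object@motif))
    msg <- c(msg, "motif must be a non-empty A/C/G/T string")
  if (nchar(object@motif) >= object@minLen)
    msg <- c(msg, "motif must be shorter than the minimum fragment length")
  if (object@motifCopies < 1L) msg <- c(msg, "motifCopies must be >= 1")
  if (nchar(object@motif) * object@motifCopies >= object@minLen)
    msg <- c(msg, "motif copies cannot fit disjointly in the shortest fragment")
  if (object@minLen < 1L || object@maxLen < object@minLen)
    msg <- c(msg, "need 1 <= minLen <= maxLen")
  if (object@maxLen > object@chromLength)
    msg <- c(msg, "maxLen exceeds chromosome length")
  if (length(object@background) != 4L || any(object@background < 0) ||
      abs(sum(object@background) - 1) > 1e-8)
    msg <- c(msg, "background must be 4 non-negative probabilities summing to 1")
  if (object@lengthDecay <= 0 || object@lengthDecay > 1)
    msg <- c(msg, "lengthDecay must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Confusion counts
#'
#' The four cells of a binary confusion table (true/false positives and
#' negatives) from which the evaluation statistics are computed.
#'
#' @slot tp,fn,tn,fp integer counts.
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
  representation(tp = "integer", fn = "integer", tn = "integer", fp = "integer")
)

setValidity("ConfusionCounts", function(object) {
  if (any(c(object@tp, object@fn, object@tn, object@fp) < 0L))
    "all counts must be non-negative" else TRUE
})

#' Classification metrics report
#'
#' Sensitivity, specificity, accuracy, Matthews correlation coefficient and
#' (when scores are available) the area under the ROC curve, together with
#' the confusion counts and the score threshold that produced them.
#'
#' @slot sn,sp,acc numeric fractions in [0,1].
#' @slot mcc numeric in [-1,1].
#' @slot auc numeric in [0,1], \code{NA} when computed from counts alone.
#' @slot threshold numeric, positive-call cutoff on the DHS score.
#' @slot counts a \linkS4class{ConfusionCounts}.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(
    sn = "numeric", sp = "numeric", acc = "numeric",
    mcc = "numeric", auc = "numeric", threshold = "numeric",
    counts = "ConfusionCounts"
  )
)

#' Cross-validation fold assignment
#'
#' @slot k integer, number of folds.
#' @slot foldOf integer vector, fold id (1..k) per sample.
#' @slot seed integer, RNG seed used for the assignment.
#' @exportClass FoldAssignment
setClass("FoldAssignment",
  representation(k = "integer", foldOf = "integer", seed = "integer")
)

setValidity("FoldAssignment", function(object) {
  msg <- character()
  if (object@k < 2L) msg <- c(msg, "k must be >= 2")
  if (length(object@foldOf) &&
      (min(object@foldOf) < 1L || max(object@foldOf) > object@k))
    msg <- c(msg, "fold ids must lie in 1..k")
  sz <- tabulate(object@foldOf, nbins = object@k)
  if (length(object@foldOf) && diff(range(sz)) > 1L)
    msg <- c(msg, "fold sizes must differ by at most 1")
  if (length(msg)) msg else TRUE
})

#' Corpus summary statistics
#'
#' Descriptive statistics of a positive/negative fragment corpus: class
#' counts, mean lengths, the positive:negative ratio, a length histogram and
#' per-class mono- and di-nucleotide frequencies.
#'
#' @slot nPositive,nNegative integer counts.
#' @slot meanLength numeric, mean fragment length over both classes (bp).
#' @slot ratio numeric, nPositive / nNegative.
#' @slot lengthHistogram table of counts per length bin.
#' @slot monoFreq,diFreq matrix, per-class (rows) nucleotide /
#'   dinucleotide frequencies (columns).
#' @exportClass CorpusStats
setClass("CorpusStats",
  representation(
    nPositive = "integer", nNegative = "integer",
    meanLength = "numeric", ratio = "numeric",
    lengthHistogram = "table",
    monoFreq = "matrix", diFreq = "matrix"
  )
)
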