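#' Create a network configuration
#'
#' The default configuration is the full classifier: inception variants
#' (A, A, B, B, C) with stage channels (48, 128, 160, 288, 384), SPP levels
#' (1, 2, 4) giving 7 pooled features per channel, and fully connected widths
#' 2688 -> 730 -> 266 -> 2. With batch normalisation on the two hidden FC
#' layers this totals exactly 3,077,382 trainable parameters
#' (see \code{\link{countParameters}}).
#'
#' @param stageVariants inception variant per conv stage.
#' @param stageChannels output channels per stage; each a multiple of 4.
#' @param inceptionAKernels kernel sizes of the variant-A branches.
#' @param fcWidths widths of the two hidden fully connected layers.
#' @param sppLevels pyramid levels of the SPP head.
#' @param leakyDivisor divisor of the leaky rectifier's negative branch.
#' @param dropoutRate dropout probability used during training.
#' @param bnMomentum batch-norm running-statistics update weight.
#' @param poolSize max-pool kernel/stride.
#' @param minInputLen,maxInputLen supported fragment length range (bp).
#' @return a \linkS4class{ModelConfig}.
#' @examples
#' cfg <- modelConfig()
#' cfg
#' @export
modelConfig <- function(stageVariants = c("A", "A", "B", "B", "C"),
                        stageChannels = c(48L, 128L, 160L, 288L, 384L),
                        inceptionAKernels = c(1L, 3L, 5L, 7L),
                        fcWidths = c(730L, 266L),
                        sppLevels = c(1L, 2L, 4L),
                        leakyDivisor = 100,
                        dropoutRate = 0.3,
                        bnMomentum = 0.5,
                        poolSize = 2L,
                        minInputLen = 200L,
                        maxInputLen = 800L) {
  new("ModelConfig",
      stageVariants = as.character(stageVariants),
      stageChannels = as.integer(stageChannels),
      inceptionAKernels = as.integer(inceptionAKernels),
      fcWidths = as.integer(fcWidths),
      sppLevels = as.integer(sppLevels),
      leakyDivisor = as.numeric(leakyDivisor),
      dropoutRate = as.numeric(dropoutRate),
      bnMomentum = as.numeric(bnMomentum),
      poolSize = as.integer(poolSize),
      minInputLen = as.integer(minInputLen),
      maxInputLen = as.integer(maxInputLen))
}

#' Reduced-width configuration for CPU-scale demonstrations
#'
#' Same topology as the default (5 inception stages, 4 max pools, SPP head,
#' 3 FC layers) with far fewer channels, sized so that training on the
#' synthetic planted-motif fixture converges in minutes on one CPU. Used by
#' the worked examples and the scaled-down learning checks.
#'
#' @param dropoutRate dropout probability; the demonstration default is 0.
#'   Dropout after every stage suits the full-width model on large corpora,
#'   but at demonstration width the compounded mask noise across seven
#'   layers drowns the weak early gradient signal and learning never
#'   bootstraps.
#' @return a \linkS4class{ModelConfig}.
#' @export
demoModelConfig <- function(dropoutRate = 0) {
  modelConfig(stageChannels = c(16L, 16L, 24L, 24L, 32L),
              fcWidths = c(64L, 32L),
              dropoutRate = dropoutRate)
}

#' Create a training configuration
#'
#' Defaults are the reference schedule: SGD with momentum 0.98, learning rate
#' 0.002 decayed exponentially by 0.97 after every epoch, mini-batches of 128,
#' and 100 iterations (an iteration = one epoch over every length bin).
#'
#' @param momentum momentum coefficient.
#' @param learningRate initial learning rate.
#' @param lrDecay multiplicative learning-rate decay.
#' @param lrDecayPer apply the decay after every per-bin epoch
#'   (\code{"epoch"}, default) or once per complete iteration over all bins
#'   (\code{"iteration"}); the latter keeps the schedule comparable across
#'   different bin counts.
#' @param batchSize mini-batch size.
#' @param iterations number of complete passes over all bins.
#' @param seed RNG seed for shuffling, dropout and padding splits.
#' @return a \linkS4class{TrainConfig}.
#' @examples
#' trainConfig(iterations = 10)
#' @export
trainConfig <- function(momentum = 0.98, learningRate = 0.002,
                        lrDecay = 0.97, lrDecayPer = c("epoch", "iteration"),
                        batchSize = 128L, iterations = 100L, seed = 1L) {
  new("TrainConfig",
      momentum = as.numeric(momentum),
      learningRate = as.numeric(learningRate),
      lrDecay = as.numeric(lrDecay),
      lrDecayPer = match.arg(lrDecayPer),
      batchSize = as.integer(batchSize),
      iterations = as.integer(iterations),
      seed = as.integer(seed))
}

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig\n")
  cat("  stages:   ", paste0(object@stageVariants, "(", object@stageChannels, ")",
                             collapse = " -> "), "\n")
  cat("  SPP levels:", paste(object@sppLevels, collapse = "+"),
      sprintf("(%d features/channel)", sum(object@sppLevels)), "\n")
  cat("  FC widths: ",
      paste(c(object@stageChannels[5] * sum(object@sppLevels),
              object@fcWidths, 2L), collapse = " -> "), "\n")
  cat(sprintf("  leaky 1/%g, dropout %g, BN momentum %g, input %d-%d bp\n",
              object@leakyDivisor, object@dropoutRate, object@bnMomentum,
              object@minInputLen, object@maxInputLen))
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: SGD momentum %g, lr %g (x%g/epoch), batch %d, %d iterations, seed %d\n",
    object@momentum, object@learningRate, object@lrDecay,
    object@batchSize, object@iterations, object@seed))
})
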