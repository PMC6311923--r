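# End-to-end benchmark on the synthetic planted-motif fixture: corpus
# construction, multi-scale training of the demonstration model, and
# held-out evaluation with a label-shuffled control.

#' Run the scaled-down learning benchmark
#'
#' Generates a planted-motif fixture, builds the corpus (length-matched
#' negatives, redundancy removal, stratified folds), trains the
#' demonstration model with the multi-scale schedule on the training folds
#' (amplification x3, the augmentation used for corpora of this size), and
#' evaluates on the held-out fold at the fragments' original lengths.
#' Optionally trains a label-shuffled control, whose held-out AUC should sit
#' near 0.5, and a single-scale comparison in which every fragment is padded
#' to the maximum length instead of being length-binned.
#'
#' @param spec a \linkS4class{FixtureSpec}.
#' @param iterations maximum training iterations.
#' @param stopAuc stop early once the held-out AUC (computed on
#'   bin-extended fragments after each iteration) reaches this value;
#'   \code{NULL} disables early stopping.
#' @param intervalWidth length-bin width (bp) for multi-scale training.
#' @param amplification padding variants per training fragment.
#' @param folds fold count; fold 1 is held out.
#' @param seed RNG seed for corpus construction, model init and training.
#' @param control also train the label-shuffled control.
#' @param controlIterations iterations for the control run; a shuffled-label
#'   model sits at chance regardless of training length, so a short run
#'   suffices to demonstrate it.
#' @param singleScale also train the pad-to-maximum single-scale comparison.
#' @param config model configuration (default: the reduced-width
#'   demonstration config).
#' @param schedule a \linkS4class{TrainConfig}; defaults to the reference
#'   constants (momentum 0.98, learning rate 0.002 decayed 0.97 per epoch,
#'   batch 128).
#' @param verbose print progress.
#' @return list with \code{report} (held-out \linkS4class{MetricsReport}),
#'   \code{history}, \code{iterationsUsed}, \code{model}, and, when
#'   requested, \code{controlAuc} and \code{singleScaleAuc}.
#' @export
learningBenchmark <- function(spec = fixtureSpec(), iterations = 20L,
                              stopAuc = 0.98, intervalWidth = 200L,
                              amplification = 3L, folds = 4L, seed = 1L,
                              control = FALSE, controlIterations = 3L,
                              singleScale = FALSE,
                              config = demoModelConfig(),
                              schedule = NULL, verbose = FALSE) {
  if (is.null(schedule))
    schedule <- trainConfig(iterations = iterations, seed = seed)
  fx <- generateFixture(spec)
  corpus <- buildCorpus(fx$genome, fx$positives, fx$excluded,
                        minBp = spec@minLen, maxBp = spec@maxLen,
                        k = folds, seed = seed)
  gr <- manifestToGRanges(corpus$manifest)
  heldout <- gr[corpus$manifest$fold == 1L]
  train <- gr[corpus$manifest$fold != 1L]
  msd <- buildMultiScaleDataset(fx$genome, train, intervalWidth,
                                minLen = spec@minLen, maxLen = spec@maxLen,
                                amplification = amplification, seed = seed)
  # a capped, stratified subset of held-out fragments, bin-extended once,
  # serves as the cheap per-iteration convergence monitor
  monIdx <- {
    lab <- mcols(heldout)$label
    set.seed(seed + 2L)
    c(sample(which(lab == "positive"), min(128L, sum(lab == "positive"))),
      sample(which(lab == "negative"), min(128L, sum(lab == "negative"))))
  }
  msdHeld <- buildMultiScaleDataset(fx$genome, heldout[monIdx], intervalWidth,
                                    minLen = spec@minLen,
                                    maxLen = spec@maxLen, seed = seed + 1L)
  quickAuc <- function(model) {
    sc <- numeric(0); yy <- integer(0)
    for (b in seq_len(nrow(msdHeld@bins))) {
      if (!length(msdHeld@labels[[b]])) next
      sc <- c(sc, predict(model, msdHeld@samples[[b]])[, "DHS"])
      yy <- c(yy, msdHeld@labels[[b]])
    }
    rocAuc(sc, yy)
  }
  monitor <- NULL
  if (!is.null(stopAuc))
    monitor <- function(model, it, hist) {
      a <- quickAuc(model)
      if (verbose)
        message(sprintf("iteration %d: held-out AUC %.3f", it, a))
      a >= stopAuc
    }
  runOne <- function(dataset, labelSeed = NULL) {
    ds <- dataset
    sch <- schedule
    if (!is.null(labelSeed)) {      # label-shuffled control
      set.seed(labelSeed)
      ds@labels <- lapply(ds@labels, function(y) y[sample.int(length(y))])
      sch@iterations <- as.integer(controlIterations)
    }
    model <- buildModel(config, seed = seed)
    trainModel(model, ds, sch, verbose = FALSE,
               monitor = if (is.null(labelSeed)) monitor else NULL)
  }
  tr <- runOne(msd)
  report <- evaluateModel(tr$model, fx$genome, heldout)
  out <- list(report = report, history = tr$history,
              iterationsUsed = max(tr$history$iteration),
              model = tr$model, fixture = fx, corpus = corpus,
              heldout = heldout)
  if (control) {
    trC <- runOne(msd, labelSeed = seed + 17L)
    out$controlAuc <- evaluateModel(trC$model, fx$genome, heldout)@auc
  }
  if (singleScale) {
    msd1 <- buildMultiScaleDataset(fx$genome, train,
                                   intervalWidth = spec@maxLen - spec@minLen,
                                   minLen = spec@minLen,
                                   maxLen = spec@maxLen,
                                   amplification = amplification,
                                   seed = seed)
    trS <- runOne(msd1)
    out$singleScaleAuc <- evaluateModel(trS$model, fx$genome, heldout)@auc
  }
  out
}
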