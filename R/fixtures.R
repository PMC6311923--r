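# Synthetic planted-motif fixtures: desk-scale genomes with "DHS" intervals
# that each carry an exact copy of a short motif, so the whole pipeline --
# corpus construction, multi-scale training, evaluation -- runs with no
# external downloads and a known learning target.

#' Create a fixture specification
#'
#' Defaults describe the standard benchmark: two 2 Mb chromosomes of uniform
#' background, 1,000 non-overlapping positives of 200-800 bp whose lengths
#' follow a truncated-geometric (decreasing) distribution, each carrying a
#' cluster of six exact copies of an 8-mer motif at random disjoint
#' internal offsets — accessible regulatory regions are typically occupied
#' by clusters of transcription-factor binding sites, and the cluster size
#' sets the benchmark's signal strength (see the package vignette for the
#' calibration). The chromosome size puts DHS occupancy near 8\% of the
#' genome, the density seen in real plant corpora, which keeps
#' on-chromosome extension noise (a padded negative swallowing a
#' neighbouring DHS) realistically rare.
#'
#' @param nChromosomes chromosome count.
#' @param chromLength chromosome length (bp).
#' @param nPositives number of planted DHS intervals.
#' @param motif planted motif (A/C/G/T string shorter than \code{minLen}).
#' @param motifCopies exact copies planted per positive.
#' @param minLen,maxLen fragment length range (bp).
#' @param lengthDecay per-bp geometric decay of the length distribution;
#'   the default 0.99 makes short fragments roughly 400 times likelier than
#'   the longest, echoing the empirical decrease of DHS counts with length.
#' @param background base probabilities (A, C, G, T).
#' @param seed RNG seed.
#' @return a \linkS4class{FixtureSpec}.
#' @export
fixtureSpec <- function(nChromosomes = 2L, chromLength = 2000000L,
                        nPositives = 1000L, motif = "GATTACGC",
                        motifCopies = 6L, minLen = 200L, maxLen = 800L,
                        lengthDecay = 0.99,
                        background = c(0.25, 0.25, 0.25, 0.25),
                        seed = 1L) {
  new("FixtureSpec",
      nChromosomes = as.integer(nChromosomes),
      chromLength = as.integer(chromLength),
      nPositives = as.integer(nPositives),
      motif = toupper(motif), motifCopies = as.integer(motifCopies),
      minLen = as.integer(minLen), maxLen = as.integer(maxLen),
      lengthDecay = as.numeric(lengthDecay),
      background = as.numeric(background), seed = as.integer(seed))
}

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf(
    "FixtureSpec: %d x %d bp chromosomes, %d positives (%d-%d bp, decay %g),\n  motif %s x%d, seed %d\n",
    object@nChromosomes, object@chromLength, object@nPositives,
    object@minLen, object@maxLen, object@lengthDecay, object@motif,
    object@motifCopies, object@seed))
})

# Truncated-geometric length distribution on [minLen, maxLen].
.length_probs <- function(spec) {
  lens <- spec@minLen:spec@maxLen
  p <- spec@lengthDecay^(lens - spec@minLen)
  p / sum(p)
}

#' Generate a synthetic planted-motif fixture
#'
#' Draws background chromosomes from the spec's base composition, places
#' non-overlapping positive intervals with lengths from the decreasing
#' length distribution, and plants the motif at a uniformly random internal
#' offset of each positive (copies never overlap). Deterministic given the
#' spec's seed. When \code{dir} is given, writes \code{genome.fa},
#' \code{positives.bed}, \code{excluded.bed} and a provenance
#' \code{fixture.json} embedding the spec.
#'
#' @param spec a \linkS4class{FixtureSpec}.
#' @param dir optional output directory.
#' @return list with \code{genome} (\code{DNAStringSet}), \code{positives}
#'   and \code{excluded} (\code{GRanges}; here identical), and \code{spec}.
#' @export
generateFixture <- function(spec = fixtureSpec(), dir = NULL) {
  validObject(spec)
  set.seed(spec@seed)
  bases <- c("A", "C", "G", "T")
  chromNames <- sprintf("chr%d", seq_len(spec@nChromosomes))
  chrs <- vapply(chromNames, function(...)
    paste(sample(bases, spec@chromLength, replace = TRUE,
                 prob = spec@background), collapse = ""), character(1))
  genome <- DNAStringSet(chrs)
  names(genome) <- chromNames

  probs <- .length_probs(spec)
  lens <- sample(spec@minLen:spec@maxLen, spec@nPositives,
                 replace = TRUE, prob = probs)
  occS <- lapply(chromNames, function(...) integer(0))
  occE <- lapply(chromNames, function(...) integer(0))
  names(occS) <- names(occE) <- chromNames
  chrom <- character(spec@nPositives); st <- integer(spec@nPositives)
  for (i in seq_len(spec@nPositives)) {
    ok <- FALSE
    for (att in 1:10000) {
      ch <- sample(chromNames, 1L)
      s <- sample.int(spec@chromLength - lens[i] + 1L, 1L)
      e <- s + lens[i] - 1L
      if (length(occS[[ch]]) && any(s <= occE[[ch]] & e >= occS[[ch]])) next
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place positive ", i, " without overlap; ",
           "genome too small for the requested corpus", call. = FALSE)
    chrom[i] <- ch; st[i] <- s
    occS[[ch]] <- c(occS[[ch]], s); occE[[ch]] <- c(occE[[ch]], e)
  }
  positives <- GRanges(factor(chrom, levels = chromNames),
                       IRanges(st, width = lens))
  mcols(positives)$label <- rep("positive", spec@nPositives)

  # plant motif copies at random internal, mutually disjoint offsets
  m <- nchar(spec@motif)
  at <- vector("list", spec@nChromosomes)
  names(at) <- chromNames
  for (i in seq_len(spec@nPositives)) {
    placedOff <- integer(0)
    for (cp in seq_len(spec@motifCopies)) {
      for (att in 1:1000) {
        off <- sample.int(lens[i] - m + 1L, 1L) - 1L
        if (!length(placedOff) ||
            all(abs(off - placedOff) >= m)) break
        off <- NA_integer_
      }
      if (is.na(off))
        stop("cannot place ", spec@motifCopies,
             " disjoint motif copies in a ", lens[i], " bp fragment",
             call. = FALSE)
      placedOff <- c(placedOff, off)
      at[[chrom[i]]] <- c(at[[chrom[i]]], st[i] + off)
    }
  }
  for (ch in chromNames) {
    if (is.null(at[[ch]])) next
    genome[[ch]] <- Biostrings::replaceAt(
      genome[[ch]], IRanges(at[[ch]], width = m),
      DNAStringSet(rep(spec@motif, length(at[[ch]]))))
  }

  out <- list(genome = genome, positives = positives,
              excluded = positives, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeXStringSet(genome, file.path(dir, "genome.fa"))
    writeBedIntervals(positives, file.path(dir, "positives.bed"))
    writeBedIntervals(positives, file.path(dir, "excluded.bed"))
    sl <- .configAsListGeneric(spec)
    jsonlite::write_json(sl, file.path(dir, "fixture.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

.configAsListGeneric <- function(obj) {
  nms <- slotNames(class(obj))
  setNames(lapply(nms, function(s) slot(obj, s)), nms)
}

#' Expected separability of a fixture
#'
#' Closed-form summary of how hard the planted-motif task is: the motif's
#' information content under the background composition, the probability
#' that a background fragment of given length contains the motif by chance
#' (\code{1 - (1 - p)^(L - m + 1)} with p the per-position motif
#' probability), and the expected fraction of negatives carrying the motif
#' under the spec's length distribution.
#'
#' @param spec a \linkS4class{FixtureSpec}.
#' @param fragmentLength optional length at which to report the chance-hit
#'   rate (default: averaged over the spec's length distribution).
#' @return list with \code{informationBits}, \code{perPositionProb},
#'   \code{chanceHitRate}.
#' @export
fixtureDifficulty <- function(spec, fragmentLength = NULL) {
  validObject(spec)
  m <- nchar(spec@motif)
  if (!is.null(fragmentLength) && fragmentLength < m)
    stop("fragment shorter than the motif", call. = FALSE)
  code <- match(strsplit(spec@motif, "")[[1]], c("A", "C", "G", "T"))
  pPos <- prod(spec@background[code])
  info <- -sum(log2(spec@background[code]))
  hit <- function(L) 1 - (1 - pPos)^(L - m + 1)
  rate <- if (!is.null(fragmentLength)) hit(fragmentLength) else {
    lens <- spec@minLen:spec@maxLen
    sum(.length_probs(spec) * hit(lens))
  }
  list(informationBits = info, perPositionProb = pPos, chanceHitRate = rate)
}

#' Does a fragment contain the motif?
#'
#' The trivial string-matching classifier for planted-motif fixtures: scores
#' 1 when the fragment contains an exact motif copy, else 0. Serves as the
#' separability oracle that guarantees the learning target exists
#' independently of the network.
#'
#' @param sequences character vector of fragments.
#' @param motif motif string.
#' @return numeric 0/1 scores.
#' @export
motifMatchScore <- function(sequences, motif) {
  as.numeric(grepl(motif, as.character(sequences), fixed = TRUE))
}
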