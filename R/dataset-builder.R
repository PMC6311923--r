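# Corpus construction: length filtering, length-matched negative sampling,
# redundancy removal, descriptive statistics, and cross-validation folds.

#' Filter intervals by fragment length
#'
#' Keeps intervals whose length lies in \code{[minBp, maxBp]}, bounds
#' inclusive. The defaults are the supported fragment range of the
#' classifier.
#'
#' @param intervals a \code{GRanges}.
#' @param minBp,maxBp inclusive length bounds (bp).
#' @return the retained \code{GRanges}.
#' @export
filterByLength <- function(intervals, minBp = 200L, maxBp = 800L) {
  stopifnot(minBp >= 1L, maxBp >= minBp)
  intervals[width(intervals) >= minBp & width(intervals) <= maxBp]
}

#' Sample length-matched negatives
#'
#' Draws, for every positive interval, one interval of identical length on
#' the same chromosome that overlaps neither any excluded region (all known
#' DHSs) nor any previously placed negative, so the negative length
#' distribution matches the positive one exactly. Placement is uniform
#' rejection sampling, deterministic given \code{seed}.
#'
#' @param genome a \code{DNAStringSet}.
#' @param positives a \code{GRanges} of positive (DHS) intervals.
#' @param excluded a \code{GRanges} of all regions negatives must avoid
#'   (defaults to the positives themselves).
#' @param seed RNG seed.
#' @param maxAttempts rejection-sampling cap per positive.
#' @return a \code{GRanges} of negatives, parallel to \code{positives}, with
#'   \code{label = "negative"}.
#' @export
sampleNegatives <- function(genome, positives, excluded = positives,
                            seed = 1L, maxAttempts = 10000L) {
  set.seed(seed)
  chromLen <- setNames(nchar(as.character(genome)), names(genome))
  n <- length(positives)
  chroms <- as.character(seqnames(positives))
  lens <- width(positives)
  outChrom <- character(n); outStart <- integer(n)
  # per-chromosome lists of occupied [start,end] (1-based) for overlap checks
  excl <- split(data.frame(s = start(excluded), e = end(excluded)),
                as.character(seqnames(excluded)))
  placedS <- lapply(chromLen, function(...) integer(0))
  placedE <- lapply(chromLen, function(...) integer(0))
  for (i in seq_len(n)) {
    chr <- chroms[i]; len <- lens[i]
    if (!chr %in% names(chromLen))
      stop("positive ", i, ": chromosome '", chr, "' not in genome",
           call. = FALSE)
    room <- chromLen[[chr]] - len
    if (room < 0L)
      stop("positive ", i, ": no feasible placement of length ", len,
           " on ", chr, call. = FALSE)
    ex <- excl[[chr]]
    ok <- FALSE
    for (att in seq_len(maxAttempts)) {
      s <- sample.int(room + 1L, 1L)       # 1-based start in [1, room+1]
      e <- s + len - 1L
      if (!is.null(ex) && any(s <= ex$e & e >= ex$s)) next
      if (length(placedS[[chr]]) &&
          any(s <= placedE[[chr]] & e >= placedS[[chr]])) next
      ok <- TRUE
      break
    }
    if (!ok)
      stop("positive ", i, " (", chr, ":", start(positives)[i] - 1L, "-",
           end(positives)[i], "): no disjoint placement found after ",
           maxAttempts, " attempts", call. = FALSE)
    outChrom[i] <- chr; outStart[i] <- s
    placedS[[chr]] <- c(placedS[[chr]], s)
    placedE[[chr]] <- c(placedE[[chr]], e)
  }
  gr <- GRanges(factor(outChrom, levels = names(genome)),
                IRanges(outStart, width = lens))
  mcols(gr)$label <- rep("negative", n)
  gr
}

# Integer encoding A=0 C=1 G=2 T=3 (N -> NA) of one sequence.
.seq_codes <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
}

# Positions of all k-mer codes (no N) of a coded sequence.
.kmer_codes <- function(codes, k) {
  L <- length(codes)
  if (L < k) return(integer(0))
  v <- numeric(L - k + 1L)
  for (j in 0:(k - 1L)) v <- v * 4 + codes[(1L + j):(L - k + 1L + j)]
  v   # NA where the window contains an N
}

# Ungapped identity of two coded sequences at a given offset
# (offset = posA - posB for aligned positions): matches / shorter length.
.offset_identity <- function(a, b, off) {
  # aligned region: a[i] vs b[i - off]
  lo <- max(1L, 1L + off)
  hi <- min(length(a), length(b) + off)
  if (hi < lo) return(0)
  m <- sum(a[lo:hi] == b[(lo - off):(hi - off)], na.rm = TRUE)
  m / min(length(a), length(b))
}

#' Remove near-identical sequences
#'
#' Greedy redundancy removal in the style of sequence-clustering tools:
#' sequences are visited longest first, and a sequence is dropped when its
#' identity to any already-kept sequence reaches the threshold. Identity is
#' matches divided by the shorter sequence's length at the best ungapped
#' offset; candidate offsets are seeded by shared k-mers (k = 8 at the
#' default threshold), which is exact for thresholds around 0.9 and above
#' because any qualifying alignment must contain a shared 8-mer.
#'
#' @param sequences character vector (or \code{DNAStringSet}) of fragment
#'   sequences.
#' @param identityThreshold drop threshold in (0.5, 1].
#' @return logical vector marking the kept sequences (order-deterministic);
#'   use \code{sequences[removeRedundant(sequences)]} for the kept set.
#' @export
removeRedundant <- function(sequences, identityThreshold = 0.9) {
  stopifnot(identityThreshold > 0.5, identityThreshold <= 1)
  seqs <- as.character(sequences)
  n <- length(seqs)
  if (n == 0L) return(logical(0))
  k <- if (identityThreshold >= 0.88) 9L else
    max(4L, min(9L, floor(identityThreshold / (1 - identityThreshold))))
  ord <- order(-nchar(seqs), seq_len(n))   # longest first, stable
  codes <- lapply(seqs, .seq_codes)
  keep <- logical(n)
  index <- new.env(parent = emptyenv())  # k-mer code -> list of c(seqIdx, pos)
  for (i in ord) {
    ci <- codes[[i]]
    km <- .kmer_codes(ci, k)
    pos <- which(!is.na(km))
    # collect (kept sequence, offset) hits from shared k-mers
    hitIdx <- integer(0); hitOff <- integer(0)
    for (p in pos) {
      hits <- index[[as.character(km[p])]]
      if (is.null(hits)) next
      for (h in hits) {
        hitIdx <- c(hitIdx, h[1]); hitOff <- c(hitOff, p - h[2])
      }
    }
    drop <- FALSE
    if (length(hitIdx)) {
      # a qualifying ungapped alignment carries many diagonal k-mer matches;
      # requiring a few seeds screens out chance k-mer collisions
      key <- paste0(hitIdx, "@", hitOff)
      cnt <- table(key)
      minSeeds <- max(1L, min(3L, length(ci) - k + 1L))
      for (ck in names(cnt)[cnt >= minSeeds]) {
        h <- strsplit(ck, "@", fixed = TRUE)[[1]]
        j <- as.integer(h[1]); off <- as.integer(h[2])
        if (.offset_identity(ci, codes[[j]], off) >= identityThreshold) {
          drop <- TRUE
          break
        }
      }
    }
    if (!drop) {
      keep[i] <- TRUE
      for (p in pos) {
        key <- as.character(km[p])
        index[[key]] <- c(index[[key]], list(c(i, p)))
      }
    }
  }
  keep
}

#' Descriptive corpus statistics
#'
#' Class counts, mean fragment length, positive:negative ratio, a length
#' histogram, and per-class mono- and di-nucleotide frequencies.
#'
#' @param positives,negatives \code{GRanges} of the two classes.
#' @param genome a \code{DNAStringSet}.
#' @param binWidth length-histogram bin width (bp).
#' @return a \linkS4class{CorpusStats}.
#' @export
corpusStats <- function(positives, negatives, genome, binWidth = 50L) {
  stopifnot(length(positives) > 0L, length(negatives) > 0L)
  lens <- c(width(positives), width(negatives))
  brk <- seq(floor(min(lens) / binWidth) * binWidth,
             ceiling(max(lens) / binWidth) * binWidth, by = binWidth)
  if (length(brk) < 2L) brk <- c(brk, brk + binWidth)
  hist <- table(cut(lens, breaks = brk, include.lowest = TRUE, right = TRUE))
  freqs <- function(gr) {
    ss <- DNAStringSet(extractFragments(genome, gr))
    mono <- colSums(oligonucleotideFrequency(ss, 1L))
    di <- colSums(oligonucleotideFrequency(ss, 2L))
    list(mono = mono / sum(mono), di = di / sum(di))
  }
  fp <- freqs(positives); fn <- freqs(negatives)
  new("CorpusStats",
      nPositive = length(positives), nNegative = length(negatives),
      meanLength = mean(lens),
      ratio = length(positives) / length(negatives),
      lengthHistogram = hist,
      monoFreq = rbind(positive = fp$mono, negative = fn$mono),
      diFreq = rbind(positive = fp$di, negative = fn$di))
}

setMethod("show", "CorpusStats", function(object) {
  cat(sprintf("CorpusStats: %d positives, %d negatives (ratio %.2f), mean length %.1f bp\n",
              object@nPositive, object@nNegative, object@ratio,
              object@meanLength))
  cat("  mononucleotide frequencies:\n")
  print(round(object@monoFreq, 3))
})

#' Assign stratified cross-validation folds
#'
#' Random fold assignment stratified by class label: within each class the
#' fold sizes differ by at most one, and classes are filled round-robin so
#' overall fold sizes also differ by at most one. Deterministic given
#' \code{seed}.
#'
#' @param labels class label per sample (any vector; typically
#'   "positive"/"negative").
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return a \linkS4class{FoldAssignment}.
#' @export
makeFolds <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k = ", k, " exceeds sample count ", n, call. = FALSE)
  set.seed(seed)
  foldOf <- integer(n)
  cursor <- 0L     # global round-robin cursor keeps overall sizes balanced
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    foldOf[idx] <- ((cursor + seq_along(idx) - 1L) %% k) + 1L
    cursor <- (cursor + length(idx)) %% k
  }
  new("FoldAssignment", k = k, foldOf = foldOf, seed = as.integer(seed))
}

#' Build a complete corpus from genome and DHS intervals
#'
#' Runs the full recipe: length filtering of positives, length-matched
#' negative sampling away from all excluded regions, greedy redundancy
#' removal over both classes jointly, and stratified fold assignment. Two
#' construction invariants are asserted on every build: the negative length
#' multiset equals the positive length multiset (before redundancy removal),
#' and no negative overlaps any excluded interval.
#'
#' @param genome a \code{DNAStringSet}.
#' @param positives \code{GRanges} of DHS intervals.
#' @param excluded \code{GRanges} of all regions negatives must avoid
#'   (default: the unfiltered positives).
#' @param minBp,maxBp fragment length bounds (bp).
#' @param identityThreshold redundancy-removal threshold; \code{NULL} skips
#'   the step.
#' @param k number of cross-validation folds.
#' @param seed RNG seed (negative placement and fold assignment).
#' @return a list with \code{positives}, \code{negatives} (\code{GRanges}),
#'   \code{folds} (\linkS4class{FoldAssignment} over the combined corpus) and
#'   \code{manifest} (data.frame: id, chrom, start, end, label, fold;
#'   coordinates 0-based half-open).
#' @export
buildCorpus <- function(genome, positives, excluded = positives,
                        minBp = 200L, maxBp = 800L,
                        identityThreshold = 0.9, k = 5L, seed = 1L) {
  pos <- filterByLength(positives, minBp, maxBp)
  if (length(pos) == 0L) stop("no positives in length range", call. = FALSE)
  neg <- sampleNegatives(genome, pos, excluded, seed = seed)
  stopifnot(identical(sort(width(neg)), sort(width(pos))))
  stopifnot(!any(countOverlaps(neg, excluded) > 0L))
  if (!is.null(identityThreshold)) {
    seqsP <- extractFragments(genome, pos)
    seqsN <- extractFragments(genome, neg)
    keep <- removeRedundant(c(seqsP, seqsN), identityThreshold)
    pos <- pos[keep[seq_along(seqsP)]]
    neg <- neg[keep[length(seqsP) + seq_along(seqsN)]]
  }
  mcols(pos)$label <- rep("positive", length(pos))
  mcols(neg)$label <- rep("negative", length(neg))
  all <- c(pos, neg)
  labels <- mcols(all)$label
  folds <- makeFolds(labels, k = k, seed = seed)
  manifest <- data.frame(
    id = sprintf("frag%05d", seq_along(all)),
    chrom = as.character(seqnames(all)),
    start = start(all) - 1L, end = end(all),
    label = labels, fold = folds@foldOf,
    stringsAsFactors = FALSE)
  list(positives = pos, negatives = neg, folds = folds, manifest = manifest)
}

#' Read / write a corpus manifest
#'
#' The manifest is the tab-separated exchange format between corpus
#' construction, training and evaluation: columns id, chrom, start, end
#' (0-based half-open), label, fold.
#'
#' @param manifest a manifest data.frame.
#' @param path file path.
#' @return \code{readManifest} returns the manifest data.frame.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("id", "chrom", "start", "end", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

# GRanges view of a manifest (1-based internal convention).
manifestToGRanges <- function(manifest) {
  gr <- GRanges(manifest$chrom,
                IRanges(manifest$start + 1L, manifest$end))
  mcols(gr)$label <- manifest$label
  if (!is.null(manifest$fold)) mcols(gr)$fold <- manifest$fold
  gr
}
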