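# Small in-code fixtures shared across tests.

randomSeq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A deterministic two-chromosome toy genome.
toyGenome <- function(len = 2000L, seed = 11L) {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(c(chr1 = randomSeq(len), chr2 = randomSeq(len)))
  g
}

# GRanges helper (1-based internal convention).
gr <- function(chrom, start1, end1, label = NULL) {
  out <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1))
  if (!is.null(label)) S4Vectors::mcols(out)$label <- label
  out
}

writeTempFasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(nm)
    c(paste0(">", nm), records[[nm]]))), path)
  path
}

writeTempBed <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}

# A small planted-motif fixture spec sized for fast tests.
smallFixtureSpec <- function(seed = 7L, nPositives = 60L)
  fixtureSpec(nChromosomes = 2L, chromLength = 150000L,
              nPositives = nPositives, seed = seed)

# Brute-force same-padded convolution oracle (independent of the engine).
naiveConv <- function(x, W, b, k) {
  # x: C x L matrix; W: O x (C*k); returns O x L
  C <- nrow(x); L <- ncol(x); O <- nrow(W)
  p <- (k - 1) %/% 2
  out <- matrix(0, O, L)
  for (o in seq_len(O)) {
    for (l in seq_len(L)) {
      acc <- b[o]
      for (j in seq_len(k)) {
        src <- l + j - 1 - p
        if (src >= 1 && src <= L)
          for (c in seq_len(C))
            acc <- acc + W[o, (j - 1) * C + c] * x[c, src]
      }
      out[o, l] <- acc
    }
  }
  out
}

naiveGatedConv <- function(x, w) {
  lin <- naiveConv(x, w$Wl, w$bl, w$k)
  gate <- naiveConv(x, w$Wg, w$bg, w$k)
  lin * (1 / (1 + exp(-gate)))
}

# Exhaustive pairwise-concordance AUC oracle.
naiveAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
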