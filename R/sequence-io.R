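# Genome / interval I/O and fragment encoding.
#
# Intervals are held as GRanges (1-based, closed) in memory; BED files are
# read and written in the standard 0-based half-open convention, converted at
# the file boundary.

#' @importFrom Biostrings readBStringSet DNAStringSet writeXStringSet
#'   oligonucleotideFrequency subseq
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   countOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits
NULL

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a genome from FASTA
#'
#' Reads a multi-record (optionally line-wrapped) FASTA file. Record names
#' are the first whitespace-delimited token of each header; lowercase bases
#' are uppercased; any character outside A/C/G/T/N is a format error.
#'
#' @param path FASTA file.
#' @return a \code{DNAStringSet}, one entry per record.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  seqs <- tryCatch(readBStringSet(path),
                   error = function(e)
                     stop("malformed FASTA in ", path, ": ",
                          conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L)
    stop("malformed FASTA in ", path, ": no records", call. = FALSE)
  chr <- toupper(as.character(seqs))
  bad <- grepl(sprintf("[^%s]", paste(.DNA_ALPHABET, collapse = "")), chr)
  if (any(bad))
    stop("record '", sub("\\s.*", "", names(seqs)[which(bad)[1]]),
         "' contains characters outside {A,C,G,T,N}", call. = FALSE)
  if (any(nchar(chr) == 0L))
    stop("record '", sub("\\s.*", "", names(seqs)[which(nchar(chr) == 0L)[1]]),
         "' is empty", call. = FALSE)
  out <- DNAStringSet(chr)
  names(out) <- sub("\\s.*", "", names(seqs))
  out
}

#' Read labeled intervals from a BED file
#'
#' Parses a 3+ column tab-separated BED file (0-based half-open coordinates);
#' extra columns are ignored. Malformed lines (non-integer or negative
#' coordinates, start >= end, fewer than 3 fields) raise a format error
#' naming the offending line. An empty file yields an empty result.
#'
#' @param path BED file.
#' @param label class label attached to every interval, \code{"positive"}
#'   or \code{"negative"}.
#' @return a \code{GRanges} (1-based) with a \code{label} metadata column.
#' @export
readBedIntervals <- function(path, label = c("positive", "negative")) {
  label <- match.arg(label)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) {
    gr <- GRanges()
    mcols(gr)$label <- character(0)
    return(gr)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- character(length(lines))
  s <- integer(length(lines)); e <- integer(length(lines))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L)
      stop("BED format error at line ", i, ": fewer than 3 fields",
           call. = FALSE)
    si <- suppressWarnings(as.integer(p[2]))
    ei <- suppressWarnings(as.integer(p[3]))
    if (is.na(si) || is.na(ei))
      stop("BED format error at line ", i, ": non-integer coordinates",
           call. = FALSE)
    if (si < 0L || ei < 0L)
      stop("BED format error at line ", i, ": negative coordinates",
           call. = FALSE)
    if (si >= ei)
      stop("BED format error at line ", i, ": start >= end", call. = FALSE)
    chrom[i] <- p[1]; s[i] <- si; e[i] <- ei
  }
  gr <- GRanges(chrom, IRanges(start = s + 1L, end = e))
  mcols(gr)$label <- rep(label, length(gr))
  gr
}

#' Write intervals to a BED3 file
#'
#' @param gr a \code{GRanges} (1-based, as produced by this package).
#' @param path output file; written tab-separated, 0-based half-open.
#' @return \code{path}, invisibly.
#' @export
writeBedIntervals <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract fragment sequences for intervals
#'
#' Returns the forward-strand sequence under each interval (the pipeline is
#' forward-strand only by default; no reverse-complement augmentation).
#' Unknown chromosomes or out-of-bounds coordinates raise a coordinate
#' error.
#'
#' @param genome a \code{DNAStringSet} of chromosomes.
#' @param intervals a \code{GRanges}.
#' @param reverseComplement return the reverse complement of each fragment
#'   instead of the forward strand (off by default).
#' @return character vector of fragment sequences, one per interval, each of
#'   length \code{width(intervals)}.
#' @export
extractFragments <- function(genome, intervals, reverseComplement = FALSE) {
  chroms <- as.character(seqnames(intervals))
  unknown <- !(chroms %in% names(genome))
  if (any(unknown))
    stop("unknown chromosome '", chroms[which(unknown)[1]], "'",
         call. = FALSE)
  clen <- nchar(as.character(genome))[match(chroms, names(genome))]
  oob <- start(intervals) < 1L | end(intervals) > clen
  if (any(oob)) {
    i <- which(oob)[1]
    stop("interval [", start(intervals)[i] - 1L, ", ", end(intervals)[i],
         ") out of bounds on ", chroms[i], " (length ", clen[i], ")",
         call. = FALSE)
  }
  out <- character(length(intervals))
  for (chr in unique(chroms)) {
    idx <- which(chroms == chr)
    out[idx] <- as.character(Biostrings::extractAt(
      genome[[chr]], IRanges(start(intervals)[idx], end(intervals)[idx])))
  }
  if (reverseComplement)
    out <- as.character(Biostrings::reverseComplement(DNAStringSet(out)))
  out
}

#' One-hot encode a nucleotide sequence
#'
#' Encodes a fragment as an n x 4 matrix over the fixed column order
#' A, C, G, T: unambiguous bases get a single 1; N rows are uniform 0.25 so
#' every row sums to 1. Characters outside A/C/G/T/N are an encoding error.
#'
#' @param seq nucleotide string.
#' @return n x 4 numeric matrix with colnames A, C, G, T.
#' @examples
#' oneHotEncode("ACGT")   # the 4 x 4 identity matrix
#' @export
oneHotEncode <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "T"))
  bad <- is.na(code) & chars != "N"
  if (any(bad))
    stop("cannot encode character '", chars[which(bad)[1]], "' at position ",
         which(bad)[1], call. = FALSE)
  M <- matrix(0, length(chars), 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  known <- !is.na(code)
  M[cbind(which(known), code[known])] <- 1
  M[!known, ] <- 0.25
  M
}

#' Decode a one-hot matrix back to sequence
#'
#' Takes the per-row argmax over the A, C, G, T columns; uniform (N) rows
#' decode to \code{"N"}.
#'
#' @param mat an n x 4 one-hot matrix.
#' @return nucleotide string.
#' @export
oneHotDecode <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) == 4L)
  bases <- c("A", "C", "G", "T")
  out <- vapply(seq_len(nrow(mat)), function(i) {
    r <- mat[i, ]
    if (max(r) - min(r) < 1e-12) "N" else bases[which.max(r)]
  }, character(1))
  paste(out, collapse = "")
}
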