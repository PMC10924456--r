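# Degenerate (strand-merged) oligonucleotide alphabet and composition
# counting. Genome assemblies deposit an arbitrary one of the two
# complementary strands, so a k-mer and its reverse complement are counted
# as one class; this makes composition vectors strand-invariant.

.revcompChar <- function(x) {
  # reverse complement of character k-mers without DNAStringSet overhead
  vapply(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Build the degenerate oligonucleotide class index
#'
#' Enumerates all `4^k` k-mers over \{A,C,G,T\} and merges each with its
#' reverse complement into a single canonical class. The canonical member is
#' the lexicographically smaller of the pair; classes are ordered
#' lexicographically by canonical member. Non-palindromic classes are
#' labelled `"GA+TC"`-style (canonical member first); self-complementary
#' k-mers keep their own label. The class count is `4^k / 2` for odd k and
#' `(4^k + 4^(k/2)) / 2` for even k (e.g. 10 dinucleotide, 32 trinucleotide,
#' 136 tetranucleotide and 512 pentanucleotide classes).
#'
#' @param k Oligonucleotide length, 1..8 (the pipeline uses 2..5).
#' @return A [DegeClassIndex].
#' @examples
#' idx <- buildDegeIndex(2)
#' length(idx)          # 10
#' degeClasses(idx)[1:4]
#' @export
buildDegeIndex <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1L) {
    stop("k must be a single integer >= 1")
  }
  if (k > 8L) stop("k > 8 not supported (alphabet grows as 4^k)")
  k <- as.integer(k)
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)
  ))
  canon <- ifelse(kmers <= rc, kmers, rc)
  canonU <- sort(unique(canon), method = "radix")
  rcU <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(canonU)
  ))
  labels <- ifelse(canonU == rcU, canonU, paste0(canonU, "+", rcU))
  new("DegeClassIndex",
    k = k,
    classes = labels,
    kmerToClass = setNames(match(canon, canonU), kmers)
  )
}

#' Members of a degenerate class label
#'
#' Splits a class label such as `"GA+TC"` into its member k-mers; a single
#' k-mer label (e.g. `"CG"`) is returned as-is.
#'
#' @param label Class label string.
#' @return Character vector of one or two k-mers.
#' @export
degeClassMembers <- function(label) {
  members <- strsplit(label, "+", fixed = TRUE)[[1]]
  if (!all(grepl("^[ACGT]+$", members)) ||
      length(unique(nchar(members))) != 1L) {
    stop("malformed class label: ", label)
  }
  unique(members)
}

.asDNA <- function(sequence) {
  if (is(sequence, "DNAString")) return(sequence)
  if (is.character(sequence) && length(sequence) == 1L) {
    return(Biostrings::DNAString(sequence))
  }
  stop("sequence must be a single character string or DNAString")
}

#' Degenerate composition of one sequence
#'
#' Slides a width-k window with step 1 over the sequence; windows containing
#' N are skipped. Each valid window increments its strand-merged class; the
#' percentage vector is `100 * counts / validCount`. A sequence with no
#' valid window (shorter than k, or all windows containing N) yields an
#' all-zero vector with `validCount = 0`.
#'
#' @param sequence Character string or [Biostrings::DNAString] over
#'   \{A,C,G,T,N\}.
#' @param index A [DegeClassIndex].
#' @return List with `percent` (named numeric over classes), `counts`
#'   (named integer over classes) and `validCount`.
#' @examples
#' idx <- buildDegeIndex(2)
#' countComposition("ACGT", idx)$percent[c("AC+GT", "CG")]
#' @export
countComposition <- function(sequence, index) {
  stopifnot(is(index, "DegeClassIndex"))
  dna <- .asDNA(sequence)
  counts4 <- Biostrings::oligonucleotideFrequency(dna, width = index@k)
  cls <- .foldCounts(counts4, index)
  valid <- sum(counts4)
  pct <- if (valid > 0) 100 * cls / valid else cls * 0
  list(percent = pct, counts = cls, validCount = valid)
}

# fold raw 4^k counts (vector or matrix with k-mer columns) onto classes
.foldCounts <- function(counts4, index) {
  nc <- length(index@classes)
  if (is.matrix(counts4)) {
    folded <- matrix(0, nrow = nrow(counts4), ncol = nc,
                     dimnames = list(NULL, index@classes))
    map <- index@kmerToClass[colnames(counts4)]
    for (j in seq_len(ncol(counts4))) {
      folded[, map[j]] <- folded[, map[j]] + counts4[, j]
    }
    folded
  } else {
    folded <- as.vector(tapply(counts4, index@kmerToClass[names(counts4)], sum))
    setNames(folded, index@classes)
  }
}

#' Composition matrix of tiled fragments
#'
#' Extracts each fragment's sequence, counts its degenerate composition and
#' assembles the fragments x classes percentage matrix. Fragments with no
#' valid k-mer window are excluded (with a message). Rows follow fragment
#' order.
#'
#' @param records [Biostrings::DNAStringSet] of source sequences with a
#'   `species` metadata column (see [readGenomeFasta()]).
#' @param fragments [GenomicRanges::GRanges] of fragment coordinates as
#'   produced by [tileWindows()].
#' @param index A [DegeClassIndex].
#' @return A [CompositionMatrix].
#' @export
compositionMatrix <- function(records, fragments, index) {
  stopifnot(is(records, "DNAStringSet"), is(fragments, "GRanges"),
            is(index, "DegeClassIndex"))
  if (length(fragments) == 0L) stop("no fragments supplied")
  src <- as.character(GenomicRanges::seqnames(fragments))
  if (!all(src %in% names(records))) {
    stop("fragments refer to sources absent from records: ",
         paste(setdiff(src, names(records)), collapse = ", "))
  }
  seqs <- Biostrings::subseq(
    records[src],
    start = GenomicRanges::start(fragments),
    end = GenomicRanges::end(fragments)
  )
  counts4 <- Biostrings::oligonucleotideFrequency(seqs, width = index@k)
  folded <- .foldCounts(counts4, index)
  valid <- rowSums(folded)
  keep <- valid > 0
  if (!all(keep)) {
    message(sum(!keep), " fragment(s) with no valid k-mer window excluded")
  }
  if (!any(keep)) stop("all fragments lack valid k-mer windows")
  pct <- 100 * folded[keep, , drop = FALSE] / valid[keep]
  new("CompositionMatrix",
    values = pct,
    fragments = fragments[keep],
    index = index,
    validCounts = valid[keep]
  )
}

#' Write / read a composition matrix as TSV
#'
#' Provenance columns (`species`, `source`, `start`, `end`,
#' `valid_fraction`, `valid_count`) come first, followed by one column per
#' degenerate class. Coordinates are 0-based half-open.
#'
#' @param x A [CompositionMatrix].
#' @param path Output / input file path.
#' @return `writeCompositionTSV` returns `path` invisibly;
#'   `readCompositionTSV` returns a [CompositionMatrix].
#' @export
writeCompositionTSV <- function(x, path) {
  stopifnot(is(x, "CompositionMatrix"))
  fr <- x@fragments
  df <- data.frame(
    species = S4Vectors::mcols(fr)$species,
    source = as.character(GenomicRanges::seqnames(fr)),
    start = GenomicRanges::start(fr) - 1L,
    end = GenomicRanges::end(fr),
    valid_fraction = S4Vectors::mcols(fr)$valid_fraction,
    valid_count = x@validCounts,
    check.names = FALSE
  )
  df <- cbind(df, as.data.frame(x@values, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCompositionTSV
#' @param k Oligonucleotide length of the stored matrix (needed to rebuild
#'   the index on read).
#' @export
readCompositionTSV <- function(path, k) {
  df <- read.delim(path, check.names = FALSE)
  index <- buildDegeIndex(k)
  meta <- c("species", "source", "start", "end", "valid_fraction",
            "valid_count")
  if (!all(meta %in% colnames(df)) ||
      !all(index@classes %in% colnames(df))) {
    stop("file does not look like a k = ", k, " composition TSV")
  }
  fr <- GenomicRanges::GRanges(
    seqnames = df$source,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    species = df$species,
    valid_fraction = df$valid_fraction
  )
  new("CompositionMatrix",
    values = as.matrix(df[, index@classes, drop = FALSE]),
    fragments = fr,
    index = index,
    validCounts = df$valid_count
  )
}
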