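# Chromosomal window tracks: dinucleotide/oligonucleotide frequency and
# motif occurrence counts along a chromosome, with robust-z peak flagging.
# Track windowing reuses the ingest tiling (same 0-based half-open windows,
# trailing partial window discarded).

#' Frequency track along one chromosome
#'
#' Tiles a record into fixed windows and reports, per window, the percentage
#' of a degenerate oligonucleotide class (e.g. `"GA+TC"`, `"CG"`),
#' N-containing k-mer windows excluded. Windows without any valid k-mer
#' window get `NA` (flagged missing).
#'
#' @param record A [Biostrings::DNAString], single-record
#'   [Biostrings::DNAStringSet], or character string.
#' @param windowSize Window size in bases.
#' @param classLabel Degenerate class label.
#' @return [GenomicRanges::GRanges] with a `value` metadata column
#'   (percent); `metadata()$value_kind` is `"frequency_percent"`.
#' @export
frequencyTrack <- function(record, windowSize, classLabel) {
  rec <- .asSingleRecord(record)
  members <- degeClassMembers(classLabel)
  k <- nchar(members[1])
  gr <- tileWindows(rec, windowSize, minValidFraction = 0)
  if (length(gr) == 0L) return(.emptyTrack("frequency_percent"))
  seqs <- Biostrings::subseq(rec[rep(1L, length(gr))],
                             start = GenomicRanges::start(gr),
                             end = GenomicRanges::end(gr))
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  valid <- rowSums(counts)
  val <- ifelse(valid > 0,
                100 * rowSums(counts[, members, drop = FALSE]) / valid,
                NA_real_)
  S4Vectors::mcols(gr)$value <- val
  S4Vectors::metadata(gr)$value_kind <- "frequency_percent"
  S4Vectors::metadata(gr)$class_label <- classLabel
  gr
}

.asSingleRecord <- function(record) {
  if (is(record, "DNAStringSet")) {
    stopifnot(length(record) == 1L)
    if (is.null(S4Vectors::mcols(record)$species)) {
      S4Vectors::mcols(record)$species <- "unknown"
    }
    return(record)
  }
  dna <- .asDNA(record)
  out <- Biostrings::DNAStringSet(list(dna))
  names(out) <- "seq1"
  S4Vectors::mcols(out)$species <- "unknown"
  out
}

.emptyTrack <- function(kind) {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr)$value <- numeric(0)
  S4Vectors::metadata(gr)$value_kind <- kind
  gr
}

#' Build a strand-merged motif set
#'
#' Fixed-length motifs (e.g. degenerate pentanucleotides used as consensus
#' core elements of transcription-factor binding motifs). With
#' `strandMerged = TRUE` each motif's reverse complement is added; the set
#' is deduplicated.
#'
#' @param motifs Character vector of same-length A/C/G/T strings, or a path
#'   to a plain-text file with one motif per line.
#' @param name Set name.
#' @param strandMerged Add reverse complements (default `TRUE`).
#' @return A [Biostrings::DNAStringSet] with `metadata()$name` and
#'   `metadata()$strand_merged`.
#' @export
makeMotifSet <- function(motifs, name = "motifs", strandMerged = TRUE) {
  if (length(motifs) == 1L && file.exists(motifs)) {
    motifs <- readLines(motifs)
    motifs <- motifs[nzchar(trimws(motifs))]
  }
  motifs <- toupper(trimws(motifs))
  if (length(motifs) == 0L) stop("empty motif set")
  if (!all(grepl("^[ACGT]+$", motifs))) {
    stop("motifs must contain only A/C/G/T")
  }
  if (length(unique(nchar(motifs))) != 1L) {
    stop("motifs must all have the same length")
  }
  if (strandMerged) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(motifs)))
    motifs <- unique(c(motifs, rc))
  } else {
    motifs <- unique(motifs)
  }
  out <- Biostrings::DNAStringSet(motifs)
  names(out) <- motifs
  S4Vectors::metadata(out)$name <- name
  S4Vectors::metadata(out)$strand_merged <- strandMerged
  out
}

#' Motif occurrence track along one chromosome
#'
#' Per fixed window, the number of exact (overlapping) occurrences of any
#' motif in the set. N positions never match, so only N-free matches are
#' counted.
#'
#' @inheritParams frequencyTrack
#' @param motifs A motif set from [makeMotifSet()].
#' @return [GenomicRanges::GRanges] with a `value` metadata column (count);
#'   `metadata()$value_kind` is `"motif_count"`.
#' @export
motifTrack <- function(record, windowSize, motifs) {
  stopifnot(is(motifs, "DNAStringSet"), length(motifs) > 0)
  rec <- .asSingleRecord(record)
  if (max(Biostrings::width(motifs)) > windowSize) {
    stop("motif longer than window")
  }
  gr <- tileWindows(rec, windowSize, minValidFraction = 0)
  if (length(gr) == 0L) return(.emptyTrack("motif_count"))
  seqs <- Biostrings::subseq(rec[rep(1L, length(gr))],
                             start = GenomicRanges::start(gr),
                             end = GenomicRanges::end(gr))
  counts <- Reduce(`+`, lapply(as.character(motifs), function(m) {
    Biostrings::vcountPattern(m, seqs)
  }))
  S4Vectors::mcols(gr)$value <- counts
  S4Vectors::metadata(gr)$value_kind <- "motif_count"
  S4Vectors::metadata(gr)$motif_set <- S4Vectors::metadata(motifs)$name
  gr
}

#' Flag peak windows in a track
#'
#' Robust z-score rule: windows whose value exceeds
#' `median + zThreshold * mad` (MAD scaled by 1.4826 for normal
#' consistency) are flagged. MAD scaling keeps the rule usable on
#' heavy-tailed tracks; a flat track yields no flags.
#'
#' @param track A track from [frequencyTrack()] or [motifTrack()].
#' @param zThreshold Robust z threshold (default 5).
#' @return Integer vector of flagged window indices (1-based, in track
#'   order).
#' @export
flagPeaks <- function(track, zThreshold = 5) {
  v <- S4Vectors::mcols(track)$value
  ok <- is.finite(v)
  if (sum(ok) < 10L) stop("need at least 10 non-missing windows")
  med <- median(v[ok])
  scale <- mad(v[ok])
  which(ok & v > med + zThreshold * scale)
}

#' Export a track as BED-like TSV
#'
#' Four columns: chrom, start, end (0-based half-open), value.
#'
#' @param track A track `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTrackTSV <- function(track, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(track)),
    start = GenomicRanges::start(track) - 1L,
    end = GenomicRanges::end(track),
    value = S4Vectors::mcols(track)$value
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
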