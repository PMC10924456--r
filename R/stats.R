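# Fragment- and chromosome-level composition statistics. All statistics
# exclude N: G+C% is taken over counted A/C/G/T bases only, and dinucleotide
# frequencies are taken over step-1 overlapping windows free of N.

.monoCounts <- function(sequence) {
  dna <- .asDNA(sequence)
  Biostrings::letterFrequency(dna, letters = c("A", "C", "G", "T"))
}

#' G+C percentage of a sequence
#'
#' `100 * (G + C) / (A + C + G + T)`; N bases are excluded from both
#' numerator and denominator.
#'
#' @param sequence Character string or [Biostrings::DNAString].
#' @return Percentage, or `NA` (with a warning) when the sequence has no
#'   A/C/G/T base.
#' @export
gcPercent <- function(sequence) {
  m <- .monoCounts(sequence)
  tot <- sum(m)
  if (tot == 0) {
    warning("no A/C/G/T bases; G+C% undefined")
    return(NA_real_)
  }
  100 * (m[["G"]] + m[["C"]]) / tot
}

#' Dinucleotide (or any degenerate class) percentage
#'
#' Percentage of step-1 overlapping k-mer windows matching the class, with
#' N-containing windows excluded. The class may be a single k-mer
#' (`"CG"`) or a strand-merged pair (`"GA+TC"`); merged-pair percentages are
#' identical on a sequence and its reverse complement.
#'
#' @param sequence Character string or [Biostrings::DNAString].
#' @param classLabel Class label, e.g. `"CG"` or `"GA+TC"`.
#' @return Percentage, or `NA` (with a warning) when no valid window exists.
#' @examples
#' dinucleotidePercent("CGCG", "CG")      # 66.67: windows CG, GC, CG
#' dinucleotidePercent("GATC", "GA+TC")   # 66.67: GA, AT, TC
#' @export
dinucleotidePercent <- function(sequence, classLabel) {
  members <- degeClassMembers(classLabel)
  k <- nchar(members[1])
  dna <- .asDNA(sequence)
  counts <- Biostrings::oligonucleotideFrequency(dna, width = k)
  valid <- sum(counts)
  if (valid == 0) {
    warning("no valid ", k, "-mer window; percentage undefined")
    return(NA_real_)
  }
  100 * sum(counts[members]) / valid
}

#' CG odds ratio of a sequence
#'
#' Observed CG dinucleotide frequency divided by its expectation
#' `p_C * p_G` from the mononucleotide composition of the same fragment.
#' Values below 1 indicate CG deficiency (in vertebrates linked to
#' methylation-driven CG decay; insects are generally less CG-deficient).
#'
#' @param sequence Character string or [Biostrings::DNAString].
#' @return List with `observed` (fraction), `expected` (fraction) and
#'   `oddsRatio`; `oddsRatio` is `NA` (with a warning) when `p_C * p_G` is
#'   zero or no valid window exists.
#' @export
cgOddsRatio <- function(sequence) {
  dna <- .asDNA(sequence)
  m <- .monoCounts(dna)
  tot <- sum(m)
  di <- Biostrings::oligonucleotideFrequency(dna, width = 2)
  valid <- sum(di)
  if (tot < 2 || valid == 0) {
    warning("sequence too short for an odds ratio")
    return(list(observed = NA_real_, expected = NA_real_,
                oddsRatio = NA_real_))
  }
  obs <- di[["CG"]] / valid
  expd <- (m[["C"]] / tot) * (m[["G"]] / tot)
  if (expd == 0) {
    warning("p_C * p_G is zero; odds ratio undefined")
    return(list(observed = obs, expected = 0, oddsRatio = NA_real_))
  }
  list(observed = obs, expected = expd, oddsRatio = obs / expd)
}

#' CG/GC ratio of a sequence
#'
#' Ratio of the CG to the GC dinucleotide percentage. Ratios below 1 (CG
#' deficiency relative to the same bases in the opposite order) are typical
#' of most insect genomes.
#'
#' @param sequence Character string or [Biostrings::DNAString].
#' @return Dimensionless ratio; `NA` (with a warning) when GC% is zero.
#' @export
cgGcRatio <- function(sequence) {
  cg <- dinucleotidePercent(sequence, "CG")
  gc <- dinucleotidePercent(sequence, "GC")
  if (is.na(gc) || gc == 0) {
    warning("GC% is zero; CG/GC ratio undefined")
    return(NA_real_)
  }
  cg / gc
}

#' Tukey box-plot summary
#'
#' Quartiles by linear interpolation of the order statistics
#' (`p(k) = (k-1)/(n-1)`, i.e. R's quantile type 7); whiskers extend to the
#' most extreme data points within `whiskerMultiplier * IQR` of the
#' quartiles; points beyond are outliers.
#'
#' @param values Numeric vector (at least one finite value).
#' @param whiskerMultiplier Whisker reach in IQR units (default 1.5).
#' @return List with `median`, `q1`, `q3`, `whiskerLow`, `whiskerHigh`,
#'   `outliers`, `whiskerMultiplier`.
#' @export
boxplotSummary <- function(values, whiskerMultiplier = 1.5) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L) stop("no finite values")
  x <- sort(values)
  q7 <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    if (lo + 1 >= n) return(x[n])
    x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
  }
  q1 <- q7(0.25); med <- q7(0.5); q3 <- q7(0.75)
  iqr <- q3 - q1
  loFence <- q1 - whiskerMultiplier * iqr
  hiFence <- q3 + whiskerMultiplier * iqr
  inRange <- x >= loFence & x <= hiFence
  list(
    median = med, q1 = q1, q3 = q3,
    whiskerLow = min(x[inRange]),
    whiskerHigh = max(x[inRange]),
    outliers = x[!inRange],
    whiskerMultiplier = whiskerMultiplier
  )
}

#' Per-fragment statistics table
#'
#' G+C%, CG%, GC%, CG/GC ratio and CG odds ratio for every fragment.
#'
#' @param records [Biostrings::DNAStringSet] of source sequences.
#' @param fragments [GenomicRanges::GRanges] from [tileWindows()].
#' @return Data frame with provenance and statistic columns.
#' @export
fragmentStats <- function(records, fragments) {
  src <- as.character(GenomicRanges::seqnames(fragments))
  seqs <- Biostrings::subseq(records[src],
                             start = GenomicRanges::start(fragments),
                             end = GenomicRanges::end(fragments))
  rows <- lapply(seq_along(seqs), function(r) {
    s <- seqs[[r]]
    or <- suppressWarnings(cgOddsRatio(s))
    data.frame(
      species = S4Vectors::mcols(fragments)$species[r],
      source = src[r],
      start = GenomicRanges::start(fragments)[r] - 1L,
      end = GenomicRanges::end(fragments)[r],
      gc_percent = suppressWarnings(gcPercent(s)),
      cg_percent = suppressWarnings(dinucleotidePercent(s, "CG")),
      gc_dinuc_percent = suppressWarnings(dinucleotidePercent(s, "GC")),
      cg_gc_ratio = suppressWarnings(cgGcRatio(s)),
      cg_odds_ratio = or$oddsRatio
    )
  })
  do.call(rbind, rows)
}

#' Per-chromosome G+C% table
#'
#' Whole-sequence G+C% (N excluded) for each record.
#'
#' @param records [Biostrings::DNAStringSet].
#' @return Data frame with `species`, `source`, `length`, `gc_percent`.
#' @export
chromosomeStats <- function(records) {
  data.frame(
    species = S4Vectors::mcols(records)$species,
    source = names(records),
    length = Biostrings::width(records),
    gc_percent = vapply(seq_along(records), function(r) {
      suppressWarnings(gcPercent(records[[r]]))
    }, numeric(1))
  )
}
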