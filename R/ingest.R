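# Reading assemblies, pooling short scaffolds with N separators, and tiling
# sequences into fixed-size fragments. A single N between concatenated
# scaffolds is sufficient: every k-mer window that crosses a junction
# contains the N and is excluded from counting, so composition vectors of
# the joined record equal the sum over its parts.

#' Read a genome assembly from FASTA
#'
#' Reads a (possibly gzipped) multi-FASTA file, uppercases sequences and
#' maps every character outside \{A,C,G,T,N\} to N. Entry order is
#' preserved; a `species` metadata column is attached to every record.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @param speciesLabel Species label attached to all records in the file.
#' @return [Biostrings::DNAStringSet] with `mcols()$species` set; names are
#'   the first whitespace-delimited token of each FASTA header.
#' @export
readGenomeFasta <- function(path, speciesLabel) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  chars <- toupper(as.character(raw))
  chars <- gsub("[^ACGTN]", "N", chars, perl = TRUE)
  ids <- sub("\\s.*$", "", names(raw))
  if (any(nchar(chars) == 0L)) {
    stop("zero-length record(s): ",
         paste(ids[nchar(chars) == 0L], collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- ids
  S4Vectors::mcols(out)$species <- speciesLabel
  out
}

#' Write records back to FASTA
#'
#' @param records [Biostrings::DNAStringSet] as returned by
#'   [readGenomeFasta()].
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(records, path) {
  Biostrings::writeXStringSet(records, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Pool short scaffolds with N separators
#'
#' Records of length `>= minLength` pass through unchanged. Per species, all
#' shorter records are joined in input order into one synthetic record with
#' a single N between consecutive scaffolds, so fragment analysis does not
#' simply drop assemblies registered as many short scaffolds. Downstream
#' k-mer counting excludes every window containing N, so the junction
#' introduces no artificial oligonucleotides.
#'
#' @param records [Biostrings::DNAStringSet] with a `species` metadata
#'   column.
#' @param minLength Records shorter than this are pooled. Defaults to the
#'   analysis window size in the pipeline.
#' @return [Biostrings::DNAStringSet]: the long records in input order,
#'   followed by one `<species>_concat` record per species that had short
#'   scaffolds.
#' @export
concatenateWithN <- function(records, minLength) {
  stopifnot(is(records, "DNAStringSet"), minLength >= 1)
  species <- S4Vectors::mcols(records)$species
  if (is.null(species)) stop("records must carry a 'species' metadata column")
  short <- Biostrings::width(records) < minLength
  keep <- records[!short]
  if (!any(short)) return(records)
  joinedList <- lapply(split(seq_along(records)[short], species[short]),
    function(idx) {
      paste(as.character(records[idx]), collapse = "N")
    })
  joined <- Biostrings::DNAStringSet(unlist(joinedList))
  names(joined) <- paste0(names(joinedList), "_concat")
  S4Vectors::mcols(joined)$species <- names(joinedList)
  out <- c(keep, joined)
  out
}

#' Tile records into fixed-size fragments
#'
#' Cuts every record into non-overlapping windows `[0, w), [w, 2w), ...`
#' (0-based half-open); the trailing partial window is discarded so that all
#' composition vectors come from equal-length fragments. Windows whose
#' fraction of A/C/G/T bases falls below `minValidFraction` are dropped with
#' a message (N-rich windows carry little composition signal).
#'
#' @param records [Biostrings::DNAStringSet] with a `species` metadata
#'   column, or a single [Biostrings::DNAString] (then `species` must be
#'   given).
#' @param windowSize Fragment size in bases (1 Mb and 100 kb in typical
#'   genome-signature analyses).
#' @param minValidFraction Minimum fraction of non-N bases per retained
#'   window (default 0.5).
#' @param species Species label when `records` is a bare `DNAString`.
#' @return [GenomicRanges::GRanges] with metadata columns `species` and
#'   `valid_fraction`; seqnames are record ids. Ranges are stored 1-based
#'   closed (GRanges convention); exported manifests use 0-based half-open.
#' @export
tileWindows <- function(records, windowSize, minValidFraction = 0.5,
                        species = NULL) {
  stopifnot(windowSize >= 1, minValidFraction >= 0, minValidFraction <= 1)
  if (is(records, "DNAString")) {
    records <- Biostrings::DNAStringSet(list(records))
    names(records) <- if (is.null(species)) "seq1" else species
    S4Vectors::mcols(records)$species <-
      if (is.null(species)) "unknown" else species
  }
  stopifnot(is(records, "DNAStringSet"))
  sp <- S4Vectors::mcols(records)$species
  if (is.null(sp)) stop("records must carry a 'species' metadata column")
  widths <- Biostrings::width(records)
  nwin <- widths %/% windowSize
  if (sum(nwin) == 0L) {
    return(GenomicRanges::GRanges(species = character(0),
                                  valid_fraction = numeric(0)))
  }
  src <- rep(names(records), nwin)
  spw <- rep(sp, nwin)
  starts <- unlist(lapply(nwin, function(n) {
    if (n == 0L) integer(0) else (seq_len(n) - 1L) * windowSize + 1L
  }), use.names = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = src,
    ranges = IRanges::IRanges(start = starts, width = windowSize)
  )
  seqs <- Biostrings::subseq(records[src],
                             start = starts,
                             width = windowSize)
  acgt <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T"))
  vf <- rowSums(acgt) / windowSize
  S4Vectors::mcols(gr)$species <- spw
  S4Vectors::mcols(gr)$valid_fraction <- vf
  drop <- vf < minValidFraction
  if (any(drop)) {
    message(sum(drop), " window(s) below valid-fraction threshold dropped")
  }
  gr[!drop]
}

#' Write a fragment manifest as TSV
#'
#' Columns: species, source, start, end (0-based half-open), valid_fraction.
#'
#' @param fragments [GenomicRanges::GRanges] from [tileWindows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFragmentManifest <- function(fragments, path) {
  df <- data.frame(
    species = S4Vectors::mcols(fragments)$species,
    source = as.character(GenomicRanges::seqnames(fragments)),
    start = GenomicRanges::start(fragments) - 1L,
    end = GenomicRanges::end(fragments),
    valid_fraction = S4Vectors::mcols(fragments)$valid_fraction
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
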