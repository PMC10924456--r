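# Independent oracles used across the suite. These deliberately avoid the
# package's counting path (and Biostrings' k-mer counters): plain substring
# enumeration and hand-rolled reverse complements.

oracleRevcomp <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# degenerate class counts of one sequence by brute-force window scan
oracleDegeCounts <- function(seq, k) {
  n <- nchar(seq)
  counts <- list()
  if (n >= k) {
    wins <- substring(seq, 1:(n - k + 1), k:n)
    wins <- wins[!grepl("N", wins, fixed = TRUE)]
    for (w in wins) {
      canon <- min(w, oracleRevcomp(w))
      counts[[canon]] <- (counts[[canon]] %||% 0) + 1
    }
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random A/C/G/T/N sequence
randomSeq <- function(len, pN = 0.05) {
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(rep((1 - pN) / 4, 4), pN)), collapse = "")
}

# compare package class counts against the oracle for one sequence
expectCountsMatchOracle <- function(seq, k) {
  idx <- buildDegeIndex(k)
  got <- countComposition(seq, idx)$counts
  oracle <- oracleDegeCounts(seq, k)
  full <- setNames(numeric(length(degeClasses(idx))),
                   vapply(strsplit(degeClasses(idx), "+", fixed = TRUE),
                          `[`, character(1), 1))
  full[names(oracle)] <- oracle
  expect_equal(unname(got), unname(full))
}

# small labelled DNAStringSet for ingest/pipeline tests
toyRecords <- function(seqs, species) {
  out <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(out) <- paste0("r", seq_along(seqs))
  S4Vectors::mcols(out)$species <- species
  out
}
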