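test_that("FASTA reading normalizes case and ambiguity codes", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1 some description", "acgt", ">c2", "ARGT"), path)
  recs <- readGenomeFasta(path, "spX")
  expect_identical(names(recs), c("c1", "c2"))
  expect_identical(as.character(recs[["c1"]]), "ACGT")
  expect_identical(as.character(recs[["c2"]]), "ANGT")  # R -> N
  expect_identical(S4Vectors::mcols(recs)$species, c("spX", "spX"))
  expect_error(readGenomeFasta(file.path(tempdir(), "absent.fa"), "x"),
               "cannot read")
})

test_that("FASTA write/read round-trips normalized records", {
  recs <- toyRecords(c(s1 = "ACGTNACGT", s2 = "TTTT"), c("x", "x"))
  path <- withr::local_tempfile(fileext = ".fa")
  writeGenomeFasta(recs, path)
  back <- readGenomeFasta(path, "x")
  expect_identical(as.character(back), as.character(recs))
})

test_that("short scaffolds are pooled with a single N separator", {
  recs <- toyRecords(c(s1 = "AC", s2 = "GT", chr1 = "ACGTACGTAC"),
                     c("x", "x", "x"))
  out <- concatenateWithN(recs, minLength = 5)
  expect_identical(names(out), c("chr1", "x_concat"))
  expect_identical(as.character(out[["x_concat"]]), "ACNGT")
  # nothing short: records pass through untouched
  expect_identical(concatenateWithN(recs, minLength = 2), recs)
})

test_that("N-joined scaffolds count like the sum of their parts", {
  # the single N separator removes every junction-crossing window
  set.seed(21)
  for (rep in 1:25) {
    k <- sample(2:5, 1)
    n <- sample(2:6, 1)
    parts <- vapply(seq_len(n), function(i) randomSeq(sample(10:80, 1)),
                    character(1))
    joined <- paste(parts, collapse = "N")
    idx <- buildDegeIndex(k)
    summed <- Reduce(`+`, lapply(parts, function(p) {
      countComposition(p, idx)$counts
    }))
    expect_identical(countComposition(joined, idx)$counts, summed)
  }
})

test_that("tiling partitions each record into ordered full windows", {
  recs <- toyRecords(c(chr = "ACGTACGTAC"), "x")  # length 10
  fr <- tileWindows(recs, 4)
  expect_identical(GenomicRanges::start(fr) - 1L, c(0L, 4L))
  expect_identical(GenomicRanges::end(fr), c(4L, 8L))   # remainder dropped
  expect_identical(S4Vectors::mcols(fr)$species, c("x", "x"))

  # window larger than the record: empty result, not an error
  expect_length(tileWindows(recs, 100), 0)

  # partition property on random records
  set.seed(22)
  for (rep in 1:20) {
    L <- sample(50:500, 1)
    w <- sample(7:60, 1)
    r <- toyRecords(setNames(randomSeq(L, pN = 0), "c"), "x")
    fr <- tileWindows(r, w, minValidFraction = 0)
    expect_length(fr, L %/% w)
    if (length(fr)) {
      expect_identical(GenomicRanges::start(fr),
                       as.integer((seq_along(fr) - 1) * w + 1))
      expect_true(all(GenomicRanges::width(fr) == w))
    }
  }
})

test_that("N-rich windows are dropped by the valid-fraction threshold", {
  seq60N <- paste0(strrep("N", 60), strrep("ACGT", 10))  # 60% N window
  recs <- toyRecords(setNames(seq60N, "c"), "x")
  expect_length(tileWindows(recs, 100, minValidFraction = 0.4), 1)
  expect_message(fr <- tileWindows(recs, 100, minValidFraction = 0.5),
                 "dropped")
  expect_length(fr, 0)
})

test_that("fragment manifests are written 0-based half-open", {
  recs <- toyRecords(c(chr = strrep("ACGT", 10)), "x")
  fr <- tileWindows(recs, 20)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeFragmentManifest(fr, path)
  df <- read.delim(path)
  expect_identical(df$start, c(0L, 20L))
  expect_identical(df$end, c(20L, 40L))
})
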