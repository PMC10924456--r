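test_that("degenerate class counts follow the strand-merge arithmetic", {
  # brute-force enumeration: merge every k-mer with its reverse complement
  bruteClassCount <- function(k) {
    kmers <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k)))
    length(unique(pmin(kmers, oracleRevcomp(kmers))))
  }
  for (k in 1:6) {
    expect_identical(length(buildDegeIndex(k)), bruteClassCount(k))
  }
  expect_identical(length(buildDegeIndex(2)), 10L)
  expect_identical(length(buildDegeIndex(3)), 32L)
  expect_identical(length(buildDegeIndex(5)), 512L)
  expect_error(buildDegeIndex(0), "k must be")
})

test_that("every k-mer maps to the same class as its reverse complement", {
  for (k in 2:5) {
    idx <- buildDegeIndex(k)
    kmers <- names(idx@kmerToClass)
    expect_identical(unname(idx@kmerToClass),
                     unname(idx@kmerToClass[oracleRevcomp(kmers)]))
  }
})

test_that("class labels are canonical-first and ordered lexicographically", {
  idx <- buildDegeIndex(2)
  expect_identical(degeClasses(idx)[1:3], c("AA+TT", "AC+GT", "AG+CT"))
  expect_true("CG" %in% degeClasses(idx))  # palindrome keeps its own label
  canon <- vapply(strsplit(degeClasses(idx), "+", fixed = TRUE),
                  `[`, character(1), 1)
  expect_identical(canon, sort(canon, method = "radix"))
  expect_identical(degeClassMembers("GA+TC"), c("GA", "TC"))
  expect_error(degeClassMembers("GA+TCA"), "malformed")
})

test_that("composition of small sequences matches hand enumeration", {
  idx <- buildDegeIndex(2)
  r <- countComposition("ACGT", idx)
  expect_equal(r$validCount, 3)
  expect_equal(unname(r$percent["AC+GT"]), 200 / 3)  # AC and GT merge
  expect_equal(unname(r$percent["CG"]), 100 / 3)
  expect_equal(sum(r$percent), 100)

  r <- countComposition("ANGT", idx)  # windows AN, NG skipped
  expect_equal(r$validCount, 1)
  expect_equal(unname(r$percent["AC+GT"]), 100)

  short <- countComposition("A", idx)
  expect_equal(short$validCount, 0)
  expect_true(all(short$percent == 0))
})

test_that("composition equals the brute-force oracle on random sequences", {
  set.seed(11)
  for (k in 2:5) {
    for (rep in 1:60) {
      expectCountsMatchOracle(randomSeq(sample(20:200, 1)), k)
    }
  }
})

test_that("composition is exactly strand-invariant", {
  set.seed(12)
  for (k in 2:5) {
    idx <- buildDegeIndex(k)
    for (rep in 1:20) {
      s <- randomSeq(150)
      expect_identical(countComposition(s, idx)$percent,
                       countComposition(oracleRevcomp(s), idx)$percent)
    }
  }
})

test_that("compositionMatrix builds percentage rows and drops dead fragments", {
  recs <- toyRecords(c(a = "ACGTACGTACGTACGT", b = "GGGGGGGGCCCCCCCC",
                       c = "NNNNNNNNNNNNNNNN"),
                     species = c("x", "x", "x"))
  fr <- tileWindows(recs, 8, minValidFraction = 0)
  idx <- buildDegeIndex(2)
  expect_message(cm <- compositionMatrix(recs, fr, idx), "excluded")
  expect_identical(dim(cm), c(4L, 10L))   # 2 all-N windows dropped
  expect_equal(unname(rowSums(compositionValues(cm))), rep(100, 4))
  # duplicate fragment sequences give identical rows
  expect_identical(compositionValues(cm)[1, ], compositionValues(cm)[2, ])
})

test_that("composition TSV round-trips", {
  recs <- toyRecords(c(a = paste(rep("ACGT", 12), collapse = "")), "x")
  fr <- tileWindows(recs, 16, minValidFraction = 0)
  cm <- compositionMatrix(recs, fr, buildDegeIndex(2))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCompositionTSV(cm, path)
  cm2 <- readCompositionTSV(path, k = 2)
  expect_equal(compositionValues(cm2), compositionValues(cm),
               ignore_attr = TRUE)
  expect_equal(validCounts(cm2), validCounts(cm))
})
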