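test_that("species models hit their stationary targets analytically", {
  m <- makeSpeciesModel("a", 42, cgSuppression = 1)
  # no bias: chain is i.i.d. with stationary GC equal to the target
  expect_equal(unname(m$stationary), c(0.29, 0.21, 0.21, 0.29))
  expect_equal(m$achievedGC, 42)
  expect_equal(m$cgOddsRatio, 1)
  expect_true(all(abs(rowSums(m$transition) - 1) < 1e-9))

  mb <- makeSpeciesModel("b", 42, cgSuppression = 0.5)
  expect_equal(mb$cgOddsRatio, 0.5, tolerance = 1e-8)
  expect_equal(mb$achievedGC, 42, tolerance = 1e-8)
  expect_true(all(mb$transition >= 0))

  expect_error(makeSpeciesModel("c", 5), "targetGC")
  expect_error(makeSpeciesModel("d", 80, cgSuppression = 3), "infeasible")
  # construction is deterministic
  expect_identical(makeSpeciesModel("e", 37, 0.7, seed = 9),
                   makeSpeciesModel("e", 37, 0.7, seed = 9))
})

test_that("generated chromosomes concentrate around the target G+C", {
  m <- makeSpeciesModel("a", 38, 0.8, seed = 71)
  g <- generateGenome(m, 3e6)
  expect_identical(unname(Biostrings::width(g)), 3000000L)
  expect_equal(gcPercent(g[[1]]), 38, tolerance = 0.5)
  # same seed, same bytes
  g2 <- generateGenome(m, 3e6)
  expect_identical(as.character(g), as.character(g2))
})

test_that("terminal zones reach the requested dinucleotide enrichment", {
  m <- makeSpeciesModel("z", 40, seed = 72)
  z <- zoneSpec(1, 5e5, "GA+TC", fold = 2, placement = "terminal")
  g <- generateGenome(m, 3e6, zones = list(z))
  zones <- S4Vectors::metadata(g)$zones
  expect_identical(zones$start, 2500000)
  expect_identical(zones$end, 3000000)
  tr <- frequencyTrack(g[1], 1e5, "GA+TC")
  vals <- S4Vectors::mcols(tr)$value
  bg <- median(vals[1:25])
  expect_true(all(vals[26:30] >= 1.8 * bg))
  # G+C inside the zone stays near background (not a mononucleotide artifact)
  zoneGC <- gcPercent(substr(as.character(g[[1]]), 2500001, 3000000))
  expect_equal(zoneGC, 40, tolerance = 2.5)
  expect_error(
    generateGenome(m, 3e6, zones = list(z, zoneSpec(1, 1e6, fold = 2,
                                                    placement = 2.2e6))),
    "overlapping")
})

test_that("scaffold splitting cuts chromosomes into fixed pieces", {
  m <- makeSpeciesModel("s", 35, seed = 73)
  g <- generateGenome(m, 1e6, scaffoldSplit = 4e4)
  expect_length(g, 25)
  expect_true(all(Biostrings::width(g) == 4e4))
  expect_identical(names(g)[1], "s_chr1_s1")
  # pieces reassemble to the unsplit chromosome
  whole <- generateGenome(m, 1e6)
  expect_identical(paste(as.character(g), collapse = ""),
                   as.character(whole[[1]]))
})

test_that("communities are reproducible with spaced G+C and distinct biases", {
  comm <- generateCommunity(4, windowSize = 5e4, seed = 3)
  expect_identical(length(unique(S4Vectors::mcols(comm$records)$species)), 4L)
  gcs <- comm$truth$achieved_gc
  expect_true(all(diff(sort(gcs)) >= 3))
  expect_identical(anyDuplicated(comm$truth$cg_suppression), 0L)
  # one species arrives as sub-window scaffolds
  split <- comm$truth$scaffold_split
  expect_identical(sum(!is.na(split)), 1L)
  comm2 <- generateCommunity(4, windowSize = 5e4, seed = 3)
  expect_identical(as.character(comm$records), as.character(comm2$records))
  # fixtures: FASTA per species plus truth table
  dir <- withr::local_tempdir()
  writeCommunityFixtures(comm, dir)
  expect_length(list.files(dir, pattern = "\\.fasta$"), 4)
  expect_true(file.exists(file.path(dir, "truth.tsv")))
})

test_that("empirical window frequencies match the chain's analytic values", {
  m <- makeSpeciesModel("a", 45, 0.7, seed = 74)
  g <- generateGenome(m, 2e6)
  for (cl in c("CG", "GA+TC", "AA+TT")) {
    f0 <- 100 * oligoSOM:::.classStationaryFreq(m, cl)
    tr <- frequencyTrack(g[1], 2e5, cl)
    expect_equal(mean(S4Vectors::mcols(tr)$value), f0, tolerance = 0.02)
  }
})
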