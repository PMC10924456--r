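# hand-built trained model on an I x J lattice with given weights
toyModel <- function(W, I, J, assignments = integer(0)) {
  colnames(W) <- paste0("c", seq_len(ncol(W)))
  new("BLSOMModel", I = as.integer(I), J = as.integer(J), weights = W,
      classLabels = colnames(W), sigma1 = 1, sigma2 = 1,
      assignments = as.integer(assignments),
      fragments = GenomicRanges::GRanges(), trained = TRUE,
      config = list(standardizeColumns = FALSE))
}

test_that("territory categories partition the lattice", {
  W <- matrix(0, 4, 2)
  # nodes: 1 <- two x fragments, 2 <- x and y, 3 <- empty, 4 <- one y
  m <- toyModel(W, 2, 2, assignments = c(1, 1, 2, 2, 4))
  terr <- territoryMap(m, c("x", "x", "x", "y", "y"))
  v <- layerValues(terr)
  expect_identical(v, c("single:x", "multiple", "vacant", "single:y"))
  expect_identical(sum(startsWith(v, "single")) +
                     sum(v == "multiple") + sum(v == "vacant"), 4L)
  expect_error(territoryMap(m, c("x", NA, "x", "y", "y")), "unlabeled")
  expect_error(territoryMap(m, c("x", "y")), "one label per")
})

test_that("purity counts fragments on single-label nodes", {
  W <- matrix(0, 4, 2)
  m <- toyModel(W, 2, 2, assignments = c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3))
  # 8 of 10 fragments on pure nodes
  labels <- c(rep("x", 4), rep("y", 4), "x", "y")
  expect_equal(mapPurity(m, labels), 0.8)
  expect_equal(mapPurity(m, rep("x", 10)), 1.0)
  m2 <- toyModel(W, 2, 2, assignments = rep(1, 4))
  expect_equal(mapPurity(m2, c("x", "x", "y", "y")), 0.0)
})

test_that("U-matrix marks the boundary of a two-block lattice", {
  # 4 x 2 lattice: i in 0..3; left half weight a, right half weight b
  a <- c(0, 0); b <- c(6, 0)
  W <- rbind(a, a, a, a, b, b, b, b)  # linear order i*J+j
  m <- toyModel(W, 4, 2)
  u <- layerMatrix(computeUMatrix(m))
  expect_equal(dim(u), c(4, 2))
  # interior columns touch the other block; outer columns do not
  expect_true(all(u[c(1, 4), ] == 0))
  expect_true(all(u[c(2, 3), ] == 1))
  # all-identical weights: all zero
  expect_true(all(layerValues(computeUMatrix(toyModel(matrix(1, 8, 2),
                                                      4, 2))) == 0))
  expect_error(computeUMatrix(toyModel(matrix(0, 1, 2), 1, 1)), "1 x 1")
})

test_that("U-matrix is invariant under adding a constant vector", {
  set.seed(41)
  W <- matrix(rnorm(24), 12, 2)
  m1 <- toyModel(W, 4, 3)
  m2 <- toyModel(W + 5, 4, 3)
  expect_equal(layerValues(computeUMatrix(m1)),
               layerValues(computeUMatrix(m2)))
  u <- layerValues(computeUMatrix(m1))
  expect_equal(range(u), c(0, 1))
})

test_that("heatmap bins hit the endpoints and midpoint exactly", {
  f <- c(2, 5, 8, 11)  # fmin 2, fmax 11, midpoint 6.5
  W <- cbind(f, 0)
  m <- toyModel(W, 2, 2)
  bins <- layerValues(heatmapBins(m, "c1"))
  expect_identical(bins[f == 2], 0L)
  expect_identical(bins[f == 11], 20L)
  # midpoint: floor(21 * 0.5) = 10
  W2 <- cbind(c(2, 6.5, 11, 11), 0)
  m2 <- toyModel(W2, 2, 2)
  expect_identical(layerValues(heatmapBins(m2, "c1"))[2], 10L)
  # constant frequency: all midpoint bin
  expect_true(all(layerValues(heatmapBins(toyModel(matrix(3, 4, 2), 2, 2),
                                          "c1")) == 10L))
  expect_error(heatmapBins(m, "nope"), "unknown class")
  # monotone in node frequency
  set.seed(42)
  ff <- runif(12)
  mm <- toyModel(cbind(ff, 0), 4, 3)
  bb <- layerValues(heatmapBins(mm, "c1"))
  expect_true(all(diff(bb[order(ff)]) >= 0))
})

test_that("satellite territories fenced by strong boundaries are flagged", {
  # 6 x 6 lattice: species A main block (i 0..2), species B block (i 4..5),
  # and a one-node satellite of A at (5, 5) with distinct composition
  I <- 6; J <- 6
  co <- expand.grid(j = 0:(J - 1), i = 0:(I - 1))[, c("i", "j")]
  W <- matrix(0, I * J, 2)
  W[co$i >= 4, 1] <- 10
  sat <- which(co$i == 5 & co$j == 5)
  W[sat, ] <- c(40, 40)
  m <- toyModel(W, I, J)
  # occupy: A on i<=2, B on i==4..5 except the satellite, A on the satellite
  occA <- which(co$i <= 2)
  occB <- setdiff(which(co$i >= 4), sat)
  m@assignments <- as.integer(c(occA, occB, sat))
  labels <- c(rep("A", length(occA)), rep("B", length(occB)), "A")
  flagged <- flagSpecialZoneCandidates(m, labels, quantile = 0.9)
  expect_identical(flagged$node, sat)
  expect_identical(flagged$label, "A")
  # homogeneous map: nothing flagged
  m2 <- toyModel(matrix(0, 9, 2), 3, 3, assignments = 1:9)
  expect_identical(nrow(flagSpecialZoneCandidates(m2, rep("A", 9))), 0L)
})

test_that("node tables and special-zone tables carry provenance", {
  set.seed(43)
  tc <- rbind(matrix(0, 20, 2), matrix(20, 20, 2)) +
    matrix(rnorm(80, sd = 0.1), 40, 2)
  colnames(tc) <- c("a", "b")
  m <- trainBLSOM(tc, config = blsomConfig(seqsPerNode = 5, epochs = 10))
  labels <- rep(c("x", "y"), each = 20)
  nt <- nodeTable(m, labels)
  expect_identical(nrow(nt), as.integer(prod(latticeDim(m))))
  expect_true(all(c("category", "x", "y") %in% colnames(nt)))
  expect_identical(sum(nt$x) + sum(nt$y), 40L)
})
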