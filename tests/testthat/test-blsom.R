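# two well-separated Gaussian composition clusters in a low-dim space
twoClusterMatrix <- function(n = 120, dim = 6, gap = 30, sd = 0.5,
                             seed = 31) {
  set.seed(seed)
  centers <- rbind(rep(10, dim), c(10 + gap, rep(10, dim - 1)))
  grp <- rep(1:2, each = n / 2)
  X <- centers[grp, ] + matrix(rnorm(n * dim, sd = sd), n, dim)
  colnames(X) <- paste0("c", seq_len(dim))
  list(X = X, grp = grp)
}

test_that("lattice shape follows the principal-axis aspect ratio", {
  # sigma1/sigma2 = 4, n* = 100 -> J = sqrt(100/4) = 5, I = 20
  expect_identical(oligoSOM:::.latticeShape(100, 4, 1, 2),
                   c(I = 20L, J = 5L))
  # degenerate second axis clamps J with a warning
  expect_warning(d <- oligoSOM:::.latticeShape(50, 2, 0, 2), "clamped")
  expect_identical(d[["J"]], 2L)
})

test_that("PCA initialization spans 5 sigma and is deterministic", {
  tc <- twoClusterMatrix()
  cfg <- blsomConfig(seqsPerNode = 10)
  m <- initLattice(tc$X, cfg)
  expect_false(m@trained)
  dims <- latticeDim(m)
  expect_equal(prod(dims), round(nrow(tc$X) / 10), tolerance = 0.35)
  expect_gte(dims[["I"]], dims[["J"]])
  # corner node (0,0) sits at mean - 2.5*sigma1*pc1 - 2.5*sigma2*pc2
  ord <- oligoSOM:::.canonicalOrder(tc$X)
  pca <- prcomp(tc$X[ord, ], center = TRUE, scale. = FALSE)
  pc1 <- pca$rotation[, 1]
  s1 <- sign(pc1[which.max(abs(pc1))]); pc1 <- pc1 * s1
  pc2 <- pca$rotation[, 2]
  s2 <- sign(pc2[which.max(abs(pc2))]); pc2 <- pc2 * s2
  corner <- pca$center - 2.5 * pca$sdev[1] * pc1 - 2.5 * pca$sdev[2] * pc2
  expect_equal(unname(nodeWeights(m)[1, ]), unname(corner))
  # no randomness: identical on repeat
  expect_identical(nodeWeights(initLattice(tc$X, cfg)), nodeWeights(m))
  expect_error(initLattice(tc$X[1:5, ], cfg), "at least")
  expect_error(initLattice(matrix(1, 40, 4), cfg), "degenerate")
})

test_that("training is bit-identical under row permutation", {
  tc <- twoClusterMatrix(n = 200)
  cfg <- blsomConfig(seqsPerNode = 10, epochs = 40)
  m1 <- trainBLSOM(tc$X, config = cfg)
  set.seed(33)
  p <- sample(nrow(tc$X))
  m2 <- trainBLSOM(tc$X[p, ], config = cfg)
  expect_identical(nodeWeights(m1), nodeWeights(m2))
  expect_identical(nodeAssignments(m1)[p], nodeAssignments(m2))
})

test_that("single epoch with a tiny radius averages each node's fragments", {
  tc <- twoClusterMatrix(n = 60)
  cfg <- blsomConfig(seqsPerNode = 10, epochs = 1,
                     neighborhoodFinalRadius = 1e-6)
  m0 <- initLattice(tc$X, cfg)
  bmu0 <- assignNodes(tc$X, m0)
  m1 <- trainBLSOM(tc$X, model = m0)
  for (node in unique(bmu0)) {
    expect_equal(unname(nodeWeights(m1)[node, ]),
                 unname(colMeans(tc$X[bmu0 == node, , drop = FALSE])))
  }
  # unassigned nodes keep their initial weights
  idle <- setdiff(seq_len(prod(latticeDim(m1))), bmu0)
  expect_identical(nodeWeights(m1)[idle, ], nodeWeights(m0)[idle, ])
  expect_error(blsomConfig(epochs = 0), "epochs")
})

test_that("well-separated clusters never share a node after training", {
  tc <- twoClusterMatrix(n = 200, gap = 50, sd = 1)  # >= 10x within-SD gap
  m <- trainBLSOM(tc$X, config = blsomConfig(seqsPerNode = 10, epochs = 60))
  mixed <- tapply(tc$grp, nodeAssignments(m),
                  function(g) length(unique(g)))
  expect_true(all(mixed == 1))
})

test_that("BMU assignment matches an exhaustive scan and stated tie rule", {
  tc <- twoClusterMatrix(n = 100)
  m <- trainBLSOM(tc$X, config = blsomConfig(epochs = 10))
  W <- nodeWeights(m)
  set.seed(34)
  probes <- tc$X + matrix(rnorm(length(tc$X), sd = 2), nrow(tc$X))
  got <- assignNodes(probes, m)
  oracle <- apply(probes, 1, function(v) {
    which.min(colSums((t(W) - v)^2))  # which.min takes first minimum
  })
  expect_identical(got, unname(oracle))
  # a fragment equal to a node weight lands on that node
  expect_identical(assignNodes(W[7, , drop = FALSE], m), 7L)
  # exact tie between two nodes: smaller linear index wins
  tie <- matrix(c(0, 0, 10, 0), 2, 2, byrow = TRUE)
  colnames(tie) <- c("a", "b")
  mt <- new("BLSOMModel", I = 1L, J = 2L, weights = tie,
            classLabels = c("a", "b"), sigma1 = 1, sigma2 = 1,
            assignments = integer(0),
            fragments = GenomicRanges::GRanges(), trained = TRUE,
            config = list(standardizeColumns = FALSE))
  expect_identical(assignNodes(matrix(c(5, 0), 1, 2,
                                      dimnames = list(NULL, c("a", "b"))),
                               mt), 1L)
})

test_that("the neighborhood radius schedule decays linearly to the floor", {
  cfg <- blsomConfig(epochs = 5, neighborhoodInitialRadius = 9,
                     neighborhoodFinalRadius = 1)
  r <- vapply(1:5, function(t) 9 + (1 - 9) * (t - 1) / 4, numeric(1))
  expect_identical(r, c(9, 7, 5, 3, 1))
  expect_true(all(diff(r) < 0))
})

test_that("trained models serialize to text and restore", {
  tc <- twoClusterMatrix(n = 80)
  m <- trainBLSOM(tc$X, config = blsomConfig(epochs = 10))
  dir <- withr::local_tempdir()
  writeBLSOM(m, dir)
  m2 <- readBLSOM(dir)
  expect_equal(nodeWeights(m2), nodeWeights(m), tolerance = 1e-12)
  expect_identical(latticeDim(m2), latticeDim(m))
  expect_identical(nodeAssignments(m2), nodeAssignments(m))
})
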