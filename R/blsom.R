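# Batch-learning self-organizing map. Unlike the sequential Kohonen SOM,
# every epoch (i) assigns all fragments to their best-matching unit (BMU,
# smallest Euclidean distance) and (ii) replaces every node weight by the
# neighborhood-kernel-weighted mean of the assigned fragments. With a fixed
# PCA initialization and batch updates the trained map is a function of the
# multiset of input rows only; rows are additionally summed in a canonical
# sort order so results are bit-identical under any row permutation.

#' Training parameters for a batch-learning SOM
#'
#' @param seqsPerNode Target mean number of fragments per node (default 10);
#'   sets the total node count `round(N / seqsPerNode)`.
#' @param sdMultiplier Width of the initial lattice along each principal
#'   axis, in standard deviations of the corresponding principal component
#'   (default 5, i.e. the lattice spans 5 sigma).
#' @param epochs Number of batch assignment/update rounds (default 200; the
#'   procedure is conventionally repeated several hundred times).
#' @param neighborhoodInitialRadius Starting neighborhood radius in lattice
#'   units; `NULL` (default) means `max(I, J) / 2`, set at init time.
#' @param neighborhoodFinalRadius Radius used in the last epoch (default 1).
#' @param minJ Minimum size of the second lattice axis (default 2).
#' @param standardizeColumns Standardize composition columns to unit
#'   variance before PCA and training (default `FALSE`: the map is trained
#'   on raw percentages).
#' @return A list of class `blsomConfig`.
#' @export
blsomConfig <- function(seqsPerNode = 10, sdMultiplier = 5, epochs = 200L,
                        neighborhoodInitialRadius = NULL,
                        neighborhoodFinalRadius = 1, minJ = 2L,
                        standardizeColumns = FALSE) {
  stopifnot(seqsPerNode > 0, sdMultiplier > 0, epochs >= 1,
            neighborhoodFinalRadius > 0, minJ >= 2)
  if (!is.null(neighborhoodInitialRadius)) {
    stopifnot(neighborhoodInitialRadius > 0)
  }
  structure(list(
    seqsPerNode = seqsPerNode,
    sdMultiplier = sdMultiplier,
    epochs = as.integer(epochs),
    neighborhoodInitialRadius = neighborhoodInitialRadius,
    neighborhoodFinalRadius = neighborhoodFinalRadius,
    minJ = as.integer(minJ),
    standardizeColumns = standardizeColumns
  ), class = "blsomConfig")
}

# lattice shape: J from the sigma2/sigma1 aspect ratio, then I from the
# target node count. Guarantees I >= J >= minJ.
.latticeShape <- function(nStar, sigma1, sigma2, minJ) {
  if (sigma2 <= 0 || !is.finite(sigma2 / sigma1)) {
    warning("second principal component has zero variance; J clamped")
    J <- minJ
  } else {
    J <- max(minJ, round(sqrt(nStar * sigma2 / sigma1)))
  }
  I <- max(J, round(nStar / J))
  c(I = as.integer(I), J = as.integer(J))
}

.asMatrixInput <- function(x) {
  if (is(x, "CompositionMatrix")) compositionValues(x) else as.matrix(x)
}

# canonical row order: lexicographic over all columns. Exact duplicates are
# adjacent, so column sums taken in this order do not depend on the input
# permutation even in floating point.
.canonicalOrder <- function(X) {
  do.call(order, c(lapply(seq_len(ncol(X)), function(j) X[, j]),
                   list(method = "radix")))
}

#' Initialize a SOM lattice on the PCA plane
#'
#' Computes the principal components of the composition matrix and lays out
#' an `I x J` lattice of weight vectors on the plane spanned by the first
#' two principal axes, spanning `sdMultiplier * sigma` along each axis and
#' centred on the data mean. The node count is `round(N / seqsPerNode)` and
#' the aspect ratio follows `sigma1 / sigma2`. Initialization is fully
#' deterministic: no random values are involved.
#'
#' @param x A [CompositionMatrix] or numeric matrix (rows = fragments).
#' @param config A [blsomConfig()].
#' @return An untrained [BLSOMModel].
#' @export
initLattice <- function(x, config = blsomConfig()) {
  X <- .asMatrixInput(x)
  N <- nrow(X)
  if (N < 2 * config$seqsPerNode) {
    stop("need at least 2 * seqsPerNode rows to initialize a lattice")
  }
  if (config$standardizeColumns) {
    sds <- apply(X, 2, sd)
    sds[sds == 0] <- 1
    X <- sweep(X, 2, sds, "/")
  }
  # PCA on canonically sorted rows: bit-identical under row permutation
  pca <- prcomp(X[.canonicalOrder(X), , drop = FALSE],
                center = TRUE, scale. = FALSE)
  sigma1 <- pca$sdev[1]
  sigma2 <- if (length(pca$sdev) >= 2) pca$sdev[2] else 0
  if (sigma1 <= 0) stop("degenerate matrix: zero total variance")
  nStar <- round(N / config$seqsPerNode)
  dims <- .latticeShape(nStar, sigma1, sigma2, config$minJ)
  I <- dims[["I"]]; J <- dims[["J"]]
  mu <- pca$center
  pc1 <- pca$rotation[, 1]
  pc2 <- if (ncol(pca$rotation) >= 2) pca$rotation[, 2] else pc1 * 0
  # fix axis signs so initialization does not depend on eigen-solver sign
  s1 <- sign(pc1[which.max(abs(pc1))]); if (s1 == 0) s1 <- 1
  s2 <- sign(pc2[which.max(abs(pc2))]); if (s2 == 0) s2 <- 1
  pc1 <- pc1 * s1
  pc2 <- pc2 * s2
  iPos <- if (I > 1) (0:(I - 1)) / (I - 1) - 0.5 else 0
  jPos <- if (J > 1) (0:(J - 1)) / (J - 1) - 0.5 else 0
  grid <- expand.grid(j = jPos, i = iPos)[, c("i", "j")]  # linear idx i*J+j
  W <- matrix(rep(mu, each = I * J), nrow = I * J) +
    outer(grid$i * config$sdMultiplier * sigma1, pc1) +
    outer(grid$j * config$sdMultiplier * sigma2, pc2)
  colnames(W) <- colnames(X)
  frag <- if (is(x, "CompositionMatrix")) fragmentRanges(x) else
    GenomicRanges::GRanges()
  cfg <- unclass(config)
  if (is.null(cfg$neighborhoodInitialRadius)) {
    cfg$neighborhoodInitialRadius <- max(I, J) / 2
  }
  new("BLSOMModel",
    I = I, J = J, weights = W,
    classLabels = colnames(X),
    sigma1 = sigma1, sigma2 = sigma2,
    assignments = integer(0),
    fragments = frag,
    trained = FALSE,
    config = cfg
  )
}

# squared Euclidean distances rows(X) x rows(W)
.sqDist <- function(X, W) {
  d <- outer(rowSums(X^2), rowSums(W^2), "+") - 2 * tcrossprod(X, W)
  d[d < 0] <- 0
  d
}

# BMU per row with smallest-linear-index tie-break (max.col ties.method
# "first" picks the lowest column index; columns are in linear-index order)
.bmu <- function(X, W) {
  max.col(-.sqDist(X, W), ties.method = "first")
}

# node-to-node squared lattice distances for an I x J grid, linear order
.latticeSqDist <- function(I, J) {
  ii <- rep(0:(I - 1), each = J)
  jj <- rep(0:(J - 1), times = I)
  outer(ii, ii, "-")^2 + outer(jj, jj, "-")^2
}

#' Train a batch-learning SOM
#'
#' Runs `epochs` rounds of (1) Euclidean BMU assignment of every fragment
#' (ties broken toward the smallest linear node index `i*J + j`) and (2)
#' batch weight update: every node's weight becomes the Gaussian-kernel
#' (`exp(-d^2 / (2 r(t)^2))` over lattice distance `d`) weighted mean of all
#' fragments, grouped by their BMU. The radius `r(t)` decays linearly from
#' the initial to the final radius. Nodes receiving zero kernel mass keep
#' their previous weight. The result is independent of fragment input
#' order: identical multisets of rows give bit-identical weights.
#'
#' @param x A [CompositionMatrix] or numeric matrix: the training data.
#' @param model An untrained model from [initLattice()], or `NULL` to
#'   initialize from `x` and `config`.
#' @param config A [blsomConfig()]; ignored (the model's stored config is
#'   used) when `model` is supplied.
#' @return A trained [BLSOMModel] with fragment assignments.
#' @export
trainBLSOM <- function(x, model = NULL, config = blsomConfig()) {
  X <- .asMatrixInput(x)
  if (is.null(model)) model <- initLattice(x, config)
  stopifnot(is(model, "BLSOMModel"))
  if (ncol(X) != ncol(model@weights)) {
    stop("dimension mismatch between data and model weights")
  }
  cfg <- model@config
  if (isTRUE(cfg$standardizeColumns)) {
    sds <- apply(X, 2, sd)
    sds[sds == 0] <- 1
    X <- sweep(X, 2, sds, "/")
  }
  ord <- .canonicalOrder(X)
  Xs <- X[ord, , drop = FALSE]
  W <- model@weights
  nNodes <- nrow(W)
  D2 <- .latticeSqDist(model@I, model@J)
  r0 <- cfg$neighborhoodInitialRadius
  rf <- cfg$neighborhoodFinalRadius
  epochs <- cfg$epochs
  bmu <- integer(nrow(Xs))
  for (t in seq_len(epochs)) {
    r <- if (epochs == 1) rf else r0 + (rf - r0) * (t - 1) / (epochs - 1)
    bmu <- .bmu(Xs, W)
    # per-node sums and counts in canonical row order
    Sg <- rowsum(Xs, group = bmu)
    S <- matrix(0, nrow = nNodes, ncol = ncol(Xs))
    S[as.integer(rownames(Sg)), ] <- Sg
    cnt <- tabulate(bmu, nbins = nNodes)
    H <- exp(-D2 / (2 * r^2))
    num <- H %*% S
    den <- as.vector(H %*% cnt)
    upd <- den > 0
    W[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  bmu <- .bmu(Xs, W)
  assignments <- integer(nrow(X))
  assignments[ord] <- bmu
  model@weights <- W
  model@assignments <- assignments
  model@trained <- TRUE
  validObject(model)
  model
}

#' Assign fragments to best-matching nodes
#'
#' Deterministic Euclidean BMU lookup against a model's weights; ties go to
#' the smallest linear node index.
#'
#' @param x A [CompositionMatrix] or numeric matrix.
#' @param model A [BLSOMModel].
#' @return Integer vector of 1-based node rows (linear index + 1).
#' @export
assignNodes <- function(x, model) {
  X <- .asMatrixInput(x)
  stopifnot(is(model, "BLSOMModel"))
  if (ncol(X) != ncol(model@weights)) {
    stop("dimension mismatch between data and model weights")
  }
  if (isTRUE(model@config$standardizeColumns)) {
    sds <- apply(X, 2, sd)
    sds[sds == 0] <- 1
    X <- sweep(X, 2, sds, "/")
  }
  .bmu(X, model@weights)
}

#' Lattice coordinates of node rows
#'
#' @param model A [BLSOMModel].
#' @param nodes 1-based node rows (default: all nodes).
#' @return Data frame with columns `node` (1-based row), `i`, `j` (0-based
#'   lattice coordinates).
#' @export
nodeCoordinates <- function(model, nodes = seq_len(model@I * model@J)) {
  lin <- nodes - 1L
  data.frame(node = nodes, i = lin %/% model@J, j = lin %% model@J)
}

#' Serialize / restore a trained model as plain text
#'
#' Writes a directory with `dims.tsv` (lattice dimensions, sigmas, config),
#' `weights.tsv` (nodes x classes) and, when available, `assignments.tsv`
#' (fragment provenance and node coordinates).
#'
#' @param model A [BLSOMModel].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; `readBLSOM` returns the restored model (without
#'   fragment provenance sequences).
#' @export
writeBLSOM <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(
    key = c("I", "J", "sigma1", "sigma2", "trained",
            names(model@config)),
    value = c(model@I, model@J, model@sigma1, model@sigma2,
              as.integer(model@trained),
              vapply(model@config, function(v)
                if (is.null(v)) NA_real_ else as.numeric(v), numeric(1)))
  )
  write.table(meta, file.path(dir, "dims.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  W <- as.data.frame(model@weights, check.names = FALSE)
  write.table(W, file.path(dir, "weights.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (length(model@assignments)) {
    co <- nodeCoordinates(model, model@assignments)
    df <- data.frame(node = model@assignments, i = co$i, j = co$j)
    if (length(model@fragments) == length(model@assignments)) {
      fr <- model@fragments
      df <- cbind(data.frame(
        species = S4Vectors::mcols(fr)$species,
        source = as.character(GenomicRanges::seqnames(fr)),
        start = GenomicRanges::start(fr) - 1L,
        end = GenomicRanges::end(fr)
      ), df)
    }
    write.table(df, file.path(dir, "assignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname writeBLSOM
#' @export
readBLSOM <- function(dir) {
  meta <- read.delim(file.path(dir, "dims.tsv"))
  kv <- setNames(meta$value, meta$key)
  W <- as.matrix(read.delim(file.path(dir, "weights.tsv"),
                            check.names = FALSE))
  cfgKeys <- setdiff(meta$key, c("I", "J", "sigma1", "sigma2", "trained"))
  cfg <- as.list(kv[cfgKeys])
  cfg$epochs <- as.integer(cfg$epochs)
  cfg$minJ <- as.integer(cfg$minJ)
  cfg$standardizeColumns <- as.logical(cfg$standardizeColumns)
  assignments <- integer(0)
  frag <- GenomicRanges::GRanges()
  apath <- file.path(dir, "assignments.tsv")
  if (file.exists(apath)) {
    adf <- read.delim(apath)
    assignments <- as.integer(adf$node)
    if ("source" %in% colnames(adf)) {
      frag <- GenomicRanges::GRanges(
        seqnames = adf$source,
        ranges = IRanges::IRanges(start = adf$start + 1L, end = adf$end),
        species = adf$species,
        valid_fraction = NA_real_
      )
    }
  }
  new("BLSOMModel",
    I = as.integer(kv[["I"]]), J = as.integer(kv[["J"]]),
    weights = W, classLabels = colnames(W),
    sigma1 = kv[["sigma1"]], sigma2 = kv[["sigma2"]],
    assignments = assignments, fragments = frag,
    trained = as.logical(kv[["trained"]]),
    config = cfg
  )
}
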