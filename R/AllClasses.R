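#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement oligonucleotideFrequency
#'   letterFrequency mkAllStrings subseq countPattern
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom stats mad median prcomp quantile runif setNames sd
#' @importFrom utils write.table read.delim head
#' @useDynLib oligoSOM, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Strand-merged (degenerate) oligonucleotide alphabet
#'
#' A `DegeClassIndex` maps every k-mer over \{A,C,G,T\} to a canonical class
#' obtained by merging each k-mer with its reverse complement (e.g. `GA` and
#' `TC` form the single class `"GA+TC"`). Self-complementary k-mers (only
#' possible for even k) form singleton classes labelled by the k-mer itself.
#'
#' @slot k Oligonucleotide length (integer, 1..8).
#' @slot classes Ordered character vector of class display labels
#'   (`"GA+TC"` style, canonical member first; palindromes keep their own
#'   label). Ordering is lexicographic by canonical member.
#' @slot kmerToClass Named integer vector over all `4^k` k-mers giving the
#'   1-based index of each k-mer's class in `classes`.
#'
#' @seealso [buildDegeIndex()]
#' @export
setClass("DegeClassIndex",
  representation(
    k = "integer",
    classes = "character",
    kmerToClass = "integer"
  )
)

setValidity("DegeClassIndex", function(object) {
  k <- object@k
  if (length(k) != 1L || is.na(k) || k < 1L) {
    return("k must be a single integer >= 1")
  }
  if (length(object@kmerToClass) != 4L^k) {
    return(sprintf("kmerToClass must cover all %d k-mers", 4L^k))
  }
  expected <- if (k %% 2L == 0L) (4^k + 4^(k / 2)) / 2 else 4^k / 2
  if (length(object@classes) != expected) {
    return(sprintf("expected %d classes for k = %d", expected, k))
  }
  if (any(object@kmerToClass < 1L) ||
      any(object@kmerToClass > length(object@classes))) {
    return("kmerToClass indices out of range")
  }
  TRUE
})

#' Fragment-by-class composition matrix
#'
#' Holds the percentage composition of degenerate oligonucleotide classes in
#' each genomic fragment, together with fragment provenance (species, source
#' sequence, 0-based half-open coordinates) and the number of valid
#' (N-free) k-mer windows counted per fragment. Rows are fragments, columns
#' are classes of the associated [DegeClassIndex].
#'
#' @slot values Numeric matrix, fragments x classes, percentages. Each row
#'   sums to 100 (within numerical tolerance).
#' @slot fragments [GenomicRanges::GRanges] of fragment provenance with
#'   metadata columns `species` and `valid_fraction`.
#' @slot index The [DegeClassIndex] used for counting.
#' @slot validCounts Integer vector, number of N-free k-mer windows counted
#'   in each fragment.
#'
#' @seealso [compositionMatrix()]
#' @export
setClass("CompositionMatrix",
  representation(
    values = "matrix",
    fragments = "GRanges",
    index = "DegeClassIndex",
    validCounts = "numeric"
  )
)

setValidity("CompositionMatrix", function(object) {
  n <- nrow(object@values)
  if (length(object@fragments) != n) {
    return("fragments must have one range per matrix row")
  }
  if (length(object@validCounts) != n) {
    return("validCounts must have one entry per matrix row")
  }
  if (ncol(object@values) != length(object@index@classes)) {
    return("matrix columns must match index classes")
  }
  if (any(object@values < 0)) {
    return("composition percentages must be non-negative")
  }
  rs <- rowSums(object@values)
  ok <- object@validCounts > 0
  if (any(ok) && any(abs(rs[ok] - 100) > 1e-6)) {
    return("rows with valid counts must sum to 100")
  }
  if (!all(c("species", "valid_fraction") %in%
           colnames(S4Vectors::mcols(object@fragments)))) {
    return("fragments must carry 'species' and 'valid_fraction' columns")
  }
  TRUE
})

#' Batch-learning self-organizing map of composition vectors
#'
#' A rectangular lattice of `I x J` nodes (first axis follows the first
#' principal component of the training matrix). Node (i, j), with
#' `i = 0..I-1` and `j = 0..J-1`, has linear index `i*J + j`; weights are
#' stored with nodes in linear-index order. Fragments are assigned to the
#' node whose weight vector is nearest in Euclidean distance (best-matching
#' unit, BMU).
#'
#' @slot I,J Lattice dimensions (nodes along first / second PC axis).
#' @slot weights Numeric matrix, `I*J` x classes; row `m` is the weight
#'   vector of the node with linear index `m - 1`.
#' @slot classLabels Column labels (degenerate class labels).
#' @slot sigma1,sigma2 Standard deviations of the first and second principal
#'   components of the training matrix.
#' @slot assignments Integer vector: for each training fragment, the 1-based
#'   row of `weights` holding its BMU (empty until trained).
#' @slot fragments Provenance [GenomicRanges::GRanges] of the training
#'   fragments (may be empty).
#' @slot trained Logical flag.
#' @slot config List of training parameters (see [blsomConfig()]).
#'
#' @seealso [initLattice()], [trainBLSOM()], [assignNodes()]
#' @export
setClass("BLSOMModel",
  representation(
    I = "integer",
    J = "integer",
    weights = "matrix",
    classLabels = "character",
    sigma1 = "numeric",
    sigma2 = "numeric",
    assignments = "integer",
    fragments = "GRanges",
    trained = "logical",
    config = "list"
  )
)

setValidity("BLSOMModel", function(object) {
  if (object@I < 1L || object@J < 1L) return("lattice dimensions must be >= 1")
  if (nrow(object@weights) != object@I * object@J) {
    return("weights must have I*J rows")
  }
  if (ncol(object@weights) != length(object@classLabels)) {
    return("weight columns must match classLabels")
  }
  if (length(object@assignments) &&
      (any(object@assignments < 1L) ||
       any(object@assignments > nrow(object@weights)))) {
    return("assignments out of node range")
  }
  TRUE
})

#' Per-node derived map layer
#'
#' A single derived grid over the SOM lattice: territory categories
#' (`"single:<label>"`, `"multiple"`, `"vacant"`), a min-max normalized
#' U-matrix, or 21-level heatmap bins for one oligonucleotide class.
#'
#' @slot I,J Lattice dimensions.
#' @slot kind One of `"territory"`, `"umatrix"`, `"heatmap"`.
#' @slot values Vector over nodes in linear-index order: character for
#'   territory layers, numeric in `[0, 1]` for U-matrix layers, integer bins
#'   `0..20` for heatmap layers.
#' @slot label For heatmap layers, the oligonucleotide class displayed.
#' @export
setClass("MapLayer",
  representation(
    I = "integer",
    J = "integer",
    kind = "character",
    values = "ANY",
    label = "character"
  )
)

setValidity("MapLayer", function(object) {
  if (length(object@values) != object@I * object@J) {
    return("values must have one entry per node")
  }
  if (!object@kind %in% c("territory", "umatrix", "heatmap")) {
    return("kind must be territory, umatrix or heatmap")
  }
  TRUE
})
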