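# Accessors and show() methods for the core classes.

#' @describeIn DegeClassIndex-class Number of degenerate classes.
#' @param x,object A `DegeClassIndex`.
#' @export
setMethod("length", "DegeClassIndex", function(x) length(x@classes))

#' Class labels of a degenerate index or composition matrix
#' @param x A [DegeClassIndex] or [CompositionMatrix].
#' @return Character vector of class display labels (e.g. `"GA+TC"`).
#' @export
setGeneric("degeClasses", function(x) standardGeneric("degeClasses"))

#' @rdname degeClasses
#' @export
setMethod("degeClasses", "DegeClassIndex", function(x) x@classes)

#' @rdname degeClasses
#' @export
setMethod("degeClasses", "CompositionMatrix", function(x) x@index@classes)

#' Oligonucleotide length of an index
#' @param x A [DegeClassIndex] or [CompositionMatrix].
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' @rdname kmerSize
#' @export
setMethod("kmerSize", "DegeClassIndex", function(x) x@k)

#' @rdname kmerSize
#' @export
setMethod("kmerSize", "CompositionMatrix", function(x) x@index@k)

setMethod("show", "DegeClassIndex", function(object) {
  cat(sprintf(
    "DegeClassIndex: k = %d, %d strand-merged classes (of %d k-mers)\n",
    object@k, length(object@classes), 4L^object@k
  ))
  cat("  first classes:",
      paste(head(object@classes, 5L), collapse = ", "), "...\n")
})

#' Composition values, fragment provenance and valid window counts
#'
#' `compositionValues()` returns the fragments x classes percentage matrix,
#' `fragmentRanges()` the provenance `GRanges`, and `validCounts()` the
#' number of N-free k-mer windows counted per fragment.
#'
#' @param x A [CompositionMatrix] (or [BLSOMModel] for `fragmentRanges`).
#' @export
setGeneric("compositionValues", function(x) standardGeneric("compositionValues"))

#' @rdname compositionValues
#' @export
setMethod("compositionValues", "CompositionMatrix", function(x) x@values)

#' @rdname compositionValues
#' @export
setGeneric("fragmentRanges", function(x) standardGeneric("fragmentRanges"))

#' @rdname compositionValues
#' @export
setMethod("fragmentRanges", "CompositionMatrix", function(x) x@fragments)

#' @rdname compositionValues
#' @export
setMethod("fragmentRanges", "BLSOMModel", function(x) x@fragments)

#' @rdname compositionValues
#' @export
setGeneric("validCounts", function(x) standardGeneric("validCounts"))

#' @rdname compositionValues
#' @export
setMethod("validCounts", "CompositionMatrix", function(x) x@validCounts)

#' @describeIn CompositionMatrix-class Dimensions (fragments, classes).
#' @param x A `CompositionMatrix`.
#' @export
setMethod("dim", "CompositionMatrix", function(x) dim(x@values))

setMethod("show", "CompositionMatrix", function(object) {
  cat(sprintf(
    "CompositionMatrix: %d fragments x %d classes (k = %d)\n",
    nrow(object@values), ncol(object@values), object@index@k
  ))
  sp <- unique(S4Vectors::mcols(object@fragments)$species)
  cat(sprintf("  species: %s\n", paste(sp, collapse = ", ")))
})

#' Lattice dimensions of a SOM
#' @param x A [BLSOMModel].
#' @return Named integer vector `c(I = ..., J = ...)`.
#' @export
setGeneric("latticeDim", function(x) standardGeneric("latticeDim"))

#' @rdname latticeDim
#' @export
setMethod("latticeDim", "BLSOMModel", function(x) c(I = x@I, J = x@J))

#' Node weight vectors of a SOM
#' @param x A [BLSOMModel].
#' @return `I*J` x classes matrix, nodes in linear-index (`i*J + j`) order.
#' @export
setGeneric("nodeWeights", function(x) standardGeneric("nodeWeights"))

#' @rdname nodeWeights
#' @export
setMethod("nodeWeights", "BLSOMModel", function(x) x@weights)

#' Fragment-to-node assignments of a trained SOM
#' @param x A [BLSOMModel].
#' @return Integer vector of 1-based node rows (linear index + 1), one per
#'   training fragment.
#' @export
setGeneric("nodeAssignments", function(x) standardGeneric("nodeAssignments"))

#' @rdname nodeAssignments
#' @export
setMethod("nodeAssignments", "BLSOMModel", function(x) x@assignments)

setMethod("show", "BLSOMModel", function(object) {
  state <- if (object@trained) "trained" else "untrained"
  cat(sprintf(
    "BLSOMModel (%s): %d x %d lattice, %d-dimensional weights\n",
    state, object@I, object@J, ncol(object@weights)
  ))
  cat(sprintf("  sigma1 = %.4g, sigma2 = %.4g\n",
              object@sigma1, object@sigma2))
  if (length(object@assignments)) {
    occ <- length(unique(object@assignments))
    cat(sprintf("  %d fragments on %d occupied nodes (%d vacant)\n",
                length(object@assignments), occ,
                object@I * object@J - occ))
  }
})

#' Values of a map layer as an I x J matrix
#' @param x A [MapLayer].
#' @return Matrix with rows indexed by `i` (first lattice axis) and columns
#'   by `j`.
#' @export
setGeneric("layerMatrix", function(x) standardGeneric("layerMatrix"))

#' @rdname layerMatrix
#' @export
setMethod("layerMatrix", "MapLayer", function(x) {
  matrix(x@values, nrow = x@I, ncol = x@J, byrow = TRUE)
})

#' @describeIn MapLayer-class Values over nodes in linear-index order.
#' @param x A `MapLayer`.
#' @export
setGeneric("layerValues", function(x) standardGeneric("layerValues"))

#' @rdname MapLayer-class
#' @export
setMethod("layerValues", "MapLayer", function(x) x@values)

setMethod("show", "MapLayer", function(object) {
  cat(sprintf("MapLayer (%s): %d x %d lattice", object@kind,
              object@I, object@J))
  if (length(object@label) && nzchar(object@label)) {
    cat(sprintf(" [%s]", object@label))
  }
  cat("\n")
})
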