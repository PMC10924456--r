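# Map-level readouts of a trained SOM: territory categories per node,
# U-matrix (boundary strength), 21-level heatmap bins per oligonucleotide,
# clustering purity, and a heuristic flagger for satellite territories
# ("special zones": islands of locally distinct composition separated from
# a species' main territory by strong U-matrix boundaries).

.nodeLabelTable <- function(model, labels) {
  if (length(labels) != length(model@assignments)) {
    stop("need one label per assigned fragment")
  }
  if (anyNA(labels)) stop("unlabeled fragment(s) present")
  split(as.character(labels), model@assignments)
}

#' Territory map: node categories by fragment label
#'
#' Nodes whose fragments carry exactly one label are `"single:<label>"`;
#' nodes mixing two or more labels are `"multiple"` (rendered black in
#' territory plots); unoccupied nodes are `"vacant"`. Labels may be species,
#' lineage groups, or chromosomes (the single-species workflow).
#'
#' @param model A trained [BLSOMModel].
#' @param labels Character vector, one label per training fragment (in
#'   fragment order).
#' @return A [MapLayer] of kind `"territory"`.
#' @export
territoryMap <- function(model, labels) {
  stopifnot(is(model, "BLSOMModel"), model@trained)
  byNode <- .nodeLabelTable(model, labels)
  nNodes <- model@I * model@J
  cats <- rep("vacant", nNodes)
  for (nm in names(byNode)) {
    u <- unique(byNode[[nm]])
    cats[as.integer(nm)] <- if (length(u) == 1L) paste0("single:", u)
      else "multiple"
  }
  new("MapLayer", I = model@I, J = model@J, kind = "territory",
      values = cats, label = "")
}

# existing 8-neighbors of each node; returns list of integer node rows
.neighborList <- function(I, J) {
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  lapply(seq_len(I * J), function(m) {
    i <- (m - 1L) %/% J
    j <- (m - 1L) %% J
    ni <- i + offs$di
    nj <- j + offs$dj
    ok <- ni >= 0 & ni < I & nj >= 0 & nj < J
    as.integer(ni[ok] * J + nj[ok] + 1L)
  })
}

#' U-matrix of a trained SOM
#'
#' For every node, the mean Euclidean distance between its weight vector and
#' the weights of its existing 8-neighbors, min-max normalized to `[0, 1]`.
#' High values mark composition boundaries between clusters; species
#' territory borders coincide with dark U-matrix lines.
#'
#' @param model A trained [BLSOMModel] (lattice larger than 1 x 1).
#' @return A [MapLayer] of kind `"umatrix"`.
#' @export
computeUMatrix <- function(model) {
  stopifnot(is(model, "BLSOMModel"))
  if (model@I * model@J < 2L) stop("U-matrix undefined for a 1 x 1 lattice")
  nb <- .neighborList(model@I, model@J)
  W <- model@weights
  u <- vapply(seq_along(nb), function(m) {
    d <- sqrt(rowSums((W[nb[[m]], , drop = FALSE] -
                       rep(W[m, ], each = length(nb[[m]])))^2))
    mean(d)
  }, numeric(1))
  rng <- range(u)
  u <- if (rng[2] > rng[1]) (u - rng[1]) / (rng[2] - rng[1]) else u * 0
  new("MapLayer", I = model@I, J = model@J, kind = "umatrix",
      values = u, label = "")
}

#' 21-level heatmap bins for one oligonucleotide class
#'
#' The range between the minimum and maximum weight-vector frequency of the
#' class across nodes is divided into 21 equal bins; each node gets
#' `floor(21 * (f - fmin) / (fmax - fmin))` clamped to `0..20` (so the
#' maximum lands in bin 20, the minimum in bin 0). If all nodes share the
#' same frequency, every node gets the midpoint bin 10.
#'
#' @param model A [BLSOMModel].
#' @param classLabel A class label present in the model (e.g. `"GA+TC"`).
#' @return A [MapLayer] of kind `"heatmap"` with integer values `0..20`.
#' @export
heatmapBins <- function(model, classLabel) {
  stopifnot(is(model, "BLSOMModel"))
  if (!classLabel %in% model@classLabels) {
    stop("unknown class label: ", classLabel)
  }
  f <- model@weights[, classLabel]
  fmin <- min(f); fmax <- max(f)
  bins <- if (fmax > fmin) {
    pmin(pmax(floor(21 * (f - fmin) / (fmax - fmin)), 0L), 20L)
  } else {
    rep(10L, length(f))
  }
  new("MapLayer", I = model@I, J = model@J, kind = "heatmap",
      values = as.integer(bins), label = classLabel)
}

#' Clustering purity of a labeled map
#'
#' Fraction of fragments assigned to nodes whose occupants all share one
#' label. A purity near 1 quantifies the qualitative observation that nodes
#' mixing several species are rare on genome-signature maps.
#'
#' @inheritParams territoryMap
#' @return A number in `[0, 1]`.
#' @export
mapPurity <- function(model, labels) {
  terr <- territoryMap(model, labels)
  pure <- startsWith(layerValues(terr)[model@assignments], "single:")
  mean(pure)
}

#' Node occupancy table
#'
#' @inheritParams territoryMap
#' @return Data frame with one row per node: coordinates, category, and the
#'   number of fragments per label.
#' @export
nodeTable <- function(model, labels) {
  terr <- territoryMap(model, labels)
  co <- nodeCoordinates(model)
  labs <- sort(unique(as.character(labels)))
  counts <- matrix(0L, nrow = model@I * model@J, ncol = length(labs),
                   dimnames = list(NULL, labs))
  tab <- table(model@assignments, factor(labels, levels = labs))
  counts[as.integer(rownames(tab)), ] <- as.integer(tab)
  data.frame(co, category = layerValues(terr), counts, check.names = FALSE)
}

#' Flag special-zone (satellite territory) candidates
#'
#' Special zones are small islands of nodes, occupied by a single label,
#' that lie away from that label's main territory and are fenced by strong
#' U-matrix boundaries — the map signature of genomic regions whose local
#' oligonucleotide composition departs from the species' genome signature.
#' This flagger finds 8-connected components of `single:<label>` nodes that
#' are (i) disjoint from the label's largest component and (ii) whose
#' outward-facing nodes have a mean U-matrix value at or above the given
#' quantile of all U-matrix values. It is an explicit quantitative surrogate
#' for what is usually identified by visual inspection.
#'
#' @inheritParams territoryMap
#' @param umatrix Optional precomputed [MapLayer] from [computeUMatrix()].
#' @param quantile Boundary-strength quantile threshold (default 0.9).
#' @return Data frame with columns `label`, `component` (id within label),
#'   `node`, `i`, `j`; zero rows when nothing is flagged.
#' @export
flagSpecialZoneCandidates <- function(model, labels, umatrix = NULL,
                                      quantile = 0.9) {
  stopifnot(is(model, "BLSOMModel"), model@trained)
  if (is.null(umatrix)) umatrix <- computeUMatrix(model)
  u <- layerValues(umatrix)
  thr <- stats::quantile(u, quantile, names = FALSE)
  terr <- layerValues(territoryMap(model, labels))
  nb <- .neighborList(model@I, model@J)
  out <- list()
  for (lab in unique(as.character(labels))) {
    sel <- which(terr == paste0("single:", lab))
    if (length(sel) == 0L) next
    # 8-connected components among this label's nodes
    edges <- do.call(rbind, lapply(sel, function(m) {
      hits <- intersect(nb[[m]], sel)
      if (length(hits)) cbind(m, hits) else NULL
    }))
    g <- igraph::graph_from_data_frame(
      d = if (is.null(edges)) data.frame(from = integer(0), to = integer(0))
          else data.frame(from = as.character(edges[, 1]),
                          to = as.character(edges[, 2])),
      directed = FALSE,
      vertices = data.frame(name = as.character(sel))
    )
    comp <- igraph::components(g)
    membership <- comp$membership[as.character(sel)]
    sizes <- table(membership)
    main <- names(sizes)[which.max(sizes)]
    for (cid in setdiff(names(sizes), main)) {
      nodes <- sel[membership == cid]
      boundary <- nodes[vapply(nodes, function(m) {
        length(setdiff(nb[[m]], nodes)) > 0L
      }, logical(1))]
      if (length(boundary) == 0L) next
      if (mean(u[boundary]) >= thr) {
        co <- nodeCoordinates(model, nodes)
        out[[length(out) + 1L]] <- data.frame(
          label = lab, component = as.integer(cid), co
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(label = character(0), component = integer(0),
                      node = integer(0), i = integer(0), j = integer(0)))
  }
  do.call(rbind, out)
}

#' Special-zone table with genomic coordinates
#'
#' Expands flagged satellite components into the fragments they host:
#' species, component id, source sequence and 0-based half-open coordinates.
#'
#' @inheritParams flagSpecialZoneCandidates
#' @return Data frame (`species`, `zone`, `source`, `start`, `end`), one row
#'   per fragment in a flagged zone.
#' @export
specialZoneTable <- function(model, labels, umatrix = NULL, quantile = 0.9) {
  cand <- flagSpecialZoneCandidates(model, labels, umatrix, quantile)
  if (nrow(cand) == 0L || length(model@fragments) == 0L) {
    return(data.frame(species = character(0), zone = character(0),
                      source = character(0), start = integer(0),
                      end = integer(0)))
  }
  fr <- model@fragments
  rows <- lapply(seq_len(nrow(cand)), function(r) {
    hit <- which(model@assignments == cand$node[r])
    data.frame(
      species = S4Vectors::mcols(fr)$species[hit],
      zone = paste0(cand$label[r], "_SZ", cand$component[r]),
      source = as.character(GenomicRanges::seqnames(fr))[hit],
      start = GenomicRanges::start(fr)[hit] - 1L,
      end = GenomicRanges::end(fr)[hit]
    )
  })
  do.call(rbind, rows)
}
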