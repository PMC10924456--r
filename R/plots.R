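# Base-graphics renders of map layers. Heatmaps use a 21-step diverging
# palette (red/blue by default; orange/blue alternative for accessibility).

.degePalette <- function(scheme = c("red_blue", "orange_blue")) {
  scheme <- match.arg(scheme)
  ends <- if (scheme == "red_blue") c("darkblue", "white", "darkred")
          else c("darkblue", "white", "darkorange3")
  grDevices::colorRampPalette(ends)(21)
}

#' Plot a map layer
#'
#' Territory layers color nodes by label (black = multiple labels, white =
#' vacant); U-matrix layers use a grey ramp (dark = strong boundary);
#' heatmap layers use the 21-step diverging palette.
#'
#' @param layer A [MapLayer].
#' @param palette `"red_blue"` (default) or `"orange_blue"` for heatmap
#'   layers.
#' @param main Plot title.
#' @return Invisibly, the matrix of colors drawn.
#' @export
plotMapLayer <- function(layer, palette = "red_blue", main = NULL) {
  stopifnot(is(layer, "MapLayer"))
  I <- layer@I; J <- layer@J
  vals <- layerValues(layer)
  cols <- switch(layer@kind,
    territory = {
      labs <- sort(unique(sub("^single:", "", vals[startsWith(vals, "single:")])))
      pal <- grDevices::hcl.colors(max(length(labs), 1L), "Dark 3")
      out <- rep("white", length(vals))
      out[vals == "multiple"] <- "black"
      for (q in seq_along(labs)) {
        out[vals == paste0("single:", labs[q])] <- pal[q]
      }
      out
    },
    umatrix = grDevices::grey(1 - vals),
    heatmap = .degePalette(palette)[vals + 1L]
  )
  if (is.null(main)) {
    main <- if (nzchar(layer@label)) paste(layer@kind, layer@label)
            else layer@kind
  }
  cm <- matrix(cols, nrow = I, ncol = J, byrow = TRUE)
  graphics::plot(NULL, xlim = c(0, I), ylim = c(0, J), asp = 1,
                 xlab = "i (first PC axis)", ylab = "j (second PC axis)",
                 main = main, xaxs = "i", yaxs = "i")
  for (i in seq_len(I)) {
    graphics::rect(i - 1, seq_len(J) - 1, i, seq_len(J),
                   col = cm[i, ], border = NA)
  }
  invisible(cm)
}

#' Plot a chromosomal track
#'
#' @param track A track from [frequencyTrack()] or [motifTrack()].
#' @param peaks Optional indices from [flagPeaks()] to mark.
#' @param main Plot title.
#' @export
plotTrack <- function(track, peaks = NULL, main = NULL) {
  pos <- (GenomicRanges::start(track) - 1 +
          GenomicRanges::end(track)) / 2 / 1e6
  v <- S4Vectors::mcols(track)$value
  kind <- S4Vectors::metadata(track)$value_kind
  ylab <- if (identical(kind, "motif_count")) "occurrences"
          else "frequency (%)"
  graphics::plot(pos, v, type = "l", xlab = "position (Mb)", ylab = ylab,
                 main = main)
  graphics::points(pos, v, pch = 16, cex = 0.4)
  if (length(peaks)) {
    graphics::points(pos[peaks], v[peaks], col = "red", pch = 16)
  }
}
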