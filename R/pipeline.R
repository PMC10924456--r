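# End-to-end orchestration: ingest -> count -> train -> diagnostics ->
# stats -> scans, writing TSV artifacts and a machine-readable manifest.
# The single-species workflow (territories colored by chromosome) is the
# same code path with labelMode = "chromosome".

#' Pipeline configuration
#'
#' @param windowSize Fragment size in bases (1e6 or 1e5 typical).
#' @param k Degenerate oligonucleotide length (2..5).
#' @param blsom A [blsomConfig()].
#' @param labelMode `"species"`, `"lineage"` or `"chromosome"` — what the
#'   territory map is colored by.
#' @param lineageMap Named character vector species -> lineage group;
#'   required (and must cover all input species) when
#'   `labelMode = "lineage"`.
#' @param minValidFraction Minimum non-N fraction per retained window.
#' @param trackClasses Degenerate dinucleotide classes to scan along each
#'   chromosome (default `c("GA+TC", "AG+CT", "CG", "GC")`).
#' @param szQuantile U-matrix quantile for special-zone flagging.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when inputs are generated).
#' @return List of class `runConfig`.
#' @export
runConfig <- function(windowSize = 1e5, k = 3, blsom = blsomConfig(),
                      labelMode = c("species", "lineage", "chromosome"),
                      lineageMap = NULL, minValidFraction = 0.5,
                      trackClasses = c("GA+TC", "AG+CT", "CG", "GC"),
                      szQuantile = 0.9, seed = 1L) {
  labelMode <- match.arg(labelMode)
  stopifnot(k >= 2, k <= 5, windowSize >= 10 * k)
  structure(list(
    windowSize = windowSize, k = as.integer(k), blsom = blsom,
    labelMode = labelMode, lineageMap = lineageMap,
    minValidFraction = minValidFraction, trackClasses = trackClasses,
    szQuantile = szQuantile, seed = as.integer(seed)
  ), class = "runConfig")
}

.fragmentLabels <- function(fragments, config) {
  sp <- S4Vectors::mcols(fragments)$species
  switch(config$labelMode,
    species = sp,
    chromosome = as.character(GenomicRanges::seqnames(fragments)),
    lineage = {
      if (is.null(config$lineageMap)) {
        stop("labelMode 'lineage' requires a lineageMap")
      }
      missing <- setdiff(unique(sp), names(config$lineageMap))
      if (length(missing)) {
        stop("lineageMap missing species: ",
             paste(missing, collapse = ", "))
      }
      unname(config$lineageMap[sp])
    }
  )
}

#' Run the full genome-signature pipeline
#'
#' Reads (or accepts) assemblies, pools short scaffolds with N separators,
#' tiles windows, computes the degenerate composition matrix, trains a
#' batch-learning SOM, and derives territory/U-matrix/heatmap layers,
#' purity, special-zone candidates, per-fragment statistics and per-
#' chromosome dinucleotide tracks. All tables are written under `outDir`;
#' a `manifest.json` records the configuration and artifact list. The run
#' is deterministic: identical inputs, config and seed give identical
#' outputs.
#'
#' @param inputs Either a named character vector of FASTA paths (names =
#'   species labels) or a [Biostrings::DNAStringSet] with a `species`
#'   metadata column.
#' @param config A [runConfig()].
#' @param outDir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @return List with `records`, `fragments`, `composition`, `model`,
#'   `territory`, `umatrix`, `purity`, `specialZones`, `fragmentStats`,
#'   `chromosomeStats`, `tracks`, `manifest`.
#' @export
runPipeline <- function(inputs, config = runConfig(), outDir = NULL) {
  if (is.character(inputs)) {
    if (is.null(names(inputs))) stop("FASTA paths must be named by species")
    recs <- lapply(names(inputs), function(sp) {
      readGenomeFasta(inputs[[sp]], sp)
    })
    records <- do.call(c, recs)
  } else if (is(inputs, "DNAStringSet")) {
    records <- inputs
    if (is.null(S4Vectors::mcols(records)$species)) {
      stop("records must carry a 'species' metadata column")
    }
  } else {
    stop("inputs must be FASTA paths or a DNAStringSet")
  }
  message("ingest: ", length(records), " record(s), ",
          sum(Biostrings::width(records)), " bases")
  records <- concatenateWithN(records, minLength = config$windowSize)
  fragments <- tileWindows(records, config$windowSize,
                           config$minValidFraction)
  message("tiling: ", length(fragments), " fragment(s) of ",
          config$windowSize, " bases")
  index <- buildDegeIndex(config$k)
  cm <- compositionMatrix(records, fragments, index)
  model <- trainBLSOM(cm, config = config$blsom)
  labels <- .fragmentLabels(fragmentRanges(cm), config)
  terr <- territoryMap(model, labels)
  um <- computeUMatrix(model)
  purity <- mapPurity(model, labels)
  cats <- layerValues(terr)
  message(sprintf(
    "map: %d x %d lattice, purity %.3f, %d multiple, %d vacant node(s)",
    model@I, model@J, purity, sum(cats == "multiple"),
    sum(cats == "vacant")))
  sz <- specialZoneTable(model, labels, um, config$szQuantile)
  fstats <- fragmentStats(records, fragmentRanges(cm))
  cstats <- chromosomeStats(records)
  tracks <- list()
  for (cl in config$trackClasses) {
    for (nm in names(records)) {
      if (Biostrings::width(records[nm]) < config$windowSize) next
      tracks[[paste(cl, nm, sep = "|")]] <-
        frequencyTrack(records[nm], config$windowSize, cl)
    }
  }
  manifest <- list(
    package = "oligoSOM",
    version = as.character(utils::packageVersion("oligoSOM")),
    config = unclass(config)[setdiff(names(unclass(config)),
                                     c("blsom", "lineageMap"))],
    blsom = unclass(config$blsom),
    n_records = length(records),
    n_fragments = length(fragments),
    lattice = c(I = model@I, J = model@J),
    purity = purity,
    artifacts = character(0)
  )
  out <- list(records = records, fragments = fragments, composition = cm,
              model = model, territory = terr, umatrix = um,
              purity = purity, specialZones = sz,
              fragmentStats = fstats, chromosomeStats = cstats,
              tracks = tracks, manifest = manifest)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    art <- c(
      fragments = writeFragmentManifest(
        fragments, file.path(outDir, "fragments.tsv")),
      composition = writeCompositionTSV(
        cm, file.path(outDir, "composition.tsv")),
      model = writeBLSOM(model, file.path(outDir, "blsom")),
      nodes = {
        p <- file.path(outDir, "nodes.tsv")
        nt <- nodeTable(model, labels)
        nt$umatrix <- layerValues(um)
        write.table(nt, p, sep = "\t", quote = FALSE, row.names = FALSE)
        p
      },
      special_zones = {
        p <- file.path(outDir, "special_zones.tsv")
        write.table(sz, p, sep = "\t", quote = FALSE, row.names = FALSE)
        p
      },
      fragment_stats = {
        p <- file.path(outDir, "fragment_stats.tsv")
        write.table(fstats, p, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        p
      },
      chromosome_stats = {
        p <- file.path(outDir, "chromosome_stats.tsv")
        write.table(cstats, p, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        p
      }
    )
    for (nm in names(tracks)) {
      p <- file.path(outDir, paste0(
        "track_", gsub("[^A-Za-z0-9_]+", "_", nm), ".tsv"))
      writeTrackTSV(tracks[[nm]], p)
      art[paste0("track|", nm)] <- p
    }
    manifest$artifacts <- as.list(art)
    out$manifest <- manifest
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
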