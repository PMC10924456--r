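# Synthetic multi-species genomes with the statistical structure that
# genome-signature analysis assumes: each "species" is an order-1 Markov
# chain over A/C/G/T with its own stationary G+C% and CG dinucleotide bias,
# optionally carrying localized zones enriched for a chosen dinucleotide
# pair (emulating dinucleotide-rich pericentromeric terminal regions).

.BASES <- c("A", "C", "G", "T")

.stationary <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

#' Build a species emitter model
#'
#' Constructs an order-1 Markov chain whose stationary distribution matches
#' the target G+C% (solved by fixed-point iteration on the base
#' composition, checked analytically) and whose CG odds ratio is tuned by
#' `cgSuppression`: the transition probability C -> G is scaled by this
#' factor (deficit or excess redistributed equally to C -> A and C -> T), so
#' the chain's analytic CG odds ratio is approximately `cgSuppression`.
#' Model construction involves no randomness; the stored seed governs
#' sequence generation.
#'
#' @param label Species label.
#' @param targetGC Target stationary G+C percentage (10..90).
#' @param cgSuppression CG bias factor (1 = independence, < 1 suppresses
#'   CG). Default 1.
#' @param seed Integer seed for [generateGenome()].
#' @return List of class `SpeciesModel`: `label`, `transition` (4 x 4),
#'   `stationary`, `targetGC`, `achievedGC`, `cgOddsRatio` (analytic),
#'   `cgSuppression`, `seed`.
#' @export
makeSpeciesModel <- function(label, targetGC, cgSuppression = 1,
                             seed = 1L) {
  stopifnot(targetGC >= 10, targetGC <= 90, cgSuppression > 0)
  g <- targetGC / 100
  bEff <- cgSuppression
  for (iter in 1:200) {
    p <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
    P <- matrix(rep(p, each = 4), nrow = 4,
                dimnames = list(.BASES, .BASES))
    delta <- (bEff - 1) * p[["G"]]
    P["C", "G"] <- P["C", "G"] + delta
    P["C", "A"] <- P["C", "A"] - delta / 2
    P["C", "T"] <- P["C", "T"] - delta / 2
    if (any(P < 0)) {
      stop("infeasible cgSuppression/targetGC combination")
    }
    pi <- .stationary(P)
    gcNow <- pi[2] + pi[3]
    orNow <- P["C", "G"] / pi[3]
    if (abs(gcNow * 100 - targetGC) < 1e-10 &&
        abs(orNow - cgSuppression) < 1e-10) break
    # joint fixed point: base composition toward target GC, bias factor
    # toward the requested stationary odds ratio
    g <- min(max(g * (targetGC / 100) / gcNow, 0.02), 0.98)
    bEff <- bEff * cgSuppression / orNow
  }
  names(pi) <- .BASES
  orCG <- P["C", "G"] / pi[["G"]]
  structure(list(
    label = label,
    transition = P,
    stationary = pi,
    targetGC = targetGC,
    achievedGC = 100 * (pi[["C"]] + pi[["G"]]),
    cgOddsRatio = unname(orCG),
    cgSuppression = cgSuppression,
    seed = as.integer(seed)
  ), class = "SpeciesModel")
}

#' @export
print.SpeciesModel <- function(x, ...) {
  cat(sprintf(
    "SpeciesModel '%s': stationary G+C %.2f%% (target %.1f), CG OR %.3f\n",
    x$label, x$achievedGC, x$targetGC, x$cgOddsRatio
  ))
  invisible(x)
}

#' Specify an enriched zone
#'
#' @param chromosome 1-based index into the chromosome list of
#'   [generateGenome()].
#' @param length Zone length in bases.
#' @param enrichedClass Degenerate dinucleotide class to enrich (e.g.
#'   `"GA+TC"`).
#' @param fold Target enrichment multiplier vs. the chain's stationary
#'   frequency (must exceed 1).
#' @param placement `"terminal"` (zone at the chromosome end) or an integer
#'   0-based offset.
#' @return List of class `ZoneSpec`.
#' @export
zoneSpec <- function(chromosome, length, enrichedClass = "GA+TC",
                     fold = 2, placement = "terminal") {
  stopifnot(fold > 1, length >= 2)
  structure(list(chromosome = as.integer(chromosome),
                 length = as.integer(length),
                 enrichedClass = enrichedClass,
                 fold = fold, placement = placement),
            class = "ZoneSpec")
}

# stationary frequency of a dinucleotide class under the chain
.classStationaryFreq <- function(model, classLabel) {
  members <- degeClassMembers(classLabel)
  sum(vapply(members, function(m) {
    a <- substr(m, 1, 1); b <- substr(m, 2, 2)
    model$stationary[[a]] * model$transition[a, b]
  }, numeric(1)))
}

.sampleChain <- function(model, n) {
  cumP <- t(apply(model$transition, 1, cumsum))
  init <- findInterval(runif(1), cumsum(model$stationary)) + 1L
  path <- markov_path(cumP, init, runif(n - 1))
  paste(.BASES[path], collapse = "")
}

# plant m member dinucleotides at non-overlapping even offsets inside seq
.enrichZone <- function(seqChar, model, zone) {
  L <- nchar(seqChar)
  f0 <- .classStationaryFreq(model, zone$enrichedClass)
  members <- degeClassMembers(zone$enrichedClass)
  pi <- model$stationary
  # expected net occurrences per planted member: the planted window itself,
  # plus whatever the two junction windows (flanking base + planted base)
  # contribute afterwards, minus the three prior windows it overwrites
  # (each a member with stationary probability f0)
  junction <- function(first) {
    mean(vapply(members, function(w) {
      sum(vapply(members, function(m) {
        if (first) {
          (substr(m, 2, 2) == substr(w, 1, 1)) * pi[[substr(m, 1, 1)]]
        } else {
          (substr(m, 1, 1) == substr(w, 2, 2)) * pi[[substr(m, 2, 2)]]
        }
      }, numeric(1)))
    }, numeric(1)))
  }
  net <- 1 + junction(TRUE) + junction(FALSE) - 3 * f0
  if (net < 0.1) stop("class too frequent to enrich by planting")
  m <- round((zone$fold - 1) * f0 * L / net)
  starts <- seq(1L, L - 1L, by = 2L)
  if (m > length(starts)) stop("zone too short for requested fold")
  at <- sort(sample(starts, m))
  members <- degeClassMembers(zone$enrichedClass)
  ins <- sample(members, m, replace = TRUE)
  s <- strsplit(seqChar, "", fixed = TRUE)[[1]]
  s[at] <- substr(ins, 1, 1)
  s[at + 1L] <- substr(ins, 2, 2)
  paste(s, collapse = "")
}

#' Generate a synthetic genome for one species
#'
#' Samples each chromosome from the species' Markov chain; zone intervals
#' are then re-emitted with planted member dinucleotides until the requested
#' fold enrichment over the stationary frequency is met (G+C stays close to
#' background, so zone enrichment is not a mononucleotide artifact).
#' Optionally splits chromosomes into fixed-length scaffolds to exercise
#' N-separator concatenation. Fully reproducible from the seed.
#'
#' @param model A [makeSpeciesModel()] result.
#' @param chromosomeLengths Integer vector of chromosome lengths (>= 10 kb).
#' @param zones List of [zoneSpec()] objects (may be empty). Zones on the
#'   same chromosome must not overlap.
#' @param scaffoldSplit Optional scaffold length; when set, chromosomes are
#'   cut into consecutive pieces of this size (last piece may be shorter).
#' @param seed Seed; defaults to the model's stored seed.
#' @return [Biostrings::DNAStringSet] with a `species` metadata column;
#'   chromosome names are `<label>_chr<n>` (scaffolds append `_s<m>`).
#'   Zone coordinates (0-based half-open) are recorded in
#'   `metadata()$zones`.
#' @export
generateGenome <- function(model, chromosomeLengths, zones = list(),
                           scaffoldSplit = NULL, seed = model$seed) {
  stopifnot(inherits(model, "SpeciesModel"),
            all(chromosomeLengths >= 10000))
  set.seed(seed)
  chroms <- character(length(chromosomeLengths))
  zoneRows <- list()
  for (ci in seq_along(chromosomeLengths)) {
    L <- chromosomeLengths[ci]
    s <- .sampleChain(model, L)
    czones <- Filter(function(z) z$chromosome == ci, zones)
    iv <- lapply(czones, function(z) {
      if (identical(z$placement, "terminal")) {
        c(L - z$length, L)  # 0-based half-open
      } else {
        c(z$placement, z$placement + z$length)
      }
    })
    if (length(iv) > 1L) {
      o <- order(vapply(iv, `[`, numeric(1), 1))
      ivo <- iv[o]
      for (q in seq_len(length(ivo) - 1L)) {
        if (ivo[[q]][2] > ivo[[q + 1L]][1]) stop("overlapping zones")
      }
    }
    for (q in seq_along(czones)) {
      z <- czones[[q]]
      a <- iv[[q]][1]; b <- iv[[q]][2]
      if (a < 0 || b > L) stop("zone exceeds chromosome")
      sub <- substr(s, a + 1L, b)
      enr <- .enrichZone(sub, model, z)
      substr(s, a + 1L, b) <- enr
      zoneRows[[length(zoneRows) + 1L]] <- data.frame(
        species = model$label,
        chromosome = paste0(model$label, "_chr", ci),
        start = a, end = b,
        enriched_class = z$enrichedClass, fold = z$fold
      )
    }
    chroms[ci] <- s
  }
  names(chroms) <- paste0(model$label, "_chr", seq_along(chroms))
  if (!is.null(scaffoldSplit)) {
    pieces <- list()
    for (nm in names(chroms)) {
      L <- nchar(chroms[[nm]])
      starts <- seq(1L, L, by = scaffoldSplit)
      ends <- pmin(starts + scaffoldSplit - 1L, L)
      p <- substring(chroms[[nm]], starts, ends)
      names(p) <- paste0(nm, "_s", seq_along(p))
      pieces[[nm]] <- p
    }
    chroms <- unlist(unname(pieces))
  }
  out <- Biostrings::DNAStringSet(chroms)
  S4Vectors::mcols(out)$species <- model$label
  S4Vectors::metadata(out)$zones <-
    if (length(zoneRows)) do.call(rbind, zoneRows) else NULL
  out
}

#' Generate a labeled multi-species community
#'
#' Builds `nSpecies` species models with pairwise distinct stationary G+C
#' (4-point spacing, starting at 30%) and distinct CG biases, generates two
#' chromosomes per species, and splits one species into sub-window
#' scaffolds so the N-concatenation path is exercised. Returns the records
#' plus a truth table sufficient to score territory purity downstream.
#'
#' @param nSpecies Number of species (2..30).
#' @param windowSize Analysis window the community is sized for; each
#'   species gets two chromosomes totalling `25 * windowSize` bases
#'   (25 fragments per species at the analysis window).
#' @param seed Master seed; per-species seeds are derived from it.
#' @return List with `records` ([Biostrings::DNAStringSet], `species`
#'   metadata column), `models` (list of [makeSpeciesModel()] results) and
#'   `truth` (data frame of per-species parameters).
#' @export
generateCommunity <- function(nSpecies = 5, windowSize = 1e5, seed = 1L) {
  stopifnot(nSpecies >= 2, nSpecies <= 30)
  gcs <- 30 + 4 * (seq_len(nSpecies) - 1)
  if (max(gcs) > 88) stop("too many species for 4-point G+C spacing")
  biases <- 0.5 + 0.15 * ((seq_len(nSpecies) - 1) %% 5)
  labels <- sprintf("sp%02d", seq_len(nSpecies))
  chromLen <- as.integer(25 * windowSize / 2) * 2L
  perChrom <- c(chromLen / 2L, chromLen / 2L)
  models <- lapply(seq_len(nSpecies), function(i) {
    makeSpeciesModel(labels[i], gcs[i], biases[i],
                     seed = seed * 100L + i)
  })
  scafSpecies <- min(3L, nSpecies)
  recs <- lapply(seq_len(nSpecies), function(i) {
    split <- if (i == scafSpecies) as.integer(windowSize * 0.6) else NULL
    generateGenome(models[[i]], perChrom, scaffoldSplit = split)
  })
  records <- do.call(c, recs)
  truth <- data.frame(
    species = labels,
    target_gc = gcs,
    cg_suppression = biases,
    achieved_gc = vapply(models, function(m) m$achievedGC, numeric(1)),
    n_chromosomes = 2L,
    chromosome_length = perChrom[1],
    scaffold_split = ifelse(seq_len(nSpecies) == scafSpecies,
                            as.integer(windowSize * 0.6), NA_integer_),
    seed = vapply(models, function(m) m$seed, integer(1))
  )
  list(records = records, models = models, truth = truth)
}

#' Write community fixtures to disk
#'
#' One FASTA per species plus a `truth.tsv` of generator parameters.
#'
#' @param community A [generateCommunity()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
writeCommunityFixtures <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- S4Vectors::mcols(community$records)$species
  for (lab in unique(sp)) {
    writeGenomeFasta(community$records[sp == lab],
                     file.path(dir, paste0(lab, ".fasta")))
  }
  write.table(community$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
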