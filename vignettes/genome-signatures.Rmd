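---
title: "Genome signatures with batch-learning self-organizing maps"
author: "oligoSOM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome signatures with batch-learning self-organizing maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoSOM)
```

## The problem and the model

Most fixed-size fragments (100 kb, 1 Mb) of a genome share a
species-specific oligonucleotide composition — the *genome signature*.
Because the signature is present in nearly every fragment, unsupervised
clustering of fragment composition vectors separates genomes by species
without alignment, gene annotation, or even complete assemblies. `oligoSOM`
implements this analysis end to end: ingest, strand-merged k-mer counting,
batch-SOM clustering, map diagnostics, composition statistics, and
chromosomal window scans.

### Strand-merged (degenerate) oligonucleotides

Public assemblies deposit an arbitrary one of the two complementary
strands, so composition must not depend on which strand was registered.
Each k-mer is therefore merged with its reverse complement into one class
(written `GA+TC`; self-complementary k-mers such as `CG` stay singletons),
giving $4^k/2$ classes for odd $k$ and $(4^k+4^{k/2})/2$ for even $k$:
10 (k=2), 32 (k=3), 136 (k=4), 512 (k=5). Counting slides a width-$k$
window with step 1 and skips every window containing N — this matters
because short scaffolds are pooled by joining them with a single N, which
silently removes all junction-crossing windows, so the pooled record counts
exactly like the sum of its parts. Composition vectors are percentages over
counted windows; the merged counting makes them exactly invariant under
reverse complementation.

### The batch-learning SOM

A conventional Kohonen SOM updates weights per presented sample, so the map
depends on presentation order. The batch variant removes that dependence:

1. **Initialization** (no randomness): weights are laid on the plane of the
   first two principal components of the composition matrix, spanning
   `sdMultiplier` (default 5) standard deviations along each axis, centred
   on the data mean. The node count is `round(N / seqsPerNode)` (default:
   10 fragments per node on average) and the lattice aspect ratio follows
   $\sigma_1/\sigma_2$: $J = \max(J_{min},
   \mathrm{round}\sqrt{n^\ast \sigma_2/\sigma_1})$, $I =
   \mathrm{round}(n^\ast/J)$.
2. **Epochs** (default 200, "several hundred" being conventional): every
   fragment is assigned to its best-matching unit (BMU, smallest Euclidean
   distance; ties go to the smallest linear index $iJ+j$), then every
   node's weight is replaced by the kernel-weighted mean of the fragments,
   with a Gaussian kernel $\exp(-d^2/2r(t)^2)$ over lattice distance and a
   radius decaying linearly from `max(I, J)/2` to 1. Nodes receiving zero
   kernel mass keep their previous weight.

The per-sample learning-rate schedule and neighborhood of the original
batch-SOM genome analyses are not fully specified in the literature this
package follows; the Gaussian kernel, linear radius decay and 200-epoch
default used here are documented substitutes, all exposed in
`blsomConfig()`.

**Exact order independence.** Batch updates make the map a function of the
*multiset* of rows mathematically, but floating-point addition is not
associative, so naive summation would still leak the row order. The
implementation sums fragments per node in a canonical lexicographic row
order (and computes the initialization PCA on rows in that order), so a
row-shuffled matrix yields *bit-identical* weights and assignments — this
is asserted in the test suite at 2000 x 32.

Composition percentages are used raw (no column standardization) by
default, matching practice for this analysis; `standardizeColumns = TRUE`
is available.

### Map diagnostics

* **Territory map**: a node is `single:<label>` when all its fragments
  share one label (species, lineage or chromosome — the single-species
  workflow is the same code path with chromosome labels), `multiple` when
  mixed (rendered black), `vacant` when empty. `mapPurity()` is the
  fraction of fragments on single-label nodes.
* **U-matrix**: per node, the mean Euclidean distance to its existing
  8-neighbors' weights, min-max normalized; high values fence clusters.
* **Heatmaps**: per oligonucleotide, the range between the minimum and
  maximum node frequency is divided into 21 bins;
  `floor(21 (f - f_{min})/(f_{max} - f_{min}))` clamped to 0..20, so the
  extremes land in bins 0 and 20. A constant map gets the midpoint bin 10
  (a choice; the published description fixes 21 divisions but no tie rule).
* **Special zones**: satellite territories — 8-connected components of
  single-label nodes disjoint from that label's largest component whose
  outward-facing nodes have mean U-matrix value at or above a quantile
  (default 0.9) of all values. Published special zones are identified by
  visual inspection; this flagger is an explicit, reproducible surrogate
  and is not claimed to reproduce visually drawn boundaries node-for-node.
  8-connectivity is used for both the U-matrix and components because
  territories on these maps are visually contiguous including diagonals.

### Statistics and scans

G+C% excludes N from numerator and denominator. Dinucleotide percentages
use the same overlapping-window, N-excluding convention as the k-mer
module (whether published odds ratios use overlapping windows is unstated;
this convention is documented and consistent across the package). The CG
odds ratio divides observed CG frequency by $p_C p_G$ from the same
fragment's mononucleotide composition, with no end-effect correction.
`boxplotSummary()` uses linearly interpolated quartiles
($p(k) = (k-1)/(n-1)$, R's type 7) with 1.5 IQR whiskers anchored at
extreme non-outlier points; the common `boxplot()` hinge convention differs
slightly at small n, which is why the package documents its own rule and
tests it against the `quantile()` oracle rather than `boxplot.stats()`.

Window tracks reuse the ingest tiling (0-based half-open, trailing partial
window discarded). Motif tracks count exact overlapping matches of a
strand-merged motif set; N never matches. `flagPeaks()` uses a robust z
rule, `value > median + z * 1.4826 \cdot MAD` with default `z = 5`: MAD
scaling keeps the rule stable on heavy-tailed tracks where a standard
deviation would be inflated by the peaks themselves.

## The synthetic world

`generateCommunity()` emulates a multi-species comparative study at desk
scale: each species is an order-1 Markov chain over A/C/G/T.

* **Stationary targets are solved, not sampled.** `makeSpeciesModel()`
  fixes the chain so that its *stationary* G+C equals the target and its
  *stationary* CG odds ratio equals the requested suppression factor
  (joint fixed-point iteration to 1e-10). Scaling $P(G\mid C)$ by the raw
  factor alone would overshoot the odds ratio (~0.56 for a requested 0.5)
  because the stationary $\pi_G$ shrinks too; the iteration removes that
  bias, which is what makes parameter-recovery tests meaningful.
* **Community defaults** (chosen once): G+C from 30% in 4-point steps
  (comfortably above the 3-point spacing the separation analysis assumes;
  real insect genomes span roughly 26-54%), CG suppression cycling
  0.5..1.1 in 0.15 steps (real insect CG odds ratios straddle 1), two
  chromosomes per species totalling 25 analysis windows, and one species
  split into 0.6-window scaffolds so the N-concatenation path is always
  exercised.
* **Enriched zones** emulate Mb-scale dinucleotide-rich pericentromeric
  terminal regions: member dinucleotides are planted at random
  non-overlapping even offsets inside the zone until a target fold over
  the stationary frequency is reached. The number of plants accounts
  analytically for the three windows each plant overwrites and the two
  junction windows it creates, so the realized fold tracks the request to
  a few percent. Because members of a strand-merged pair have identical
  G+C, zone enrichment is not a mononucleotide artifact — zone G+C stays
  near background.
* **What it does not emulate**: repeat families, satellite monomers,
  coding/non-coding mosaic, isochores, or assembly error. A green
  separation test therefore establishes that the pipeline recovers
  *composition* structure it was pointed at, not that it would resolve any
  two real genomes; conversely real genome signatures are stronger than a
  bare first-order chain, so the synthetic world is conservative about
  within-species homogeneity but optimistic about between-species
  simplicity.

All generation is seed-deterministic (uniform variates drawn from R's RNG,
consumed by a small C++ chain sampler), and the truth tables emitted with
each community are sufficient to score purity and zone recovery without
reaching into generator internals.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open in every exported table; `GRanges`
  objects internally follow the Bioconductor 1-based convention.
* Trailing partial windows are discarded (fixed-size vectors keep all
  fragments on equal footing); windows below 50% non-N content are dropped
  by default (`minValidFraction`, configurable — both choices cover cases
  the published procedure leaves unstated).
* Fragments with zero valid k-mer windows are excluded from composition
  matrices with a message; sequences shorter than k are flagged, not
  errors.
* A zero-variance matrix fails lattice initialization ("degenerate
  matrix"); a zero second principal component clamps J to `minJ` with a
  warning.
* BMU ties and equal-frequency heatmaps are resolved by fixed documented
  rules (smallest linear index; bin 10) so no output depends on floating
  tie luck.

## Limitations

* The SOM neighborhood schedule is a documented substitute for the
  original batch-SOM implementation's (unpublished) schedule; maps are
  qualitatively, not numerically, comparable to published figures.
* The special-zone flagger trades recall for reproducibility; small zones
  whose boundary does not reach the U-matrix quantile are missed.
* The package does not download or manage reference assemblies; real
  multi-Gb analyses are possible (`readGenomeFasta` + `runPipeline`) but
  memory- and time-bound by `Biostrings` string handling on a single
  machine.
* De-novo motif discovery in flagged zones and 3D-contact (Hi-C) analysis
  are out of scope; motif sets for `motifTrack()` are user-supplied.
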