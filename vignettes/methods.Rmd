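---
title: "Methods: from ASV table to isolation-by-distance models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ASV table to isolation-by-distance models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednadivide)
```

## Overview

`ednadivide` takes a denoised eDNA metabarcoding ASV table for riverine
fish sampled across drainage basins on both sides of a main drainage
divide (MDD) and derives (i) interspecific community patterns, (ii)
intraspecific genetic dissimilarity between basins, and (iii) tests of
isolation by distance (IBD) along landscape-aware geographic distances.
Because real sequencing data live on external archives, the package ships
a synthetic generator whose ground truth makes the full chain testable;
this vignette explains the model behind every stage, the defaults and why
they were chosen, and what passing tests do and do not demonstrate.

## Quality filtering

The filter chain runs in a fixed order; each step is a pure function of
the previous step's output, which makes the chain idempotent.

1. **Taxonomic retention.** Only records assigned to class
   Actinopterygii are kept, and the nine marine families
   (`marine_families`: Clupeidae, Mugilidae, Sparidae, Moronidae,
   Engraulidae, Scombridae, Xiphiidae, Carangidae, Istiophoridae) are
   excluded by case-insensitive exact match on the family rank. Records
   with unknown class pass through with a logged warning rather than a
   silent drop, so classifier gaps are visible.
2. **Contamination subtraction.** For each ASV, the total read count
   observed across negative controls is subtracted from that ASV's count
   in every other sample — per ASV, not globally. Negative results clip
   to zero: counts are physical quantities, and a control observation
   larger than a sample count means "remove", not "owe". When several
   controls exist their counts are summed, the most conservative reading;
   subtraction precedes the thresholds below because occurrence counts
   change once contamination is removed.
3. **Occurrence and read thresholds.** ASVs detected in fewer than 2
   samples or with fewer than 10 reads overall are dropped. Both defaults
   are the standard low-frequency-noise compromise for metabarcoding in
   the absence of positive controls; both are configurable.
4. **Stop-codon (NUMT) screen.** Nuclear copies of mitochondrial genes
   accumulate frame-breaking mutations; an in-frame stop codon under the
   vertebrate mitochondrial code (stops TAA, TAG, AGA, AGG; TGA = Trp,
   ATA = Met) is the diagnostic. Two framing modes exist. `fixed-trim-15`
   removes the first 15 bases (the primer-proximal overhang of the
   amplicon) and translates the rest, truncating a trailing partial
   codon. `alignment-frame` recovers the codon phase from a global
   alignment to an in-frame reference CDS and generalises the fixed trim
   to amplicons with variable starts; it requires the reference to be
   homologous to the query, so the synthetic pipeline — whose species
   have independent random ancestral sequences that share only the frame
   convention — defaults to `fixed-trim-15`. Codons containing ambiguity
   codes are left untranslated and never count as stops; sequences
   shorter than 18 bases are unscreenable and treated as removed, with a
   report entry. The screen is verified in the tests against an
   independent translation oracle (Biostrings, table SGC1).
5. **Basin pooling.** Presence/absence per basin: an ASV is present
   where any sample of the basin has a nonzero count. Read counts do not
   propagate past this point — every downstream statistic is
   occurrence-based, because metabarcoding read abundances confound
   biomass, amplification efficiency and transport.

## Intraspecific analyses

Species qualify when their species-level ASVs occur in at least two
basins (the minimum for a between-basin comparison). Each species' ASVs
are aligned progressively: pairwise mismatch distances feed a
neighbour-joining guide tree, and profiles are merged with an affine-gap
aligner (match +1, mismatch −1, gap open −5, gap extend −1, implemented
in C++). With these scores, equal-length inputs differing only by
substitutions provably return the gap-free identity alignment, which is
the regime ASVs from one amplicon live in; the gap machinery only engages
for ragged external sequences. Pairwise genetic distance is the count of
aligned columns where both rows carry unambiguous bases and differ
(pairwise deletion), reported both raw and as a proportion of comparable
sites — raw mismatch counts are what the screen-level figures use, while
proportions normalise ragged overlaps.

**betaMPD** between two basins is the mean of the genetic distances over
all cross pairs of ASVs, one from each basin, with presence/absence
weighting. It is symmetric and zero on the diagonal by construction; two
basins sharing exactly one identical haplotype score 0. The
whole-community betaMPD runs over the union of all species' ASVs. Genetic
distances are undefined across species, and the choice of how to score
cross-species pairs is genuinely open; the default assigns them a capped
distance equal to the global maximum observed intraspecific distance,
which bounds their influence and keeps every basin pair defined, while
`cross_species = "exclude"` averages only within-species pairs. The cap
is the default because excluding cross-species pairs can leave basin
pairs with no defined pairs at all.

**Haplotype networks** collapse identical (optionally overlap-trimmed)
sequences into haplotypes with frequencies and side composition, then
build a minimum spanning tree over pairwise mismatch counts (infinite
sites: each mismatch is one mutational step). Kruskal's algorithm with
lexicographic tie-breaking makes the network reproducible; non-tree edges
whose weight equals the bottleneck (maximum) edge weight on the tree path
between their endpoints are recorded as cost-equal alternative
configurations. When external reference haplotypes are supplied the
alignment is trimmed to fully overlapping columns first, mirroring the
practice of trimming ASVs to the overlap with published fragments.

## Landscape distances

Three between-basin distance schemes:

* **Euclidean**: haversine on basin centroids, mean Earth radius
  6371.0088 km.
* **River-following least-cost path**: conductance 50 000 for water,
  0.0001 for land (a near-impenetrable barrier), 150 for marine water.
* **Elevation-weighted least-cost path**: five conductance bands,
  [0, 100) m → 10^6, [100, 500) → 10^5, [500, 1500) → 1000,
  [1500, 2000) → 100, ≥ 2000 m → 0.001.

Cost between adjacent cells (8-neighbour connectivity) is the
centre-to-centre distance divided by the mean of the two conductances,
diagonals scaled by √2; basin-to-basin cost is the all-pairs Dijkstra
shortest path (via `igraph`). On a uniform raster the 8-neighbour
discretisation overestimates off-axis straight-line distances by at most
about 8.2% (the worst bearing is arctan(1/2)); axis-aligned paths are
exact. Costs convert to kilometres by multiplying with a reference
conductance, so a path running entirely through reference-conductance
cells (water, in the river-following scheme) reads as its along-path
length in km. The transformation is monotone, so orderings — all that the
downstream GDMs' monotone splines consume beyond knot placement — are
preserved regardless of the anchor. The two conductance schemes are
independent rasters; a combined water-plus-elevation raster is
deliberately not the default since each scheme answers a different
question (network connectivity vs. relief barriers).

Synthetic grids are planar with a fixed `cell_size_km`; for geographic
rasters, longitudinal cell width should be scaled by cos(latitude) before
building the graph.

## Generalized dissimilarity models

Each species' betaMPD matrix is scaled by its maximum into [0, 1] (the
natural zero is kept as the floor) and regressed on one geographic
distance at a time:

d = 1 − exp(−η),  η = β₀ + Σⱼ βⱼ Iⱼ(x),  β ≥ 0.

The Iⱼ are order-2 I-splines (integrated M-splines) with knots at the
0th, 50th and 100th percentiles of the distances — piecewise quadratic,
0 at the smallest knot, 1 at the largest, non-decreasing — so any
non-negative coefficient vector yields a monotone curve bounded in
[0, 1). Fitting minimises squared error on the response scale: a
Lawson–Hanson non-negative least squares solve on the linearised link
η = −log(1 − d) provides a deterministic start, then damped Gauss–Newton
steps (each solving an NNLS subproblem, with step halving) polish the
fit. A squared-error objective was chosen over a likelihood because the
result is reported as explained variance — percent deviance explained,
100 (1 − RSS/RSS₀) with the intercept-only null — and because recovery is
then directly testable: noise-free responses from a known model are
refitted to RMSE below 1e−6, and the test suite verifies knot-wise curve
recovery under Gaussian noise (σ = 0.05) and that deviance increases
monotonically with the simulated IBD strength. A constant response
short-circuits to the null model (all βⱼ = 0, deviance 0).

## The synthetic generator

The generator emulates a coastal mountain range: a ridge column splits a
planar grid into a "ligurian" (west) and an "adriatic" (east) slope, the
DEM peaks at the ridge (2400 m default) and decreases monotonically to
sea-level margins, and each basin is a contiguous river channel from a
headwater beside the ridge to its own sea. Defaults: 40 × 60 cells of
1 km, 5 basins per side, 2 samples per basin, 2 negative controls.

Haplotypes evolve by stepping stones: basins chain alongshore per side,
one cross-divide edge links the first opposite pair (emulating faunal
exchange across the low western end of a divide), and each edge applies
Poisson(λ) substitutions (λ = 2 default) to a 420 bp ancestral cytb-like
sequence — 15 bp overhang plus sense codons. Substitutions that would
create an in-frame stop are resampled, a minimal model of purifying
selection on a protein-coding marker; without it, true haplotypes would
occasionally be flagged by the NUMT screen, which real purifying
selection prevents. The unconstrained mode remains available and is what
the Poisson-expectation tests exercise. Six species ship by default: four
occupying all basins, one restricted to one side, and one single-basin
species that the two-basin coverage rule must exclude.

Read counts are 1 + negative binomial (mean 5000, dispersion 2) per
occupied sample — overdispersed like real metabarcoding counts, with the
+1 guaranteeing that every true ASV meets the two-sample occurrence rule
by construction (each basin has at least two samples); the exact values
are irrelevant downstream because analyses are occurrence-based. Planted
artefacts, disjoint by construction: NUMTs (copies of true haplotypes
with ~2% substitutions plus a stop codon at an in-frame position from
codon 10 on, at moderate read depth), single-sample noise, low-read noise
(< 10 reads across ≥ 2 samples), contaminants (present in a negative
control at counts exceeding every sample count, so subtraction removes
them), and marine ASVs labelled with a family from the exclusion list.
The ground truth records every class and the expected survivor count;
filters must recover it exactly, with zero false survivals and zero false
removals, across seeds.

What the generator does **not** emulate: PCR chimeras, tag jumping,
sequencing error beyond the denoiser, within-basin haplotype diversity
per species (one lineage per basin), reticulate gene flow, and real
hydrology. Passing tests therefore demonstrate the correctness of the
analysis chain and the qualitative reproducibility of divide-side
structure and IBD under a known model — not the field performance of any
particular filtering threshold.

## Numerical choices and degenerate inputs

* Permutation tests: 999 permutations, `p = (1 + k)/(1 + N)`; the
  observed labelling is never counted as a draw. ANOSIM uses midranks for
  ties. Mantel is one-sided (greater). Both match the conventional
  defaults of the widely used implementations and are cross-checked
  against `vegan` in the tests. With very few exchangeable units a
  permutation test is conservative because few distinct label splits
  exist (35 for 4+4); the calibration tests use 6+6 groups, where the
  empirical size at α = 0.05 sits inside [0.03, 0.07].
* PCoA drops negative-eigenvalue axes (magnitudes are retained on the
  result for inspection) rather than applying Lingoes/Cailliez
  corrections — the use case is visualisation; axis signs are fixed by
  making each axis's largest-magnitude loading positive.
* Jaccard for two empty basins is defined as 0 with a warning; a basin
  pair where one basin has no ASVs of a species yields a missing betaMPD
  entry, which `scale_response()` drops (at least 3 defined pairs are
  required to fit a GDM).
* All randomness derives from one seed through a per-stage splitter, so
  stage order cannot change draws and identical configurations give
  byte-identical outputs.
* Problem sizes in the test suite (grids up to 60 × 80, up to 10 basins
  per side, 30-sequence networks, 50–100 seed replicates, 1000-replicate
  calibrations) were chosen as the smallest scales at which the
  statistical properties under test are non-trivial.

## Known limitations

* The whole-community betaMPD depends on the cross-species cap; basin
  pairs dominated by cross-species co-occurrence shrink toward the cap
  value. Report per-species betaMPD alongside it.
* The cost→km transformation is one defensible anchoring of an
  unspecified convention; absolute km from different conductance schemes
  are not comparable with each other, only orderings are.
* `alignment-frame` NUMT screening assumes the reference is homologous to
  the query; with a non-homologous reference, frames are arbitrary and
  the fixed trim should be used instead.
* The GDM fitter handles one predictor per model (one distance scheme),
  matching the one-model-per-distance design; joint multi-predictor
  models are out of scope.
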