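# ednadivide

Inter- and intraspecific diversity of riverine fish from eDNA metabarcoding
ASV data.

## The problem

Environmental DNA metabarcoding of river water yields amplicon sequence
variants (ASVs): exact denoised sequences that carry information at two
levels at once — which taxa are present (interspecific diversity) and which
haplotypes of each species are present (intraspecific diversity). Turning a
raw ASV table into defensible diversity patterns requires a chain of steps
that are usually scattered across scripts: removing contamination seen in
negative controls, discarding low-occurrence and low-read noise, screening
out nuclear mitochondrial pseudogenes (NUMTs) by in-frame stop codons,
excluding marine taxa, pooling sites to drainage basins, computing
genetic-distance-weighted dissimilarity between basins, and asking whether
that dissimilarity tracks geography — isolation by distance (IBD) — along
river-aware landscape distances.

`ednadivide` packages that chain for drainage basins on the two sides of a
main drainage divide (MDD), together with a synthetic riverscape and
haplotype generator with known ground truth, so that every stage is
testable without any sequencing data.

## The statistics at its core

* **betaMPD** — between-community mean pairwise distance. For basins $b_1,
  b_2$ holding ASV sets $A_1, A_2$ of one species with genetic distance
  matrix $D$ (pairwise base-pair mismatches, pairwise deletion):

  $$\mathrm{betaMPD}(b_1,b_2) = \frac{1}{|A_1||A_2|}\sum_{i\in A_1}\sum_{j\in A_2} D_{ij}$$

  Occurrence-weighted (presence/absence), not read-weighted. A
  whole-community variant spans all species, scoring cross-species ASV
  pairs with a capped distance (the maximum observed intraspecific
  distance) or excluding them.

* **Conductance least-cost paths** — rasters assign each cell an ease of
  movement (river-following scheme: water 50 000, land 0.0001, sea 150;
  elevation scheme: five bands from 10^6 below 100 m down to 0.001 at or
  above 2000 m). Moving between 8-neighbour cells costs
  $d_{ij}/\mathrm{mean}(c_i, c_j)$; basin-to-basin cost is the Dijkstra
  shortest path, converted to km by anchoring to a reference conductance.

* **GDM with monotone I-splines** — generalized dissimilarity model
  $d = 1 - e^{-\eta}$, $\eta = \beta_0 + \sum_j \beta_j I_j(x)$ with
  $\beta \ge 0$, where $I_j$ are order-2 I-splines of the geographic
  distance $x$ (knots at the 0/50/100th percentiles). Non-negative
  coefficients force a monotone dissimilarity–distance curve; percent
  deviance explained is $100(1 - \mathrm{RSS}/\mathrm{RSS}_{null})$.

* Community statistics: Jaccard dissimilarity, principal coordinates
  analysis, ANOSIM and Mantel permutation tests (999 permutations,
  `(1+k)/(1+N)` p-values), Wilcoxon rank-sum richness comparison between
  the sides of the divide.

## Worked example

```r
library(ednadivide)

res <- run_pipeline(pipeline_config(seed = 1))

# filtering: 93 raw ASVs -> 38 survivors (planted NUMTs, noise,
# contaminants and marine taxa removed; matches the ground truth exactly)
length(res$filtered$survivors)
#> [1] 38
table(res$filtered$report$reason)
#> <2 samples or <10 reads   in-frame stop codon        marine family
#>                      30                    20                    5

# do the two sides of the divide carry distinct haplotype communities?
anosim_test(res$intraspecific$community_betampd,
            res$filtered$community$side_of_divide, seed = 4)
#> ANOSIM statistic: 0.896  p = 0.008 ( 999 permutations )

# is genetic-weighted dissimilarity congruent with ASV identity turnover?
res$mantel
#> Mantel statistic: 0.4498  p = 0.004 ( 999 permutations )

# isolation by distance, one GDM per species and distance scheme
res$gdm[["Salmo trutta"]][["euclidean"]]
#> GDM fit: 3 I-splines, deviance explained 59.78%
```

The ANOSIM shows strong side separation of the whole-community betaMPD
(R near 0.9), the Mantel test shows moderate, significant congruence
between Jaccard and betaMPD structure, and the GDM deviances quantify how
much of each species' genetic turnover the geographic distances explain.

A command-line wrapper covering simulate / filter / full runs is installed
at `inst/cli/edna-divide.R`:

```sh
Rscript inst/cli/edna-divide.R all --out run1 --seed 1
```

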