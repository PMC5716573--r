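# barcodegap

DNA-barcoding gap analysis and distance-based species delimitation for
multilocus studies of cryptic species complexes.

Cryptic species are lineages that are genetically and ecologically distinct
but morphologically indistinguishable, so they cannot be delimited by
classical taxonomy. DNA barcoding delimits them from sequence data instead:
if within-species genetic distances are well separated from between-species
distances (a "barcoding gap"), short standard loci suffice to assign samples
to species. `barcodegap` implements the full analysis chain such studies run
on per-locus alignments — typically several plastid loci (*matK*, *rbcL*,
*rpoC1*, *trnH–psbA*, *trnL–trnF*) plus the faster nuclear ITS region — for
single loci, locus combinations, and the concatenated dataset.

## What it computes

* **Distances.** Kimura 2-parameter distances
  *d* = −½ ln(1 − 2*P* − *Q*) − ¼ ln(1 − 2*Q*), with *P* and *Q* the
  transition and transversion proportions over pairwise-usable sites, plus
  uncorrected *p*-distances and JC69 (*d* = −¾ ln(1 − 4*p*/3)); pairwise or
  complete deletion of gap/ambiguity sites; within/between-group mean
  divergence tables.
* **Barcoding-gap statistics.** Intra- vs interspecific pair partitioning;
  means, medians and 5/10/90/95th percentiles; the three overlap measures
  (max intra − min inter; P90 intra − P10 inter; P95 intra − P5 inter,
  truncated at zero); inter/intra fold ratios and Hebert's 10-fold rule;
  Mann–Whitney U tests; the classical gap flag (max intra < min inter).
* **ABGD-style delimitation.** A geometric scan of prior intraspecific
  divergences; for each prior, the barcode gap is located in the ranked
  pairwise distances (first gap wider than X times the local gap scale,
  X = 1.5 by default), samples are grouped by single linkage below the gap
  (initial partition), and the search is re-applied within groups until
  nothing splits (recursive partition).
* **Distance trees.** Neighbor-joining and UPGMA via `ape`, nonparametric
  bootstrap supports, 75% majority-rule consensus, Newick I/O, and a
  per-species monophyly check.
* **Haplotype networks.** Haplotype collapsing, median-joining networks
  (minimum spanning network plus cost-reducing median vectors), MP-style
  pruning of redundant medians/links, mutation-step separations between
  species clusters, GraphML/TSV export.
* **Recombination.** The pairwise homoplasy index (PHI): mean normalized
  incompatibility of nearby informative site pairs with a site-permutation
  null (low observed Φw ⇒ recombination).
* **Synthetic data.** A seeded K2P-process simulator that plants a known
  cryptic-species structure (two deep clades, species, within-species
  lineages, plastid + faster nuclear loci), so the whole pipeline is
  testable end to end with known truth.

## Worked example

Simulate a five-species study (8 samples/species, within-species divergence
0.2%, between-species 4%), then ask whether the combined plastid loci show a
barcoding gap and whether ABGD recovers the species:

```r
library(barcodegap)

sim    <- simulate_barcode_data(synth_config(), seed = 42)
truth  <- setNames(sim$truth$species, sim$truth$sample_id)
plastid <- sim$config$loci$locus[sim$config$loci$class == "plastid"]
cp  <- mask_columns(concatenate_loci(sim$alignments[plastid]))
dm  <- distance_matrix(cp, model = "K2P")

gap_summary(dm, truth, locus = "combined_cp")
#>   locus       n_intra n_inter intra_mean inter_mean overlap1 fold_mean  p_value gap_present
#> 1 combined_cp     140     640      0.313       6.58        0      21.0 7.83e-77 TRUE
```

Read: 140 within-species and 640 between-species pairs; mean distances 0.31%
vs 6.6% (percent scale, as such tables are printed), a 21-fold difference
(10-fold rule met), zero overlap between the distance ranges — a classical
barcoding gap — and a vanishing Mann–Whitney p-value.

```r
res <- abgd(dm, abgd_config())      # Pmin = 0.001, Pmax = 0.1, X = 1.5
glance(res)
#>      prior threshold n_initial n_recursive
#>  1 0.001    0.000978        32          32
#>  2 0.00167  0.00154         17          17
#>  3 0.00278  0.00266          8           8
#>  4 0.00464  0.00491          7           7
#>  5 0.00774  0.00772          5           5
#>  6 0.0129   0.0209           5           5
#>  7 0.0215   0.0209           5           5
#>  8 0.0359   0.0371           4           4
#>  9 0.0599   0.0617           2           2
#> 10 0.1     NA                1           1

barcode_discrimination(truth, abgd_partition(res, prior = 0.013))$pct_resolved
#> [1] 100
```

At very small priors ABGD splits within-species variation; across the
plausible prior range it returns exactly the five planted species (100%
discriminant power); at large priors groups merge. `autoplot(res)` draws the
group-count-vs-prior scan, and `run_pipeline()` executes the same analysis —
plus trees, networks and the PHI test — for every locus and combination of a
study directory, writing TSV/Newick/GraphML reports and a YAML manifest.

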