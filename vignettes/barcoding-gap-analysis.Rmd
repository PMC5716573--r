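---
title: "Barcoding-gap analysis and distance-based species delimitation with barcodegap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcoding-gap analysis and distance-based species delimitation with barcodegap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The problem

A cryptic species complex is a set of reproductively isolated lineages that
share one morphology. Multilocus DNA barcoding delimits such lineages from
sequence data: per-locus alignments of many samples are reduced to pairwise
genetic distances, and species boundaries are read off the structure of
those distances. The analysis stands on one empirical claim — that
within-species distances and between-species distances occupy separable
ranges (the *barcoding gap*) — and `barcodegap` provides the statistics that
test that claim, the delimitation method that exploits it, and supporting
analyses (distance trees, haplotype networks, a recombination test).

This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic validation data can and cannot show.

## Distances

Sequences are compared only at sites where both carry an unambiguous base
(`A/C/G/T`). Three distances are offered, all as proportions internally and
multiplied by 100 exactly once in report writers:

* **K2P** (the field's convention for barcoding comparisons):
  $d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$ with $P$ the transition
  (A↔G, C↔T) and $Q$ the transversion proportion.
* **uncorrected p**: the mismatch proportion.
* **JC69**: $d = -\tfrac34\ln(1-\tfrac43 p)$.

Two deletion policies exist because studies rarely state which their
distance software used. `mask_columns()` implements *complete deletion*
(drop any column with a gap or ambiguity in any sequence) and is the default
ahead of site classification, haplotype collapsing and concatenation, where
column identity must be shared by all samples. `distance_matrix()` defaults
to *pairwise deletion*, which keeps per-pair information when individual
samples have missing stretches; `deletion = "complete"` restores the
stricter behaviour. A saturated pair (non-positive logarithm argument) is an
error by default: at the divergences this kind of study involves (well below
20%), saturation indicates corrupted input, and silently capping it would
hide that. `on_saturation = "drop"` downgrades it to a warning and an `NA`
entry for exploratory work.

## Barcoding-gap statistics

`partition_pairs()` splits all $\binom{n}{2}$ distances into intraspecific
and interspecific sets under a species hypothesis; taxa represented by a
single sample can be excluded (they contribute no intraspecific pairs and
would distort the interspecific minimum). `gap_summary()` then reports, per
locus and on the percent scale: pair counts; mean, median, min, max and the
5/10/90/95th percentiles of each set; three overlap measures

* Overlap¹ = max intra − min inter,
* Overlap² = P90 intra − P10 inter,
* Overlap³ = P95 intra − P5 inter,

each truncated at zero for display (the signed values are kept as
diagnostics); the inter/intra fold ratios of means and medians with the
10-fold rule (`fold_mean > 10`); a Mann–Whitney U test; and the classical
gap flag, true iff Overlap¹ = 0.

Numerical choices: percentiles use linear interpolation between closest
ranks (R's type 7) — sources are typically silent on the definition, so it
is recorded in the run manifest; fold ratios are rounded to one decimal only
for display, never in comparisons; the U test treats distance pairs as
independent observations, replicating standard practice in this literature —
a known pseudo-replication caveat, since the $\binom{n}{2}$ pairs share the
$n$ underlying samples, so the p-values overstate certainty and should be
read qualitatively.

## ABGD-style delimitation

`abgd()` re-implements the Automatic Barcode Gap Discovery idea: for each
prior intraspecific divergence $P$ in a geometric series from `p_min` to
`p_max` (defaults 0.001–0.1, 10 steps), find the barcode gap in the ranked
pairwise distances, cut there, and recurse.

The published descriptions of the original tool do not fully specify its
gap-significance rule, so this package defines its own and treats it as the
contract: consecutive gaps $g_i = d_{(i+1)} - d_{(i)}$ of the sorted
distances are scanned in ascending order; distances strictly below the prior
are treated as guaranteed-intraspecific, so a gap is a candidate only when
its upper end is at least the prior; a candidate qualifies when
$g_i > X \cdot \bar g_{\text{local}}$, where $\bar g_{\text{local}}$ is the
mean of the up-to-$W$ immediately preceding gaps
($W = \max(10, \lceil 0.05\,n\rceil)$, zero-width gaps from tied distances
included) and $X$ is the relative gap width (default 1.5, overridable per
locus, e.g. 1.2 for a weakly variable locus). The first qualifying gap is
the barcode gap; its midpoint is the threshold for single-linkage grouping
(components of the graph joining pairs at distance ≤ threshold). The
recursive partition re-applies the same search within each group, on the
group-restricted distances, until nothing splits; it therefore always
refines the initial partition.

Two consequences are worth stating plainly. First, scanning from below
splits shallow substructure before deep structure: with 0.8% within-species
lineages and a 4% species gap, priors below the lineage divergence delimit
lineages in the *initial* partition, priors above it delimit species. That
matches how the original tool behaves on substructured real data and is why
delimitation results are always read across the whole prior scan, not at one
prior. A "widest gap wins" alternative was considered and rejected: when a
dataset also contains a still deeper split (two major clades), the deepest
gap can outweigh the species gap and collapse the partition to the clades.
Second, with $X = 1.5$, locally large spacings in a quasi-continuous
distance tail can qualify as gaps, so group counts at priors inside the
noise floor overestimate structure — also visible in the original method,
and the reason the prior exists at all.

Invariants the tests enforce: initial group counts are weakly decreasing in
the prior; the recursive partition refines the initial one; partitions are
invariant to sample order; and planted two-level structure is recovered at
the predicted priors.

## Trees and networks

Neighbor joining and UPGMA run on any distance matrix via `ape` (`nj_tree()`
clamps the occasional negative NJ branch length to zero rather than
redistributing it; ties in agglomeration are resolved by `ape`'s stable
ordering, so trees are deterministic). `bootstrap_support()` resamples
alignment columns with replacement — globally across a concatenated
alignment by default, since per-locus resampling conventions vary;
`stratify = TRUE` resamples within each locus block instead — rebuilds the
tree, and
counts bipartitions on the original topology; replicates whose resampled
distances saturate are dropped with a warning and excluded from the
denominator. `majority_consensus()` collapses bipartitions below the chosen
frequency (default 75%). `species_monophyly()` checks, per species, whether
some edge bipartition isolates exactly its samples — the unrooted notion of
monophyly, so no outgroup is needed.

`median_joining()` builds haplotype networks: collapse identical sequences
(`collapse_haplotypes()`, numbering by first occurrence), then alternate
between the minimum spanning network within tolerance ε (default 0, the
usual practice) and adding median vectors. Candidate medians come from
connected triples (a node and two of its neighbours); the median is the
column-wise majority sequence, and a triple whose columns ever show three
distinct states yields none — the quasi-median expansion of the original
algorithm is deliberately not implemented, which is the chief divergence
risk against the reference tool and the reason exact median-vector counts on
real data are not a contract here. A candidate is accepted only if it
strictly lowers the minimum-spanning cost, and the cheapest-improving one is
added per round, so the iteration terminates (integer costs, strictly
decreasing). `mp_prune()` afterwards removes median vectors and links lying
on no minimal-cost path between observed haplotypes; shortest-path lengths
between observed haplotypes are provably unchanged, and pruning is
idempotent. Indel columns are excluded upstream by masking, so edge weights
count substitution steps only. `cluster_separation()` reports the minimum
mutation-step path between species clusters.

## The PHI recombination test

For parsimony-informative sites, the refined incompatibility of a site pair
is the cycle rank (edges − vertices + components) of the bipartite graph of
jointly observed states — 0 exactly when the two sites fit one tree, and
otherwise the minimum number of extra mutations any tree needs. Each pair
score is normalized by its maximum $(a-1)(b-1)$ for the observed state
counts $a, b$. The statistic $\Phi_w$ is the mean over informative-site
pairs at most $w$ alignment columns apart (default $w = 100$).

Under clonal evolution incompatibility is unrelated to distance between
sites; recombination makes nearby sites *more* compatible than distant
ones. The permutation null shuffles which informative-site pattern occupies
which informative column, preserving per-site patterns while destroying
spatial structure, and the one-sided tail is
$p = (1 + \#\{\Phi_{\text{perm}} \le \Phi_{\text{obs}}\})/(1 + n_{\text{perm}})$:
a LOW observed $\Phi_w$ signals recombination. The sign convention is easy
to get backwards, hence stated here prominently. The analytic normal
approximation of the original method is not implemented; the permutation
test is assumption-free and its resolution $1/(n_{\text{perm}}+1)$ is ample
at the default 1000 permutations. Calibration is tested by simulation:
across 100 clonal alignments the rejection rate at α = 0.05 stays within
[0, 0.10], and spliced two-genealogy alignments are detected in well over
80% of runs.

## The synthetic data generator

`simulate_barcode_data()` emulates the design of a multilocus cryptic-species
study so every stage can be validated against known truth without any
external data. The genealogy is a fixed balanced hierarchy — two deep
clades, species within clades, optionally lineages within species, star-like
sampling within lineages — with node heights set to half the target pairwise
divergences, and sequences evolve along it under the exact K2P transition
probabilities (transition/transversion rate ratio κ, default 2). Defaults
represent a realistic multilocus design for a cryptic liverwort complex:
K = 5 species, 8
samples/species, within-lineage divergence 0.2%, lineage divergence 0.8%
(two lineages in each of the first two species), between-species 4%,
between-clade 8%; five "plastid" loci of realistic barcoding lengths at the
base rate sharing the genealogy, plus one "nuclear" locus at 2.5× the rate —
the observed ratio between ITS and plastid variability in such studies. All
draws are governed by one seed; outputs are byte-identical across runs.

Deliberate simplifications, and what they mean for the tests: there is no
coalescent (no incomplete lineage sorting, no gene-tree discordance), no
rate heterogeneity across sites, no indels (the pipeline masks them anyway),
and no recombination (PHI power tests splice alignments explicitly instead).
Passing the end-to-end tests therefore shows the machinery is correct under
its own model assumptions — clean clock-like divergence with a true gap —
not that real data, with chained intermediate haplotypes and missing loci,
will delimit as cleanly. `make_planted_matrix()` is the further-reduced fast
path: distances drawn directly from disjoint uniform ranges, symmetrized,
triangle inequality *not* enforced (single linkage does not require it).

## Problem sizes and reproducibility

The test-suite and acceptance runs use study-scale but economical sizes
chosen as the package's own validation design: 40-sample simulated datasets
(~3.9 kb over six loci), 100-seed replication for the planted-delimitation
and network-pruning properties, 100 + 50 simulations for PHI calibration and
power, and bootstraps of 10–50 replicates in smoke tests (1000 is the
reporting convention on real studies). Every stochastic step — simulation,
bootstrap, permutation — takes an explicit seed, and `run_pipeline()` writes
all of them into its YAML manifest together with package versions, inputs
and the percentile definition.

## Known limitations

* Real-data replication of published delimitation results requires the
  original GenBank-deposited sequences, which ship as supplementary
  accession lists rather than with this package; published group counts,
  haplotype numbers and minimum divergences on such material are therefore
  not asserted by the test suite.
* The ABGD gap rule is this package's own precise formalization of a method
  whose reference implementation differs in unpublished details; agreement
  is by behaviour (planted-gap recovery, prior-scan shape), not bit-for-bit
  group counts.
* Median-joining omits quasi-medians (above) and, with ε = 0, can depend on
  tie-breaking among equal-cost medians; exact mutation-step counts between
  real clusters should be read as approximations.
* The Mann–Whitney p-values inherit the field's pairwise pseudo-replication
  (above).
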