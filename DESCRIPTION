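Package: barcodegap
Title: DNA Barcoding Gap Analysis and Distance-Based Species Delimitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multilocus DNA-barcoding studies of cryptic species
    complexes: Kimura 2-parameter, Jukes-Cantor and uncorrected p-distances
    with pairwise or complete deletion; intra- versus interspecific
    barcoding-gap statistics (overlap measures, fold ratios, Mann-Whitney
    tests); Automatic Barcode Gap Discovery (ABGD) style delimitation with
    initial and recursive partitions; neighbor-joining and UPGMA distance
    trees with bootstrap support; median-joining haplotype networks with
    maximum-parsimony pruning; a pairwise homoplasy index (PHI) permutation
    test for recombination; and a seeded simulator of multilocus alignments
    with planted cryptic-species structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
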