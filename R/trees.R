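# Distance trees: neighbor joining, UPGMA, nonparametric bootstrap support
# and majority-rule consensus. Tree algebra is delegated to ape; this module
# fixes the conventions (clamped NJ branch lengths, percent supports,
# deterministic resampling).

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration via [ape::nj()]; negative branch lengths (a
#' known NJ artifact on noisy matrices) are clamped to zero.
#'
#' @param dm A `genetic_dist` with no undefined entries.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (anyNA(dm$d)) stop("distance matrix has undefined entries", call. = FALSE)
  n <- length(dm$sample_ids)
  if (n < 2L) stop("need at least two samples", call. = FALSE)
  if (n == 2L) {
    d <- dm$d[1L, 2L]
    tr <- ape::read.tree(text = sprintf("(%s:%.10f,%s:%.10f);",
                                        dm$sample_ids[1L], d / 2,
                                        dm$sample_ids[2L], d / 2))
    return(tr)
  }
  tr <- ape::nj(as.dist(dm$d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; the result is rooted and ultrametric, with
#' the path between two leaves equal to their cophenetic (average-linkage)
#' distance.
#'
#' @inheritParams nj_tree
#' @return A rooted ultrametric `phylo` tree.
#' @export
upgma_tree <- function(dm) {
  if (anyNA(dm$d)) stop("distance matrix has undefined entries", call. = FALSE)
  hc <- stats::hclust(as.dist(dm$d), method = "average")
  ape::as.phylo(hc)
}

#' Bootstrap support for a distance tree
#'
#' Alignment columns are resampled with replacement `B` times, the distance
#' matrix and tree rebuilt, and bipartition frequencies counted on the
#' original tree. Replicates whose distances saturate are dropped with a
#' warning and excluded from the denominator.
#'
#' @param aln A `dna_alignment`.
#' @param model Distance model passed to [distance_matrix()].
#' @param builder `"nj"` or `"upgma"`.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed; resampling is fully reproducible for fixed seed.
#' @param deletion Deletion policy passed to [distance_matrix()].
#' @param stratify When `TRUE` and the alignment carries a `locus_map`
#'   attribute (see [concatenate_loci()]), columns are resampled within each
#'   locus block instead of globally across the concatenation.
#' @param keep_trees When `TRUE` the replicate trees are attached as
#'   attribute `replicates` (for consensus building).
#' @return The original tree (`phylo`) with percent supports as
#'   `node.label`, plus attributes `n_replicates` (used) and `n_dropped`.
#' @export
bootstrap_support <- function(aln, model = "K2P", builder = c("nj", "upgma"),
                              B = 100, seed = 1, deletion = "pairwise",
                              stratify = FALSE, keep_trees = FALSE) {
  builder <- match.arg(builder)
  stopifnot(B >= 1)
  build <- if (builder == "nj") nj_tree else upgma_tree
  original <- build(distance_matrix(aln, model = model, deletion = deletion))
  lmap <- attr(aln, "locus_map")
  if (stratify && is.null(lmap)) {
    stop("stratified resampling needs a locus_map attribute", call. = FALSE)
  }
  draw_cols <- if (stratify) {
    function() unlist(lapply(seq_len(nrow(lmap)), function(k) {
      idx <- lmap$start[k]:lmap$end[k]
      sample(idx, length(idx), replace = TRUE)
    }))
  } else {
    function() sample.int(ncol(aln), ncol(aln), replace = TRUE)
  }
  set.seed(seed)
  boots <- vector("list", B)
  dropped <- 0L
  for (b in seq_len(B)) {
    cols <- draw_cols()
    rep_aln <- new_alignment(unclass(aln)[, cols, drop = FALSE],
                             locus_name(aln))
    tr <- tryCatch(
      build(distance_matrix(rep_aln, model = model, deletion = deletion)),
      error = function(e) NULL
    )
    if (is.null(tr)) dropped <- dropped + 1L else boots[[b]] <- tr
  }
  boots <- boots[!vapply(boots, is.null, logical(1))]
  if (dropped > 0L) {
    warning(dropped, " bootstrap replicate(s) dropped (saturated distances)",
            call. = FALSE)
  }
  if (length(boots) == 0L) stop("all bootstrap replicates failed", call. = FALSE)
  counts <- ape::prop.clades(original, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  original$node.label <- round(100 * counts / length(boots), 1)
  attr(original, "n_replicates") <- length(boots)
  attr(original, "n_dropped") <- dropped
  if (keep_trees) attr(original, "replicates") <- boots
  original
}

#' Majority-rule consensus of trees
#'
#' @param trees A list (or `multiPhylo`) of trees over the same leaves.
#' @param threshold Minimum bipartition frequency to retain (default 0.75,
#'   the 75% majority rule).
#' @return A `phylo` consensus tree with percent frequencies as node labels.
#' @export
majority_consensus <- function(trees, threshold = 0.75) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 1L) {
    tr <- trees[[1L]]
    tr$node.label <- rep(100, tr$Nnode)
    return(tr)
  }
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = threshold)
  if (!is.null(cons$node.label)) {
    cons$node.label <- round(100 * as.numeric(cons$node.label), 1)
  }
  cons
}

#' Does each group form a clade?
#'
#' A group is monophyletic on an unrooted tree when some edge bipartition
#' separates exactly that group from the rest (checked against the clade set
#' of the tree and its complements).
#'
#' @param tree A `phylo` tree.
#' @param partition Named character vector `sample_id -> group` or data frame
#'   with `sample_id` plus a grouping column.
#' @param group Grouping column name when `partition` is a data frame.
#' @return Tibble: `group`, `n_tips`, `monophyletic`.
#' @export
species_monophyly <- function(tree, partition, group = "species") {
  part <- as_partition(partition, group)
  tips <- tree$tip.label
  clades <- ape::prop.part(tree)
  clade_sets <- lapply(clades, function(idx) sort(tips[idx]))
  all_tips <- sort(tips)
  groups <- sort(unique(part[tips]))
  is_clade <- function(members) {
    members <- sort(members)
    if (length(members) <= 1L || length(members) == length(tips)) return(TRUE)
    comp <- sort(setdiff(all_tips, members))
    any(vapply(clade_sets, identical, logical(1), y = members)) ||
      any(vapply(clade_sets, identical, logical(1), y = comp))
  }
  tibble::tibble(
    group = groups,
    n_tips = vapply(groups, function(g) sum(part[tips] == g), integer(1)),
    monophyletic = vapply(groups, function(g) is_clade(tips[part[tips] == g]),
                          logical(1))
  )
}

#' Newick input/output
#'
#' @param tree A `phylo` tree.
#' @param path File path.
#' @return `read_newick()` a `phylo`; `write_newick()` the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
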