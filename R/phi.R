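# Pairwise homoplasy index (PHI) test for recombination.
#
# The statistic is the mean refined incompatibility of nearby pairs of
# parsimony-informative sites, each pair's score normalized by its maximum
# for the observed state counts. Under clonal (tree-like) evolution,
# incompatibility is unrelated to the distance between sites; recombination
# makes nearby sites more compatible than distant ones, so a LOW observed
# statistic relative to a site-permutation null indicates recombination.

ACGT <- c("A", "C", "G", "T")

# Indices of parsimony-informative columns (>=2 states each carried by >=2
# unambiguous rows).
informative_sites <- function(aln) {
  which(apply(unclass(aln), 2L, function(col) {
    tab <- table(col[col %in% ACGT])
    sum(tab >= 2L) >= 2L
  }))
}

#' Refined incompatibility of a site pair
#'
#' Cycle rank (edges − vertices + components) of the bipartite graph whose
#' vertex classes are the states observed at each site and whose edges are
#' the joint states observed across sequences; 0 iff the two sites are
#' compatible with a single tree, and otherwise the minimum number of extra
#' mutations any tree must invoke. The classical four-gamete violation of two
#' binary sites scores 1.
#'
#' @param site_i,site_j Character vectors of states (one element per
#'   sequence); rows where either state is not an unambiguous base are
#'   ignored.
#' @return Integer incompatibility score.
#' @export
pair_incompatibility <- function(site_i, site_j) {
  use <- site_i %in% ACGT & site_j %in% ACGT
  a <- site_i[use]; b <- site_j[use]
  joint <- unique(paste(a, b))
  sa <- unique(a); sb <- unique(b)
  if (length(sa) < 2L || length(sb) < 2L) return(0L)
  nv <- length(sa) + length(sb)
  # union-find over the vertices of the bipartite state graph
  parent <- seq_len(nv)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edges <- strsplit(joint, " ", fixed = TRUE)
  for (e in edges) {
    u <- match(e[1L], sa)
    v <- length(sa) + match(e[2L], sb)
    ru <- find(u); rv <- find(v)
    if (ru != rv) parent[ru] <- rv
  }
  comps <- length(unique(vapply(seq_len(nv), find, integer(1))))
  as.integer(length(joint) - nv + comps)
}

# Normalized m x m score matrix over informative sites plus their column
# positions. Entry = cycle rank / ((a-1)(b-1)); NA when undefined.
phi_score_matrix <- function(aln) {
  pos <- informative_sites(aln)
  m <- length(pos)
  cols <- lapply(pos, function(j) unclass(aln)[, j])
  S <- matrix(NA_real_, m, m)
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
      ci <- cols[[i]]; cj <- cols[[j]]
      use <- ci %in% ACGT & cj %in% ACGT
      a <- length(unique(ci[use])); b <- length(unique(cj[use]))
      mx <- (a - 1L) * (b - 1L)
      if (mx < 1L) next
      S[i, j] <- S[j, i] <- pair_incompatibility(ci, cj) / mx
    }
  }
  list(positions = pos, scores = S)
}

# Mean score over pairs of informative-site positions at most w columns
# apart, given a permutation of which site pattern sits at which position.
phi_mean <- function(scores, pair_idx, perm) {
  vals <- scores[cbind(perm[pair_idx[, 1L]], perm[pair_idx[, 2L]])]
  mean(vals, na.rm = TRUE)
}

#' PHI statistic
#'
#' Mean normalized incompatibility over pairs of parsimony-informative sites
#' whose alignment columns are at most `w` apart.
#'
#' @param aln A `dna_alignment` with at least 3 informative sites.
#' @param w Window width in alignment columns (default 100).
#' @return The statistic (non-negative scalar).
#' @export
phi_statistic <- function(aln, w = 100) {
  sm <- phi_score_matrix(aln)
  if (length(sm$positions) < 3L) {
    stop("PHI needs at least 3 parsimony-informative sites (got ",
         length(sm$positions), ")", call. = FALSE)
  }
  pair_idx <- which(outer(sm$positions, sm$positions,
                          function(x, y) abs(x - y) <= w) &
                      upper.tri(sm$scores), arr.ind = TRUE)
  if (nrow(pair_idx) == 0L) stop("no informative-site pair within the window",
                                 call. = FALSE)
  phi_mean(sm$scores, pair_idx, seq_along(sm$positions))
}

#' PHI permutation test for recombination
#'
#' The null distribution permutes which informative-site pattern occupies
#' which informative column, destroying any spatial clustering of
#' incompatibility while preserving every per-site pattern. Following the
#' PHI convention, the one-sided tail is the fraction of permutations with a
#' statistic at most the observed one: a LOW observed mean incompatibility of
#' nearby sites (relative to the shuffled null) is the signature of
#' recombination, so small p rejects clonality.
#'
#' @inheritParams phi_statistic
#' @param n_perm Number of permutations; p has resolution `1/(n_perm + 1)`.
#' @param seed Integer seed (test is deterministic for fixed seed).
#' @return A `phi_result`: one-row tibble with `phi`, `w`, `n_informative`,
#'   `n_perm`, `seed`, `p_value`.
#' @export
phi_test <- function(aln, w = 100, n_perm = 1000, seed = 1) {
  sm <- phi_score_matrix(aln)
  m <- length(sm$positions)
  if (m < 3L) {
    stop("PHI needs at least 3 parsimony-informative sites (got ", m, ")",
         call. = FALSE)
  }
  pair_idx <- which(outer(sm$positions, sm$positions,
                          function(x, y) abs(x - y) <= w) &
                      upper.tri(sm$scores), arr.ind = TRUE)
  if (nrow(pair_idx) == 0L) stop("no informative-site pair within the window",
                                 call. = FALSE)
  obs <- phi_mean(sm$scores, pair_idx, seq_len(m))
  set.seed(seed)
  perm_stats <- vapply(seq_len(n_perm), function(k) {
    phi_mean(sm$scores, pair_idx, sample.int(m))
  }, numeric(1))
  p <- (1 + sum(perm_stats <= obs + 1e-12)) / (1 + n_perm)
  out <- tibble::tibble(phi = obs, w = w, n_informative = m,
                        n_perm = n_perm, seed = seed, p_value = p)
  class(out) <- c("phi_result", class(out))
  out
}

#' Write a PHI report as TSV
#'
#' @param result A `phi_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phi_tsv <- function(result, path) {
  write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
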