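# Shared fixture builders: everything is generated in code at test time.

BASES <- c("A", "C", "G", "T")

random_alignment <- function(n, L, seed, ids = sprintf("s%02d", seq_len(n))) {
  set.seed(seed)
  mat <- matrix(sample(BASES, n * L, replace = TRUE), nrow = n,
                dimnames = list(ids, NULL))
  dna_alignment(mat, "random")
}

# Alignment of near-identical sequences with a controlled number of random
# substitutions per row relative to a common ancestor.
perturbed_alignment <- function(n, L, subs, seed) {
  set.seed(seed)
  root <- sample(BASES, L, replace = TRUE)
  mat <- t(vapply(seq_len(n), function(i) {
    s <- root
    pos <- sample.int(L, subs)
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(BASES, b), 1),
                     character(1))
    s
  }, character(L)))
  rownames(mat) <- sprintf("s%02d", seq_len(n))
  dna_alignment(mat, "perturbed")
}

# Clonal (single-genealogy) alignment for PHI calibration: two clades, star
# sampling within clades, evolved under the package's own K2P process.
clonal_alignment <- function(seed, L = 400, n = 12, depth = 0.08,
                             tip = 0.02) {
  set.seed(seed)
  root <- sample(BASES, L, replace = TRUE)
  c1 <- evolve_sequence(root, depth / 2)
  c2 <- evolve_sequence(root, depth / 2)
  rows <- rbind(
    t(vapply(seq_len(n / 2), function(i) evolve_sequence(c1, tip),
             character(L))),
    t(vapply(seq_len(n / 2), function(i) evolve_sequence(c2, tip),
             character(L))))
  rownames(rows) <- paste0("s", seq_len(n))
  dna_alignment(rows, "clonal")
}

# Recombinant alignment: two halves evolved on conflicting genealogies and
# spliced, the classic construction PHI is meant to detect.
recombinant_alignment <- function(seed, L = 300, n = 12) {
  set.seed(seed)
  half <- function(groups) {
    root <- sample(BASES, L, replace = TRUE)
    anc <- list(evolve_sequence(root, 0.05), evolve_sequence(root, 0.05))
    t(vapply(seq_len(n), function(i) evolve_sequence(anc[[groups[i]]], 0.02),
             character(L)))
  }
  g1 <- rep(c(1L, 2L), each = n / 2)
  g2 <- rep(c(1L, 2L), times = n / 2)
  rows <- cbind(half(g1), half(g2))
  rownames(rows) <- paste0("s", seq_len(n))
  dna_alignment(rows, "recombinant")
}

# Planted two-level distance matrix (species containing lineages) for ABGD
# nesting tests.
nested_matrix <- function(seed = 1, n_per_lineage = 4) {
  set.seed(seed)
  grp <- c(rep("A1", n_per_lineage), rep("A2", n_per_lineage),
           rep("B", 2 * n_per_lineage))
  sp <- sub("[0-9]$", "", grp)
  ids <- sprintf("%s_%02d", grp, seq_along(grp))
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <-
      if (grp[i] == grp[j]) runif(1, 0, 0.002)
      else if (sp[i] == sp[j]) runif(1, 0.0075, 0.0085)
      else runif(1, 0.038, 0.042)
  }
  dm <- as_genetic_dist(d)
  attr(dm, "species") <- stats::setNames(sp, ids)
  attr(dm, "lineage") <- stats::setNames(grp, ids)
  dm
}

# Random small haplotype set for network property tests.
random_haplotypes <- function(seed, n = 8, L = 12) {
  set.seed(seed)
  repeat {
    mat <- matrix(sample(c("A", "T"), n * L, replace = TRUE), nrow = n,
                  dimnames = list(sprintf("s%02d", seq_len(n)), NULL))
    if (!anyDuplicated(apply(mat, 1, paste, collapse = ""))) break
  }
  collapse_haplotypes(dna_alignment(mat, "haps"))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_enumeration_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vals <- c(x, y)
  stopifnot(!anyDuplicated(vals))
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Floyd-Warshall all-pairs shortest paths, an igraph-independent oracle.
fw_distances <- function(nodes, edges) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (k in seq_len(nrow(edges))) {
    i <- edges$from[k]; j <- edges$to[k]
    D[i, j] <- D[j, i] <- min(D[i, j], edges$weight[k])
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}
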