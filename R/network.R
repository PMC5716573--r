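# Median-joining haplotype networks: haplotype collapsing, the MJ iteration
# (minimum spanning network + improving median vectors), maximum-parsimony
# pruning of redundant medians/links, and inter-cluster mutation-step
# distances.

hamming <- function(a, b) sum(a != b)

seq_matrix <- function(sequences) {
  do.call(rbind, strsplit(sequences, "", fixed = TRUE))
}

hamming_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0L, n, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
    }
  }
  d
}

#' Collapse aligned sequences into haplotypes
#'
#' Identical rows are merged; haplotypes are numbered by first occurrence in
#' the alignment, so the numbering is invariant to later reordering of
#' duplicate carriers.
#'
#' @param aln A `dna_alignment`, already masked of ambiguous columns.
#' @param metadata Optional metadata tibble (`sample_id`, `geography`, ...)
#'   used to tag haplotypes with geography counts.
#' @return A `haplotype_tbl` tibble: `haplotype` (H1, H2, ...), `sequence`,
#'   `multiplicity`, `samples` (list column), `geography` (list column of
#'   named counts; empty when no metadata).
#' @export
collapse_haplotypes <- function(aln, metadata = NULL) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  first <- !duplicated(seqs)
  uniq <- seqs[first]
  idx <- match(seqs, uniq)
  geo <- if (!is.null(metadata)) {
    setNames(as.character(metadata$geography), metadata$sample_id)
  } else NULL
  out <- tibble::tibble(
    haplotype = paste0("H", seq_along(uniq)),
    sequence = unname(uniq),
    multiplicity = as.integer(tabulate(idx, nbins = length(uniq))),
    samples = lapply(seq_along(uniq), function(k) names(seqs)[idx == k]),
    geography = lapply(seq_along(uniq), function(k) {
      if (is.null(geo)) return(integer(0))
      tab <- table(geo[names(seqs)[idx == k]], useNA = "no")
      setNames(as.integer(tab), names(tab))
    })
  )
  class(out) <- c("haplotype_tbl", class(out))
  out
}

# epsilon-relaxed minimum spanning network: edge (u,v) of weight w is kept
# iff u and v are not connected using only edges of weight < w - epsilon.
# Union-find over ascending weight classes; weights are integer mutation
# counts, so classes are exact.
msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n < 2L) return(tibble::tibble(from = integer(0), to = integer(0),
                                    weight = integer(0)))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  w <- as.integer(d[upper.tri(d)])
  ord <- order(w)
  idx <- idx[ord, , drop = FALSE]
  w <- w[ord]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  keep <- logical(length(w))
  classes <- unique(w)
  merged_upto <- -Inf  # all edges with weight <= merged_upto are unioned
  for (cw in classes) {
    # union every edge strictly lighter than cw - epsilon first
    to_merge <- which(w > merged_upto & w < cw - epsilon - 1e-9)
    for (k in to_merge) {
      ru <- find(idx[k, 1L]); rv <- find(idx[k, 2L])
      if (ru != rv) parent[ru] <- rv
    }
    if (length(to_merge) > 0L) merged_upto <- max(w[to_merge])
    in_class <- which(w == cw)
    keep[in_class] <- vapply(in_class, function(k) {
      find(idx[k, 1L]) != find(idx[k, 2L])
    }, logical(1))
  }
  tibble::tibble(from = idx[keep, 1L], to = idx[keep, 2L], weight = w[keep])
}

# Dense Prim; cheap enough to call once per candidate median.
mst_cost <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(0)
  mind <- d[1L, ]
  mind[1L] <- Inf
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  total <- 0
  for (k in seq_len(n - 1L)) {
    j <- which.min(replace(mind, in_tree, Inf))
    total <- total + mind[j]
    in_tree[j] <- TRUE
    mind <- pmin(mind, d[j, ])
  }
  total
}

# Column-wise majority of a sequence triple; NULL when any column has three
# distinct states (no majority exists there).
triple_median <- function(m3) {
  a <- m3[1L, ]; b <- m3[2L, ]; c_ <- m3[3L, ]
  med <- ifelse(a == b | a == c_, a, ifelse(b == c_, b, NA_character_))
  if (anyNA(med)) return(NULL)
  paste(med, collapse = "")
}

#' Median-joining haplotype network
#'
#' Iterates between (i) the minimum spanning network over the current node
#' set within tolerance `epsilon` and (ii) adding median vectors: for every
#' triple of nodes connected in the network (sharing at least two of their
#' three links), the column-wise majority sequence is a candidate, and the
#' candidate whose addition most reduces the minimum-spanning-tree cost is
#' added. The loop stops when no candidate shortens the total connection
#' cost. Edge weights are mutation steps (Hamming distance over the analyzed
#' columns).
#'
#' @param haplos A `haplotype_tbl` from [collapse_haplotypes()].
#' @param epsilon Non-negative weight tolerance widening the spanning
#'   network (0, the default, matches common usage).
#' @return A `haplotype_network`: list with `nodes` (tibble: `name`,
#'   `sequence`, `type` observed/median, `multiplicity`, `samples`,
#'   `geography`), `edges` (tibble: `from`, `to`, `weight` in mutation
#'   steps), and `epsilon`.
#' @export
median_joining <- function(haplos, epsilon = 0) {
  stopifnot(nrow(haplos) >= 1L)
  seqs <- haplos$sequence
  types <- rep("observed", length(seqs))
  mat <- seq_matrix(seqs)
  d <- hamming_matrix(mat)
  if (length(seqs) > 1L) repeat {
    edges <- msn_edges(d, epsilon)
    n <- length(seqs)
    adj <- matrix(FALSE, n, n)
    adj[cbind(edges$from, edges$to)] <- TRUE
    adj <- adj | t(adj)
    base_cost <- mst_cost(d)
    cands <- character(0)
    if (n >= 3L) {
      # connected triples = a node plus two of its network neighbours
      nbrs <- lapply(seq_len(n), function(v) which(adj[v, ]))
      seen <- new.env(hash = TRUE)
      for (v in seq_len(n)) {
        nb <- nbrs[[v]]
        if (length(nb) < 2L) next
        prs <- combn(nb, 2L)
        for (k in seq_len(ncol(prs))) {
          key <- paste(sort(c(v, prs[, k])), collapse = ".")
          if (!is.null(seen[[key]])) next
          seen[[key]] <- TRUE
          med <- triple_median(mat[c(v, prs[, k]), , drop = FALSE])
          if (!is.null(med) && !(med %in% seqs)) cands <- c(cands, med)
        }
      }
    }
    cands <- unique(cands)
    if (length(cands) == 0L) break
    gains <- vapply(cands, function(m) {
      v <- colSums(t(mat) != strsplit(m, "", fixed = TRUE)[[1L]])
      base_cost - mst_cost(rbind(cbind(d, v), c(v, 0)))
    }, numeric(1))
    if (max(gains) <= 0) break
    best <- cands[which.max(gains)]
    newv <- colSums(t(mat) != strsplit(best, "", fixed = TRUE)[[1L]])
    d <- rbind(cbind(d, newv), c(newv, 0))
    dimnames(d) <- NULL
    mat <- rbind(mat, strsplit(best, "", fixed = TRUE)[[1L]])
    seqs <- c(seqs, best)
    types <- c(types, "median")
  }
  edges <- msn_edges(d, epsilon)
  n_obs <- nrow(haplos)
  nodes <- tibble::tibble(
    name = c(haplos$haplotype,
             if (length(seqs) > n_obs)
               paste0("mv", seq_len(length(seqs) - n_obs))),
    sequence = seqs,
    type = types,
    multiplicity = c(haplos$multiplicity,
                     rep(0L, length(seqs) - n_obs)),
    samples = c(haplos$samples,
                rep(list(character(0)), length(seqs) - n_obs)),
    geography = c(haplos$geography,
                  rep(list(integer(0)), length(seqs) - n_obs))
  )
  structure(list(nodes = nodes,
                 edges = tibble::tibble(from = nodes$name[edges$from],
                                        to = nodes$name[edges$to],
                                        weight = edges$weight),
                 epsilon = epsilon),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("<haplotype_network> ", sum(x$nodes$type == "observed"),
      " haplotypes + ", sum(x$nodes$type == "median"), " median vectors, ",
      nrow(x$edges), " links\n", sep = "")
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes$name, type = net$nodes$type,
                          multiplicity = net$nodes$multiplicity)
  )
}

network_distances <- function(net) {
  g <- as_igraph(net)
  igraph::distances(g, weights = igraph::E(g)$weight)
}

#' Maximum-parsimony pruning of a haplotype network
#'
#' Removes median vectors and links that lie on no minimal-cost path between
#' any pair of observed haplotypes. Shortest-path lengths between observed
#' haplotypes are unchanged, and pruning is idempotent.
#'
#' @param net A connected `haplotype_network`.
#' @return The pruned `haplotype_network`.
#' @export
mp_prune <- function(net) {
  D <- network_distances(net)
  nodes <- net$nodes$name
  obs <- nodes[net$nodes$type == "observed"]
  if (nrow(net$edges) == 0L) return(net)
  on_path_edge <- vapply(seq_len(nrow(net$edges)), function(k) {
    u <- net$edges$from[k]; v <- net$edges$to[k]; w <- net$edges$weight[k]
    for (a in obs) for (b in obs) {
      if (a == b) next
      if (isTRUE(all.equal(D[a, u] + w + D[v, b], D[a, b])) ||
          isTRUE(all.equal(D[a, v] + w + D[u, b], D[a, b]))) return(TRUE)
    }
    FALSE
  }, logical(1))
  on_path_node <- vapply(nodes, function(m) {
    if (m %in% obs) return(TRUE)
    for (a in obs) for (b in obs) {
      if (a == b) next
      if (isTRUE(all.equal(D[a, m] + D[m, b], D[a, b]))) return(TRUE)
    }
    FALSE
  }, logical(1))
  keep_nodes <- nodes[on_path_node]
  edges <- net$edges[on_path_edge &
                       net$edges$from %in% keep_nodes &
                       net$edges$to %in% keep_nodes, ]
  structure(list(nodes = net$nodes[net$nodes$name %in% keep_nodes, ],
                 edges = edges, epsilon = net$epsilon),
            class = "haplotype_network")
}

#' Minimal mutation steps between groups of haplotypes
#'
#' Entry (g, h) is the minimum, over cross-group pairs of observed
#' haplotypes, of the network shortest-path weight; the diagonal is 0 by
#' convention. A haplotype whose member samples span two groups contradicts
#' the partition and is an error.
#'
#' @param net A `haplotype_network`.
#' @param partition Named character vector `sample_id -> group` or a data
#'   frame with `sample_id` plus a grouping column.
#' @param group Grouping column name when `partition` is a data frame.
#' @return A symmetric numeric matrix of mutation steps with group dimnames.
#' @export
cluster_separation <- function(net, partition, group = "species") {
  part <- as_partition(partition, group)
  obs <- net$nodes[net$nodes$type == "observed", ]
  hap_group <- vapply(seq_len(nrow(obs)), function(k) {
    gs <- unique(part[obs$samples[[k]]])
    if (length(gs) != 1L || anyNA(gs)) {
      stop("haplotype ", obs$name[k], " spans groups: ",
           paste(gs, collapse = ", "), call. = FALSE)
    }
    gs
  }, character(1))
  D <- network_distances(net)
  groups <- sort(unique(hap_group))
  out <- matrix(0, length(groups), length(groups),
                dimnames = list(groups, groups))
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (i >= j) next
    hi <- obs$name[hap_group == groups[i]]
    hj <- obs$name[hap_group == groups[j]]
    out[i, j] <- out[j, i] <- min(D[hi, hj, drop = FALSE])
  }
  out
}

#' Export a haplotype network
#'
#' `write_network_graphml()` writes GraphML with node attributes (type,
#' multiplicity) and edge weights; `write_network_tsv()` writes the edge list
#' as TSV (`from`, `to`, `weight`).
#'
#' @param net A `haplotype_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_tsv <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
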