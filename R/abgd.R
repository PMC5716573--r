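# Automatic Barcode Gap Discovery (ABGD) style delimitation: scan a range of
# prior intraspecific divergences, locate the barcode gap in the ranked
# pairwise distances, partition by single linkage below the gap, and recurse
# within groups.

#' ABGD configuration
#'
#' @param p_min,p_max Bounds of the prior intraspecific divergence scan
#'   (proportion scale). Defaults follow common practice: `Pmin = 0.001`,
#'   `Pmax = 0.1`.
#' @param n_steps Number of priors, laid out in geometric progression from
#'   `p_min` to `p_max` inclusive.
#' @param gap_width Relative gap width `X`: a candidate gap must be more than
#'   `X` times the local gap scale to count as the barcode gap.
#' @return A list of class `abgd_config`.
#' @export
abgd_config <- function(p_min = 0.001, p_max = 0.1, n_steps = 10,
                        gap_width = 1.5) {
  stopifnot(p_min > 0, p_min < p_max, p_max < 1, n_steps >= 2, gap_width > 1)
  structure(list(p_min = p_min, p_max = p_max, n_steps = n_steps,
                 gap_width = gap_width),
            class = "abgd_config")
}

#' Geometric sequence of prior intraspecific divergences
#'
#' @param cfg An [abgd_config()].
#' @return Numeric vector of `n_steps` priors, geometric from `p_min` to
#'   `p_max` inclusive.
#' @export
prior_sequence <- function(cfg) {
  exp(seq(log(cfg$p_min), log(cfg$p_max), length.out = cfg$n_steps))
}

#' Locate the barcode gap in a ranked distance list
#'
#' Consecutive gaps `g_i = d[i+1] - d[i]` of the ascending distance list are
#' scanned. A gap is a candidate when its upper end is at least `prior`
#' (distances strictly below the prior are taken as guaranteed
#' intraspecific). A candidate qualifies when its width exceeds `X` times the
#' local gap scale, the mean of the up-to-`W` immediately preceding
#' consecutive gaps (`W = max(10, ceiling(0.05 * n))`, zero-width gaps
#' included; a first gap with no predecessors cannot qualify). The first
#' qualifying gap, scanning the ranked distances from below, is the barcode
#' gap and its midpoint is returned; `NA` when no gap qualifies. Scanning
#' from below means substructure above the prior splits in the initial
#' partition before deeper structure does — raise the prior (or rely on the
#' recursion) to delimit at the deeper level.
#'
#' @param distances Numeric vector of pairwise distances (any order).
#' @param prior Prior intraspecific divergence (proportion scale).
#' @param gap_width Relative gap width `X`.
#' @return Threshold distance (gap midpoint) or `NA_real_`.
#' @export
find_gap_threshold <- function(distances, prior, gap_width = 1.5) {
  if (length(distances) < 2L) {
    stop("need at least two distances to locate a gap", call. = FALSE)
  }
  d <- sort(distances)
  n <- length(d)
  g <- diff(d)
  W <- max(10L, ceiling(0.05 * n))
  for (i in seq_along(g)) {
    if (d[i + 1L] < prior) next
    if (i == 1L) next
    lo <- max(1L, i - W)
    scale <- mean(g[lo:(i - 1L)])
    if (g[i] > 0 && g[i] > gap_width * scale) {
      return((d[i] + d[i + 1L]) / 2)
    }
  }
  NA_real_
}

#' Single-linkage partition at a distance threshold
#'
#' Groups are the connected components of the graph joining samples at
#' distance `<= threshold`.
#'
#' @param dm A `genetic_dist`.
#' @param threshold Non-negative distance threshold (proportion scale).
#' @return Named integer vector `sample_id -> group index` (groups numbered
#'   by first appearance in `dm$sample_ids`).
#' @export
single_linkage <- function(dm, threshold) {
  stopifnot(threshold >= 0)
  adj <- dm$d <= threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  setNames(as.integer(comp), dm$sample_ids)
}

recursive_split <- function(dm, members, prior, gap_width) {
  if (length(members) < 3L) return(list(members))
  d <- dm$d[members, members, drop = FALSE]
  vals <- d[upper.tri(d)]
  thr <- find_gap_threshold(vals, prior, gap_width)
  if (is.na(thr)) return(list(members))
  sub <- as_genetic_dist(d, model = dm$model)
  part <- single_linkage(sub, thr)
  if (max(part) == 1L) return(list(members))
  unlist(lapply(split(members, part), recursive_split, dm = dm, prior = prior,
                gap_width = gap_width),
         recursive = FALSE, use.names = FALSE)
}

#' ABGD-style automatic species delimitation
#'
#' For each prior in the scan: find the barcode gap over all pairwise
#' distances and cut by single linkage at its midpoint (initial partition);
#' then re-apply the gap search within every group, recursively, until no
#' group splits (recursive partition). Deterministic for fixed input; the
#' recursive partition always refines the initial one, and initial group
#' counts are weakly decreasing in the prior.
#'
#' @param dm A `genetic_dist`.
#' @param cfg An [abgd_config()].
#' @return An `abgd_result`: list with `scan` (tibble: `prior`, `threshold`,
#'   `n_initial`, `n_recursive`), `partitions` (tibble: `sample_id`, `prior`,
#'   `group_initial`, `group_recursive`) and `config`.
#' @export
abgd <- function(dm, cfg = abgd_config()) {
  priors <- prior_sequence(cfg)
  vals <- dm$d[upper.tri(dm$d)]
  if (anyNA(vals)) stop("distance matrix has undefined entries", call. = FALSE)
  rows <- list(); parts <- list()
  for (p in priors) {
    thr <- find_gap_threshold(vals, p, cfg$gap_width)
    init <- if (is.na(thr)) {
      setNames(rep(1L, length(dm$sample_ids)), dm$sample_ids)
    } else {
      single_linkage(dm, thr)
    }
    groups <- split(dm$sample_ids, init)
    rec_groups <- unlist(lapply(groups, recursive_split, dm = dm, prior = p,
                                gap_width = cfg$gap_width),
                         recursive = FALSE, use.names = FALSE)
    rec <- integer(length(dm$sample_ids))
    names(rec) <- dm$sample_ids
    for (k in seq_along(rec_groups)) rec[rec_groups[[k]]] <- k
    rows[[length(rows) + 1L]] <- tibble::tibble(
      prior = p, threshold = thr,
      n_initial = length(groups), n_recursive = length(rec_groups)
    )
    parts[[length(parts) + 1L]] <- tibble::tibble(
      sample_id = dm$sample_ids, prior = p,
      group_initial = unname(init[dm$sample_ids]),
      group_recursive = unname(rec[dm$sample_ids])
    )
  }
  structure(list(scan = dplyr::bind_rows(rows),
                 partitions = dplyr::bind_rows(parts),
                 config = cfg),
            class = "abgd_result")
}

#' @export
print.abgd_result <- function(x, ...) {
  cat("<abgd_result> ", nrow(x$scan), " priors; initial groups ",
      paste(range(x$scan$n_initial), collapse = "-"), ", recursive ",
      paste(range(x$scan$n_recursive), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.abgd_result <- function(x, ...) x$partitions

#' @export
glance.abgd_result <- function(x, ...) x$scan

#' @export
autoplot.abgd_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$scan, c("n_initial", "n_recursive"),
                            names_to = "partition", values_to = "groups")
  df$partition <- sub("^n_", "", df$partition)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prior, y = .data$groups,
                                   colour = .data$partition)) +
    ggplot2::geom_step() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "prior intraspecific divergence",
                  y = "number of groups", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Extract one ABGD partition as a named vector
#'
#' @param result An `abgd_result`.
#' @param prior Prior value (matched to the nearest scanned prior).
#' @param which `"initial"` or `"recursive"`.
#' @return Named integer vector `sample_id -> group`.
#' @export
abgd_partition <- function(result, prior, which = c("initial", "recursive")) {
  which <- match.arg(which)
  scanned <- unique(result$partitions$prior)
  p <- scanned[which.min(abs(scanned - prior))]
  df <- result$partitions[result$partitions$prior == p, ]
  setNames(df[[paste0("group_", which)]], df$sample_id)
}

#' Write ABGD outputs as TSV
#'
#' @param result An `abgd_result`.
#' @param scan_path,partition_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_abgd_tsv <- function(result, scan_path = NULL, partition_path = NULL) {
  if (!is.null(scan_path)) {
    write.table(result$scan, scan_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(partition_path)) {
    write.table(result$partitions, partition_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(scan_path, partition_path))
}
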