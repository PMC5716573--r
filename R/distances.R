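# Pairwise genetic distances: Kimura 2-parameter, Jukes-Cantor 69 and
# uncorrected p, with pairwise or complete deletion of unusable sites.
#
# Distances are kept internally as proportions (substitutions/site); report
# writers multiply by 100 exactly once.

PURINES <- c("A", "G")

# Split a string into a character vector if needed.
as_sites <- function(s) {
  if (length(s) == 1L && nchar(s) > 1L) strsplit(s, "", fixed = TRUE)[[1]] else s
}

pair_counts <- function(s1, s2) {
  s1 <- toupper(as_sites(s1))
  s2 <- toupper(as_sites(s2))
  if (length(s1) != length(s2)) {
    stop("sequences must have equal aligned length", call. = FALSE)
  }
  acgt <- c("A", "C", "G", "T")
  use <- s1 %in% acgt & s2 %in% acgt
  n <- sum(use)
  if (n == 0L) stop("no usable sites shared by the pair", call. = FALSE)
  a <- s1[use]; b <- s2[use]
  diff <- a != b
  ts <- sum(diff & ((a %in% PURINES) == (b %in% PURINES)))
  list(n = n, transitions = ts, transversions = sum(diff) - ts)
}

#' Pairwise sequence distances
#'
#' `k2p_distance()` applies the Kimura 2-parameter correction
#' \eqn{d = -\frac12 \ln(1 - 2P - Q) - \frac14 \ln(1 - 2Q)} with `P` the
#' transition (A/G, C/T) and `Q` the transversion proportion over sites where
#' both sequences carry an unambiguous base. `p_distance()` is the raw
#' mismatch proportion, and `jc69_distance()` the Jukes-Cantor correction
#' \eqn{d = -\frac34 \ln(1 - \frac43 p)}.
#'
#' @param s1,s2 Aligned sequences of equal length, as strings or character
#'   vectors.
#' @return A list with `distance` (proportion scale) and `used_sites`.
#'   Saturated pairs (log argument non-positive) are an error: the distances
#'   this package targets are far below saturation, so saturation signals
#'   corrupted input.
#' @export
k2p_distance <- function(s1, s2) {
  ct <- pair_counts(s1, s2)
  P <- ct$transitions / ct$n
  Q <- ct$transversions / ct$n
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) {
    stop("K2P distance saturated (P = ", signif(P, 3), ", Q = ",
         signif(Q, 3), ")", call. = FALSE)
  }
  list(distance = -0.5 * log(a1) - 0.25 * log(a2), used_sites = ct$n)
}

#' @rdname k2p_distance
#' @export
p_distance <- function(s1, s2) {
  ct <- pair_counts(s1, s2)
  list(distance = (ct$transitions + ct$transversions) / ct$n,
       used_sites = ct$n)
}

#' @rdname k2p_distance
#' @export
jc69_distance <- function(s1, s2) {
  ct <- pair_counts(s1, s2)
  p <- (ct$transitions + ct$transversions) / ct$n
  if (p >= 0.75) {
    stop("JC69 distance saturated (p = ", signif(p, 3), ")", call. = FALSE)
  }
  list(distance = -0.75 * log(1 - 4 * p / 3), used_sites = ct$n)
}

scalar_distance <- function(model) {
  switch(model, K2P = k2p_distance, p = p_distance, JC69 = jc69_distance)
}

#' Full pairwise distance matrix for an alignment
#'
#' @param aln A `dna_alignment` with at least two rows.
#' @param model `"K2P"`, `"p"` or `"JC69"`.
#' @param deletion `"pairwise"` (default) drops gap/ambiguity sites per pair;
#'   `"complete"` first restricts the alignment to columns unambiguous in
#'   every row.
#' @param on_saturation `"error"` (default) aborts listing the offending
#'   pairs; `"drop"` records `NA` for them with a warning.
#' @return A `genetic_dist` object: list with `model`, `deletion`,
#'   `sample_ids`, `d` (symmetric matrix, proportion scale) and `used_sites`.
#' @export
distance_matrix <- function(aln, model = c("K2P", "p", "JC69"),
                            deletion = c("pairwise", "complete"),
                            on_saturation = c("error", "drop")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  on_saturation <- match.arg(on_saturation)
  if (nrow(aln) < 2L) stop("need at least two sequences", call. = FALSE)
  if (deletion == "complete") aln <- mask_columns(aln, "complete")
  ids <- sample_ids(aln)
  n <- length(ids)
  # one-hot encoding makes every pairwise count a BLAS cross-product
  oh <- lapply(c("A", "C", "G", "T"), function(b) {
    m <- matrix(0, n, ncol(aln))
    m[unclass(aln) == b] <- 1
    m
  })
  names(oh) <- c("A", "C", "G", "T")
  usable <- oh$A + oh$C + oh$G + oh$T
  us <- tcrossprod(usable)                             # pairwise usable sites
  matches <- tcrossprod(oh$A) + tcrossprod(oh$C) +
    tcrossprod(oh$G) + tcrossprod(oh$T)
  ts <- tcrossprod(oh$A, oh$G) + tcrossprod(oh$G, oh$A) +
    tcrossprod(oh$C, oh$T) + tcrossprod(oh$T, oh$C)
  diffs <- us - matches
  tv <- diffs - ts
  dimnames(us) <- dimnames(ts) <- dimnames(tv) <- dimnames(diffs) <-
    list(ids, ids)
  zero <- us == 0
  P <- ifelse(zero, NA_real_, ts / us)
  Q <- ifelse(zero, NA_real_, tv / us)
  p <- ifelse(zero, NA_real_, diffs / us)
  d <- switch(model,
    K2P = {
      a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
      ifelse(a1 <= 0 | a2 <= 0, NA_real_,
             -0.5 * log(pmax(a1, 1e-300)) - 0.25 * log(pmax(a2, 1e-300)))
    },
    p = p,
    JC69 = ifelse(p >= 0.75, NA_real_,
                  -0.75 * log(pmax(1 - 4 * p / 3, 1e-300)))
  )
  diag(d) <- 0
  diag(us) <- ncol(aln)
  bad_idx <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  if (nrow(bad_idx) > 0L) {
    bad <- paste0(ids[bad_idx[, 1L]], "/", ids[bad_idx[, 2L]],
                  ifelse(zero[bad_idx], ": no usable sites", ": saturated"))
    if (on_saturation == "error") {
      stop("undefined distances for pairs:\n  ",
           paste(head(bad, 10L), collapse = "\n  "), call. = FALSE)
    }
    warning(length(bad), " pair(s) dropped: ",
            paste(head(bad, 5L), collapse = "; "), call. = FALSE)
    us[is.na(d)] <- NA_integer_
    diag(us) <- ncol(aln)
  }
  storage.mode(us) <- "integer"
  structure(list(model = model, deletion = deletion, sample_ids = ids,
                 d = d, used_sites = us),
            class = "genetic_dist")
}

#' Build a `genetic_dist` from a plain matrix
#'
#' @param d Symmetric numeric distance matrix with dimnames (proportion
#'   scale).
#' @param model Label for the distance model.
#' @param used_sites Optional matrix of per-pair site counts.
#' @return A `genetic_dist`.
#' @export
as_genetic_dist <- function(d, model = "K2P", used_sites = NULL) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  if (max(abs(d - t(d))) > 1e-12 || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal", call. = FALSE)
  }
  structure(list(model = model, deletion = "pairwise",
                 sample_ids = rownames(d), d = d,
                 used_sites = used_sites %||%
                   matrix(NA_integer_, nrow(d), ncol(d),
                          dimnames = dimnames(d))),
            class = "genetic_dist")
}

#' @export
print.genetic_dist <- function(x, ...) {
  cat("<genetic_dist> ", x$model, " (", x$deletion, " deletion), ",
      length(x$sample_ids), " samples\n", sep = "")
  invisible(x)
}

#' @export
tidy.genetic_dist <- function(x, ...) {
  n <- length(x$sample_ids)
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble::tibble(
    sample1 = x$sample_ids[idx[, 1L]],
    sample2 = x$sample_ids[idx[, 2L]],
    distance = x$d[idx],
    used_sites = x$used_sites[idx]
  )
}

#' Within- and between-group mean divergences
#'
#' Arithmetic means of pairwise distances inside each group and across each
#' group pair; the analogue of the divergence tables barcoding papers print.
#' Singleton groups have no within-group pairs: their mean is `NA` (printed
#' as `"n/c"` by [divergence_table()]).
#'
#' @param dm A `genetic_dist`.
#' @param partition Named character vector `sample_id -> group`, or a data
#'   frame with `sample_id` and a grouping column.
#' @param group Grouping column name when `partition` is a data frame.
#' @return A tibble: `group1`, `group2`, `type` (`"within"`/`"between"`),
#'   `mean_distance` (proportion scale), `n_pairs`.
#' @export
group_divergence <- function(dm, partition, group = "species") {
  part <- as_partition(partition, group)
  miss <- setdiff(dm$sample_ids, names(part))
  if (length(miss) > 0L) {
    stop("samples missing from partition: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  grp <- part[dm$sample_ids]
  groups <- sort(unique(grp))
  pairs <- expand.grid(g1 = seq_along(groups), g2 = seq_along(groups))
  pairs <- pairs[pairs$g1 <= pairs$g2, ]
  purrr::pmap_dfr(pairs, function(g1, g2) {
    i <- which(grp == groups[g1])
    j <- which(grp == groups[g2])
    if (g1 == g2) {
      vals <- if (length(i) >= 2L) {
        combn(i, 2L, function(p) dm$d[p[1L], p[2L]])
      } else numeric(0)
    } else {
      vals <- as.vector(dm$d[i, j, drop = FALSE])
    }
    tibble::tibble(
      group1 = groups[g1], group2 = groups[g2],
      type = if (g1 == g2) "within" else "between",
      mean_distance = if (length(vals) > 0L) mean(vals) else NA_real_,
      n_pairs = length(vals)
    )
  })
}

#' Square divergence table with two models
#'
#' Lays out mean between-group divergences with one model below the diagonal
#' and (optionally) a second above, on the percent scale; within-group means
#' on the diagonal, `"n/c"` for singleton groups.
#'
#' @param gd_lower,gd_upper `group_divergence()` tibbles; `gd_upper` may be
#'   `NULL` to mirror `gd_lower`.
#' @return A character matrix, groups as row/column names.
#' @export
divergence_table <- function(gd_lower, gd_upper = NULL) {
  gd_upper <- gd_upper %||% gd_lower
  groups <- sort(unique(c(gd_lower$group1, gd_lower$group2)))
  k <- length(groups)
  out <- matrix("", k, k, dimnames = list(groups, groups))
  fmt <- function(x) ifelse(is.na(x), "n/c", sprintf("%.2f", 100 * x))
  fill <- function(gd, lower) {
    for (r in seq_len(nrow(gd))) {
      i <- match(gd$group1[r], groups); j <- match(gd$group2[r], groups)
      if (i == j) out[i, i] <<- fmt(gd$mean_distance[r])
      else if (lower) out[max(i, j), min(i, j)] <<- fmt(gd$mean_distance[r])
      else out[min(i, j), max(i, j)] <<- fmt(gd$mean_distance[r])
    }
  }
  fill(gd_lower, lower = TRUE)
  fill(gd_upper, lower = FALSE)
  out
}

#' Write a distance matrix as TSV or square PHYLIP
#'
#' @param dm A `genetic_dist`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(dm, path) {
  df <- data.frame(sample_id = dm$sample_ids, dm$d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
write_dist_phylip <- function(dm, path) {
  n <- length(dm$sample_ids)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste0(formatC(dm$sample_ids[i], width = -10),
                      paste(sprintf("%.6f", dm$d[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
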