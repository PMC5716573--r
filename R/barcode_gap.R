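# Barcoding-gap statistics: intra/inter distance partitioning, descriptive
# summaries, overlap measures, fold ratios, Mann-Whitney test.

#' Split pairwise distances into intra- and interspecific sets
#'
#' @param dm A `genetic_dist`.
#' @param partition Named character vector `sample_id -> group` or data frame
#'   with `sample_id` plus a grouping column.
#' @param exclude Group labels to drop before pairing (e.g. taxa represented
#'   by a single sample, which barcoding studies exclude from gap analysis).
#' @param group Grouping column name when `partition` is a data frame.
#' @return A `pair_distances` tibble: `sample1`, `sample2`, `group1`,
#'   `group2`, `distance` (proportion scale), `type` (`"intra"`/`"inter"`).
#'   `|intra| + |inter|` equals `choose(n, 2)` over included samples.
#' @export
partition_pairs <- function(dm, partition, exclude = NULL, group = "species") {
  part <- as_partition(partition, group)
  miss <- setdiff(dm$sample_ids, names(part))
  if (length(miss) > 0L) {
    stop("samples missing from partition: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- dm$sample_ids[!(part[dm$sample_ids] %in% exclude)]
  if (length(keep) < 2L) stop("fewer than two samples after exclusion",
                              call. = FALSE)
  d <- dm$d[keep, keep, drop = FALSE]
  grp <- part[keep]
  idx <- which(upper.tri(d), arr.ind = TRUE)
  out <- tibble::tibble(
    sample1 = keep[idx[, 1L]],
    sample2 = keep[idx[, 2L]],
    group1 = unname(grp[idx[, 1L]]),
    group2 = unname(grp[idx[, 2L]]),
    distance = d[idx]
  )
  out$type <- ifelse(out$group1 == out$group2, "intra", "inter")
  if (!any(out$type == "inter")) {
    attr(out, "single_group") <- TRUE
  }
  class(out) <- c("pair_distances", class(out))
  out
}

#' Descriptive statistics of a distance set
#'
#' Percentiles use linear interpolation between closest ranks (R quantile
#' type 7).
#'
#' @param values Non-empty numeric vector of distances.
#' @return One-row tibble: `n`, `mean`, `median`, `min`, `max`, `p5`, `p10`,
#'   `p90`, `p95`, on the scale of the input.
#' @export
dist_summary <- function(values) {
  if (length(values) == 0L) stop("empty distance set", call. = FALSE)
  q <- quantile(values, c(0.05, 0.10, 0.90, 0.95), type = 7, names = FALSE)
  tibble::tibble(
    n = length(values), mean = mean(values), median = median(values),
    min = min(values), max = max(values),
    p5 = q[1L], p10 = q[2L], p90 = q[3L], p95 = q[4L]
  )
}

#' Overlap between intra- and interspecific distance distributions
#'
#' Three measures, truncated at zero for reporting (signed values are kept
#' for diagnostics): `overlap1` = max intraspecific − min interspecific (the
#' classical barcoding-gap check), `overlap2` = 90th intraspecific percentile
#' − 10th interspecific percentile, `overlap3` = 95th intraspecific
#' percentile − 5th interspecific percentile.
#'
#' @param intra_stats,inter_stats Rows from [dist_summary()] (or any list
#'   with `max`, `min`, `p5`, `p10`, `p90`, `p95`), on a common scale.
#' @return One-row tibble with `overlap1..3` (truncated at 0) and
#'   `overlap1..3_signed`.
#' @export
overlap_stats <- function(intra_stats, inter_stats) {
  s1 <- intra_stats$max - inter_stats$min
  s2 <- intra_stats$p90 - inter_stats$p10
  s3 <- intra_stats$p95 - inter_stats$p5
  tibble::tibble(
    overlap1 = max(0, s1), overlap2 = max(0, s2), overlap3 = max(0, s3),
    overlap1_signed = s1, overlap2_signed = s2, overlap3_signed = s3
  )
}

#' Inter/intra fold ratios and the 10-fold rule
#'
#' @param mean_inter,mean_intra,median_inter,median_intra Distance means and
#'   medians on a common scale.
#' @return One-row tibble: `fold_mean`, `fold_median`, `ten_fold_rule`
#'   (`fold_mean > 10`), and a `display` string rounded to one decimal, e.g.
#'   `"35.4x"`. Zero denominators give `Inf` and a `TRUE` rule.
#' @export
fold_ratio <- function(mean_inter, mean_intra, median_inter = NA,
                       median_intra = NA) {
  fm <- if (mean_intra > 0) mean_inter / mean_intra else Inf
  fmd <- if (!is.na(median_intra) && median_intra > 0) {
    median_inter / median_intra
  } else if (is.na(median_intra)) NA_real_ else Inf
  tibble::tibble(
    fold_mean = fm, fold_median = fmd, ten_fold_rule = fm > 10,
    display = if (is.finite(fm)) sprintf("%.1fx", round(fm, 1)) else "Inf"
  )
}

#' Mann-Whitney U test between distance sets
#'
#' Exact enumeration when both samples have at most 8 tie-free observations,
#' otherwise the normal approximation with tie correction (no continuity
#' correction). U is reported for the first sample, so `U + U' = n1 * n2`.
#'
#' @param intra,inter Non-empty numeric vectors.
#' @return One-row tibble: `U`, `p_value` (two-sided), `exact`.
#' @export
mann_whitney <- function(intra, inter) {
  if (length(intra) == 0L || length(inter) == 0L) {
    stop("both distance sets must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(intra, inter)) > 0L
  exact <- length(intra) <= 8L && length(inter) <= 8L && !ties
  wt <- suppressWarnings(
    wilcox.test(intra, inter, exact = exact, correct = FALSE)
  )
  tibble::tibble(U = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Classical barcoding-gap check
#'
#' A (classical) barcoding gap is present when the largest intraspecific
#' distance is below the smallest interspecific distance, i.e. truncated
#' `overlap1 = 0`. The percentile-based overlaps are reported alongside as
#' relaxed diagnostics.
#'
#' @inheritParams mann_whitney
#' @return One-row tibble: `gap_present` plus the [overlap_stats()] columns.
#' @export
gap_present <- function(intra, inter) {
  ov <- overlap_stats(dist_summary(intra), dist_summary(inter))
  dplyr::bind_cols(tibble::tibble(gap_present = ov$overlap1 == 0), ov)
}

#' Full barcoding-gap summary for one locus
#'
#' The per-locus analogue of the intra/inter variation tables of barcoding
#' studies: pair counts, distribution summaries, overlap measures, fold
#' ratios, the 10-fold rule, a Mann-Whitney U test and the classical gap
#' flag. All distances are reported on the percent scale.
#'
#' @inheritParams partition_pairs
#' @param locus Locus label for the output row.
#' @return A one-row tibble (class `gap_summary`).
#' @export
gap_summary <- function(dm, partition, exclude = NULL, locus = "locus",
                        group = "species") {
  pairs <- partition_pairs(dm, partition, exclude = exclude, group = group)
  intra <- 100 * pairs$distance[pairs$type == "intra"]
  inter <- 100 * pairs$distance[pairs$type == "inter"]
  if (length(intra) == 0L || length(inter) == 0L) {
    stop("need both intra- and interspecific pairs for a gap summary",
         call. = FALSE)
  }
  si <- dist_summary(intra)
  se <- dist_summary(inter)
  ov <- overlap_stats(si, se)
  fr <- fold_ratio(se$mean, si$mean, se$median, si$median)
  mw <- mann_whitney(intra, inter)
  out <- dplyr::bind_cols(
    tibble::tibble(locus = locus, n_intra = si$n, n_inter = se$n),
    dplyr::rename_with(si[-1L], ~ paste0("intra_", .x)),
    dplyr::rename_with(se[-1L], ~ paste0("inter_", .x)),
    ov,
    fr[c("fold_mean", "fold_median", "ten_fold_rule")],
    mw[c("U", "p_value")],
    tibble::tibble(gap_present = ov$overlap1 == 0)
  )
  class(out) <- c("gap_summary", class(out))
  out
}

#' Histogram data for barcoding-gap plots
#'
#' @inheritParams partition_pairs
#' @param binwidth Bin width on the percent scale.
#' @return Tibble: `type`, `bin_start`, `bin_end` (percent scale, 1-based
#'   closed on the left), `count`.
#' @export
gap_histogram <- function(dm, partition, exclude = NULL, binwidth = 0.25,
                          group = "species") {
  pairs <- partition_pairs(dm, partition, exclude = exclude, group = group)
  pairs$pct <- 100 * pairs$distance
  edges <- seq(0, max(pairs$pct) + binwidth, by = binwidth)
  pairs |>
    dplyr::group_by(.data$type) |>
    dplyr::reframe({
      counts <- hist(.data$pct, breaks = edges, plot = FALSE)$counts
      tibble::tibble(bin_start = edges[-length(edges)],
                     bin_end = edges[-1L], count = counts)
    })
}

#' @export
autoplot.pair_distances <- function(object, binwidth = 0.25, ...) {
  df <- tibble::as_tibble(object)
  df$pct <- 100 * df$distance
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct, fill = .data$type)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6, boundary = 0) +
    ggplot2::labs(x = "K2P distance (%)", y = "pairs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom graphics hist
NULL
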