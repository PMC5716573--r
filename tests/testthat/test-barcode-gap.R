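toy_dm <- function() {
  # two species, two samples each: within 0.001/0.002, between ~0.04
  ids <- c("a1", "a2", "b1", "b2")
  d <- matrix(c(0, 0.001, 0.040, 0.041,
                0.001, 0, 0.042, 0.043,
                0.040, 0.042, 0, 0.002,
                0.041, 0.043, 0.002, 0), 4, 4,
              dimnames = list(ids, ids))
  as_genetic_dist(d)
}
toy_part <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")

test_that("pair partitioning counts intra and inter pairs exactly", {
  pp <- partition_pairs(toy_dm(), toy_part)
  expect_equal(sum(pp$type == "intra"), 2)
  expect_equal(sum(pp$type == "inter"), 4)
  expect_equal(nrow(pp), choose(4, 2))

  # single group: no inter pairs, flagged
  pp1 <- partition_pairs(toy_dm(), c(a1 = "A", a2 = "A", b1 = "A", b2 = "A"))
  expect_equal(sum(pp1$type == "inter"), 0)
  expect_true(isTRUE(attr(pp1, "single_group")))

  # excluding a singleton group removes exactly n - 1 inter pairs
  dm <- make_planted_matrix(n_species = 3, n_per_species = 3, seed = 2)
  truth <- attr(dm, "truth")
  truth["sp03_s03"] <- "solo"
  all_pairs <- partition_pairs(dm, truth)
  excl <- partition_pairs(dm, truth, exclude = "solo")
  expect_equal(nrow(all_pairs) - nrow(excl), 9 - 1)
  expect_equal(sum(all_pairs$type == "inter") - sum(excl$type == "inter"),
               9 - 1)
  expect_error(partition_pairs(toy_dm(), toy_part[-1]), "missing")
})

test_that("pair labels match brute-force enumeration", {
  dm <- make_planted_matrix(n_species = 2, n_per_species = 4, seed = 9)
  set.seed(9)
  part <- setNames(sample(c("x", "y"), 8, replace = TRUE), dm$sample_ids)
  pp <- partition_pairs(dm, part)
  for (r in seq_len(nrow(pp))) {
    expected <- if (part[pp$sample1[r]] == part[pp$sample2[r]]) "intra"
    else "inter"
    expect_identical(pp$type[r], expected)
    expect_equal(pp$distance[r], dm$d[pp$sample1[r], pp$sample2[r]])
  }
})

test_that("distance summaries use type-7 percentiles", {
  s <- dist_summary(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  expect_equal(s$p90, unname(quantile(1:4, 0.9)))
  cst <- dist_summary(rep(0.3, 10))
  expect_true(all(unlist(cst[-1]) == 0.3))
  expect_error(dist_summary(numeric(0)), "empty")
  # Monte-Carlo: P90 of many uniforms is near the 0.9 quantile
  set.seed(1)
  u <- runif(1000)
  expect_lt(abs(dist_summary(u)$p90 - 0.9), 0.03)
})

test_that("overlap statistics truncate at zero and ignore input order", {
  ov <- overlap_stats(list(max = 0.99, p90 = 0.25, p95 = 0.86),
                      list(min = 0.86, p10 = 1.98, p5 = 1.61))
  expect_equal(ov$overlap1, 0.13)
  expect_equal(ov$overlap2, 0)
  expect_equal(ov$overlap2_signed, 0.25 - 1.98)

  ov2 <- overlap_stats(list(max = 0.49, p90 = 0.33, p95 = 0.49),
                       list(min = 0.66, p10 = 1.16, p5 = 0.82))
  expect_equal(ov2$overlap1, 0)
  expect_equal(ov2$overlap1_signed, 0.49 - 0.66)

  set.seed(3)
  intra <- runif(50, 0, 1); inter <- runif(80, 0.5, 3)
  a <- overlap_stats(dist_summary(intra), dist_summary(inter))
  b <- overlap_stats(dist_summary(sample(intra)),
                     dist_summary(sample(inter)))
  expect_equal(a, b)
})

test_that("fold ratios implement the 10-fold rule", {
  fr <- fold_ratio(4.96, 0.14, 5.60, 0.05)
  expect_equal(fr$fold_mean, 4.96 / 0.14)
  expect_equal(round(fr$fold_mean, 1), 35.4)
  expect_equal(fr$fold_median, 112)
  expect_true(fr$ten_fold_rule)
  expect_equal(fr$display, "35.4x")

  expect_equal(round(fold_ratio(4.78, 0.31)$fold_mean, 1), 15.4)

  z <- fold_ratio(2, 0)
  expect_true(is.infinite(z$fold_mean))
  expect_true(z$ten_fold_rule)
})

test_that("Mann-Whitney exact path matches full enumeration", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)
  expect_true(mw$exact)

  set.seed(8)
  for (n1 in 2:6) for (n2 in 2:6) {
    x <- sample(seq(0.01, 1, by = 0.01), n1)
    y <- sample(setdiff(seq(0.01, 1, by = 0.01), x), n2)
    mw <- mann_whitney(x, y)
    expect_equal(mw$p_value, mw_enumeration_p(x, y), tolerance = 1e-12,
                 label = paste("n1 =", n1, "n2 =", n2))
  }
})

test_that("Mann-Whitney approximation behaves on large and null samples", {
  set.seed(2)
  x <- runif(100, 0, 1); y <- runif(100, 2, 3)
  mw <- mann_whitney(x, y)
  expect_false(mw$exact)
  expect_lt(mw$p_value, 1e-6)
  expect_equal(mw$U + (mann_whitney(y, x)$U), 100 * 100)

  same <- mann_whitney(runif(30), runif(30))
  expect_gt(same$p_value, 0.01)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("the classical gap flag follows truncated overlap1", {
  set.seed(4)
  intra <- runif(40, 0, 0.005)
  inter <- runif(60, 0.02, 0.05)
  g <- gap_present(intra, inter)
  expect_true(g$gap_present)
  overlapping <- gap_present(c(intra, 0.03), inter)
  expect_false(overlapping$gap_present)
})

test_that("gap_summary assembles the per-locus table on the percent scale", {
  gs <- gap_summary(toy_dm(), toy_part, locus = "toy")
  expect_equal(gs$n_intra, 2)
  expect_equal(gs$n_inter, 4)
  expect_equal(gs$intra_mean, 100 * mean(c(0.001, 0.002)))
  expect_equal(gs$inter_min, 4.0)
  expect_true(gs$gap_present)
  expect_true(gs$ten_fold_rule)
  expect_equal(gs$overlap1, 0)
  # percentile ordering invariant within each class
  expect_true(gs$intra_p5 <= gs$intra_p10 &&
                gs$intra_p10 <= gs$intra_median &&
                gs$intra_median <= gs$intra_p90 &&
                gs$intra_p90 <= gs$intra_p95)
})

test_that("gap histogram bins cover both distance classes", {
  h <- gap_histogram(toy_dm(), toy_part, binwidth = 0.5)
  expect_setequal(unique(h$type), c("intra", "inter"))
  expect_equal(sum(h$count[h$type == "intra"]), 2)
  expect_equal(sum(h$count[h$type == "inter"]), 4)
})
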