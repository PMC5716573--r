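# Expected values below are frozen from direct evaluation of the stated
# closed forms: K2P d = -ln(1-2P-Q)/2 - ln(1-2Q)/4, JC69 d = -3/4 ln(1-4p/3).

test_that("K2P matches the closed form on hand-computable pairs", {
  # ACGT vs AGGT: one transversion among 4 sites (P = 0, Q = 0.25)
  r <- k2p_distance("ACGT", "AGGT")
  expect_equal(r$distance, -0.5 * log(0.75) - 0.25 * log(0.5))
  expect_equal(r$distance, 0.3171278, tolerance = 1e-6)
  expect_equal(r$used_sites, 4L)

  # AAAA vs GAAA: one transition (P = 0.25, Q = 0)
  r <- k2p_distance("AAAA", "GAAA")
  expect_equal(r$distance, -0.5 * log(0.5))
  expect_equal(r$distance, 0.34657, tolerance = 1e-4)

  expect_equal(k2p_distance("ACGT", "ACGT")$distance, 0)
  expect_error(k2p_distance("AAAA", "GGGG"), "saturated")
  expect_error(k2p_distance("ACG", "ACGT"), "equal")
  expect_error(k2p_distance("NNNN", "ACGT"), "usable")
})

test_that("p-distance is the mismatch proportion over usable sites", {
  expect_equal(p_distance("ACGT", "AGGT")$distance, 0.25)
  expect_equal(p_distance("ACGT", "ACGT")$distance, 0)
  expect_equal(p_distance("ACGT", "TGCA")$distance, 1)
  r <- p_distance("AC-T", "ACGT")
  expect_equal(r$used_sites, 3L)
})

test_that("JC69 matches its closed form and saturates at p = 0.75", {
  expect_equal(jc69_distance("ACGT", "ACGT")$distance, 0)
  r <- jc69_distance("ACGT", "AGGT")  # p = 0.25
  expect_equal(r$distance, -0.75 * log(1 - 1 / 3))
  expect_equal(r$distance, 0.30410, tolerance = 1e-4)
  expect_error(jc69_distance("AAAA", "GGGT"), "saturated")
})

test_that("distance matrix equals the scalar-op loop", {
  aln <- perturbed_alignment(8, 100, subs = 15, seed = 42)
  for (model in c("K2P", "p", "JC69")) {
    dm <- distance_matrix(aln, model = model)
    rows <- unclass(aln)
    fun <- switch(model, K2P = k2p_distance, p = p_distance,
                  JC69 = jc69_distance)
    for (i in 1:7) for (j in (i + 1):8) {
      expect_equal(dm$d[i, j], fun(rows[i, ], rows[j, ])$distance,
                   tolerance = 1e-12)
    }
  }
})

test_that("K2P matrix agrees with an independent implementation", {
  skip_if_not_installed("ape")
  aln <- perturbed_alignment(6, 200, subs = 12, seed = 7)
  dm <- distance_matrix(aln, model = "K2P")
  dnab <- ape::as.DNAbin(matrix(tolower(unclass(aln)), nrow = 6,
                                dimnames = list(sample_ids(aln), NULL)))
  ref <- as.matrix(ape::dist.dna(dnab, model = "K80"))
  expect_equal(unname(dm$d), unname(ref[dm$sample_ids, dm$sample_ids]),
               tolerance = 1e-10)
})

test_that("pairwise and complete deletion count sites as predicted", {
  aln <- dna_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC",
                         c = "NNGTACGTAC"))
  dmp <- distance_matrix(aln, deletion = "pairwise")
  expect_equal(dmp$used_sites["a", "b"], 10L)
  expect_equal(dmp$used_sites["a", "c"], 8L)
  dmc <- distance_matrix(aln, deletion = "complete")
  expect_equal(dmc$used_sites["a", "b"], 8L)
  expect_equal(dmc$used_sites["a", "c"], 8L)
})

test_that("K2P dominates p-distance and reduces correctly without transversions", {
  set.seed(10)
  for (k in 1:50) {
    s1 <- sample(BASES, 60, replace = TRUE)
    s2 <- s1
    pos <- sample.int(60, 8)
    s2[pos] <- vapply(s2[pos], function(b) sample(setdiff(BASES, b), 1),
                      character(1))
    expect_gte(k2p_distance(s1, s2)$distance, p_distance(s1, s2)$distance)
  }
  # transitions only: d = -ln(1 - 2P)/2
  s1 <- rep(c("A", "C"), 20)
  s2 <- s1
  s2[1:8] <- ifelse(s1[1:8] == "A", "G", "T")
  P <- 8 / 40
  expect_equal(k2p_distance(s1, s2)$distance, -0.5 * log(1 - 2 * P))
})

test_that("distance matrices are symmetric with zero diagonal", {
  for (seed in 1:3) {
    dm <- distance_matrix(perturbed_alignment(7, 80, subs = 6, seed = seed))
    expect_equal(dm$d, t(dm$d))
    expect_equal(unname(diag(dm$d)), rep(0, 7))
    expect_true(all(dm$d >= 0))
    expect_equal(dm$used_sites, t(dm$used_sites))
  }
})

test_that("saturated pairs error by default and can be dropped", {
  aln <- dna_alignment(c(a = "AAAA", b = "AAAA", c = "GGGG"))
  expect_error(distance_matrix(aln), "a/c")
  expect_warning(dm <- distance_matrix(aln, on_saturation = "drop"),
                 "dropped")
  expect_true(is.na(dm$d["a", "c"]))
  expect_equal(dm$d["a", "b"], 0)
})

test_that("group divergences match brute-force pair enumeration", {
  # two groups of two: within 0, between 0.04
  d <- matrix(0.04, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d[1, 2] <- d[2, 1] <- 0; d[3, 4] <- d[4, 3] <- 0; diag(d) <- 0
  dm <- as_genetic_dist(d)
  part <- c(a = "g1", b = "g1", c = "g2", d = "g2")
  gd <- group_divergence(dm, part)
  expect_equal(gd$mean_distance[gd$type == "within"], c(0, 0))
  expect_equal(gd$mean_distance[gd$type == "between"], 0.04)

  # singleton group: within-group mean is NA, printed n/c
  part2 <- c(a = "g1", b = "g1", c = "g2", d = "g3")
  gd2 <- group_divergence(dm, part2)
  expect_true(is.na(gd2$mean_distance[gd2$group1 == "g3" &
                                        gd2$type == "within"]))
  tab <- divergence_table(gd2)
  expect_equal(tab["g3", "g3"], "n/c")

  # random matrix + partition vs brute force
  set.seed(5)
  dmr <- make_planted_matrix(n_species = 3, n_per_species = 4, seed = 5)
  partr <- sample(c("x", "y", "z"), 12, replace = TRUE)
  names(partr) <- dmr$sample_ids
  gdr <- group_divergence(dmr, partr)
  for (r in seq_len(nrow(gdr))) {
    g1 <- gdr$group1[r]; g2 <- gdr$group2[r]
    vals <- c()
    for (i in 1:11) for (j in (i + 1):12) {
      gi <- partr[dmr$sample_ids[i]]; gj <- partr[dmr$sample_ids[j]]
      if ((gi == g1 && gj == g2) || (gi == g2 && gj == g1)) {
        vals <- c(vals, dmr$d[i, j])
      }
    }
    if (gdr$n_pairs[r] > 0) {
      expect_equal(gdr$mean_distance[r], mean(vals))
      expect_equal(gdr$n_pairs[r], length(vals))
    }
  }
  expect_error(group_divergence(dmr, partr[-1]), "missing")
})

test_that("tidy() lists each unordered pair once", {
  dm <- distance_matrix(perturbed_alignment(5, 50, subs = 6, seed = 2))
  td <- tidy(dm)
  expect_equal(nrow(td), choose(5, 2))
  expect_false(any(td$sample1 == td$sample2))
})
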