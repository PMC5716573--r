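test_that("haplotype collapsing merges identical rows deterministically", {
  aln <- dna_alignment(c(s1 = "AAT", s2 = "AAT", s3 = "ATA", s4 = "AAT",
                         s5 = "ATA"))
  h <- collapse_haplotypes(aln)
  expect_equal(nrow(h), 2)
  expect_equal(sum(h$multiplicity), 5)
  expect_equal(h$haplotype, c("H1", "H2"))
  expect_setequal(h$samples[[1]], c("s1", "s2", "s4"))

  distinct <- random_haplotypes(seed = 2, n = 6, L = 10)
  expect_equal(nrow(distinct), 6)
  expect_true(all(distinct$multiplicity == 1))

  # permuted input: same haplotype set and multiplicities
  perm <- dna_alignment(unclass(aln)[c(5, 3, 1, 4, 2), , drop = FALSE])
  h2 <- collapse_haplotypes(perm)
  expect_setequal(h2$sequence, h$sequence)
  expect_equal(sort(h2$multiplicity), sort(h$multiplicity))

  meta <- tibble::tibble(sample_id = paste0("s", 1:5),
                         geography = c("n", "n", "s", "w", "s"))
  hg <- collapse_haplotypes(aln, meta)
  expect_equal(hg$geography[[1]], c(n = 2L, w = 1L))
})

test_that("median joining solves the classic three-haplotype star", {
  aln <- dna_alignment(c(a = "AAT", b = "ATA", c = "TAA"))
  net <- median_joining(collapse_haplotypes(aln))
  med <- net$nodes[net$nodes$type == "median", ]
  expect_equal(nrow(med), 1)
  expect_equal(med$sequence, "AAA")
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$weight == 1))
  expect_equal(sum(net$edges$weight), 3)  # beats the MST cost of 4
})

test_that("degenerate inputs give degenerate networks", {
  one <- median_joining(collapse_haplotypes(dna_alignment(c(a = "ACGT"))))
  expect_equal(nrow(one$nodes), 1)
  expect_equal(nrow(one$edges), 0)

  two <- median_joining(collapse_haplotypes(
    dna_alignment(c(a = "AAAA", b = "ATTA"))))
  expect_equal(nrow(two$edges), 1)
  expect_equal(two$edges$weight, 2L)
})

test_that("median vectors never increase the spanning cost", {
  for (seed in 1:10) {
    h <- random_haplotypes(seed, n = 7, L = 10)
    net <- median_joining(h)
    # MST over the final node set vs MST over observed haplotypes alone
    obs_mat <- do.call(rbind, strsplit(h$sequence, ""))
    all_mat <- do.call(rbind, strsplit(net$nodes$sequence, ""))
    mst_of <- function(m) {
      d <- matrix(0, nrow(m), nrow(m))
      for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
        d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
      }
      g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                               weighted = TRUE)
      sum(igraph::E(igraph::mst(g))$weight)
    }
    expect_lte(mst_of(all_mat), mst_of(obs_mat))
    # every observed haplotype is in the network, connected
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes$name)
    expect_true(igraph::is_connected(g))
    expect_equal(sum(net$nodes$multiplicity), sum(h$multiplicity))
    expect_true(all(net$edges$weight >= 1))
  }
})

test_that("MP pruning removes dead-end medians and is idempotent", {
  # hand-built network with a dead-end median vector
  net <- structure(list(
    nodes = tibble::tibble(
      name = c("H1", "H2", "mv1", "mv2"),
      sequence = c("AAAA", "AATT", "AATA", "GAAA"),
      type = c("observed", "observed", "median", "median"),
      multiplicity = c(2L, 1L, 0L, 0L),
      samples = list(c("s1", "s2"), "s3", character(0), character(0)),
      geography = rep(list(integer(0)), 4)),
    edges = tibble::tibble(from = c("H1", "mv1", "H1"),
                           to = c("mv1", "H2", "mv2"),
                           weight = c(1L, 1L, 1L)),
    epsilon = 0), class = "haplotype_network")
  pruned <- mp_prune(net)
  expect_false("mv2" %in% pruned$nodes$name)
  expect_true("mv1" %in% pruned$nodes$name)  # lies on the H1-H2 path
  again <- mp_prune(pruned)
  expect_identical(again$nodes$name, pruned$nodes$name)
  expect_identical(again$edges, pruned$edges)
})

test_that("pruning preserves observed-pair shortest paths", {
  for (seed in 1:25) {
    net <- median_joining(random_haplotypes(seed, n = 6, L = 9))
    pruned <- mp_prune(net)
    obs <- net$nodes$name[net$nodes$type == "observed"]
    d_before <- fw_distances(net$nodes$name, net$edges)[obs, obs]
    d_after <- fw_distances(pruned$nodes$name, pruned$edges)[obs, obs]
    expect_equal(d_after, d_before)
  }
})

test_that("cluster separation equals the shortest-path oracle", {
  aln <- dna_alignment(c(a1 = "AAAAAAAA", a2 = "AAAAAAAT",
                         b1 = "TTTTTAAA", b2 = "TTTTTAAT"))
  part <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  net <- median_joining(collapse_haplotypes(aln))
  cs <- cluster_separation(net, part)
  expect_equal(unname(diag(cs)), c(0, 0))
  # independent Floyd-Warshall oracle over observed haplotypes
  D <- fw_distances(net$nodes$name, net$edges)
  obs <- net$nodes[net$nodes$type == "observed", ]
  hap_grp <- vapply(obs$samples, function(s) unname(part[s[1]]), character(1))
  oracle <- min(D[obs$name[hap_grp == "A"], obs$name[hap_grp == "B"]])
  expect_equal(cs["A", "B"], oracle)

  # a haplotype shared across groups contradicts the partition
  bad <- c(a1 = "A", a2 = "B", b1 = "B", b2 = "B")
  aln2 <- dna_alignment(c(a1 = "AAAA", a2 = "AAAA", b1 = "TTTT",
                          b2 = "TTTT"))
  net2 <- median_joining(collapse_haplotypes(aln2))
  expect_error(cluster_separation(net2, bad), "spans")
})

test_that("network exports are readable", {
  net <- median_joining(random_haplotypes(seed = 5, n = 5, L = 8))
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network_graphml(net, gml)
  write_network_tsv(net, tsv)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(net$edges))
})
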