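# Seeded simulator of multilocus alignments with planted cryptic-species
# structure: K species split over two deep clades, optional within-species
# lineages, several slowly evolving "plastid" loci sharing one genealogy and
# a faster "nuclear" locus, all evolved under the Kimura 2-parameter process
# so the analysis model matches the generating model.

#' Synthetic cryptic-species study configuration
#'
#' Divergences are target mean pairwise K2P distances (proportion scale) and
#' must be ordered `intra < lineage_div < inter < deep`. The default panel
#' mirrors a typical plant-barcoding study: five plastid loci of realistic
#' lengths evolving at the base rate plus one faster nuclear locus
#' (rate x2.5).
#'
#' @param n_species Number of cryptic species `K`.
#' @param n_per_species Samples per species.
#' @param intra Target mean distance within a lineage (default 0.002, i.e.
#'   0.2%).
#' @param lineage_div Target distance between lineages of one species
#'   (default 0.008).
#' @param inter Target distance between species of the same deep clade
#'   (default 0.04).
#' @param deep Target distance across the two deep clades (default 0.08).
#' @param lineages Integer vector, one entry per species, giving the number
#'   of within-species lineages; `NULL` gives two lineages in each of the
#'   first two species and one elsewhere.
#' @param loci Tibble (`locus`, `length`, `class`, `rate`) describing the
#'   locus panel; `NULL` gives the default panel.
#' @param kappa Transition/transversion rate ratio of the K2P process.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_species = 5, n_per_species = 8,
                         intra = 0.002, lineage_div = 0.008,
                         inter = 0.04, deep = 0.08,
                         lineages = NULL, loci = NULL, kappa = 2) {
  if (!(intra < lineage_div && lineage_div < inter && inter < deep)) {
    stop("divergences must satisfy intra < lineage_div < inter < deep",
         call. = FALSE)
  }
  stopifnot(n_species >= 1, n_per_species >= 1, kappa > 0)
  lineages <- lineages %||%
    ifelse(seq_len(n_species) <= 2 & n_species >= 2, 2L, 1L)
  stopifnot(length(lineages) == n_species, all(lineages >= 1))
  loci <- loci %||% tibble::tibble(
    locus = c("matK", "rbcL", "rpoC1", "trnH-psbA", "trnL-trnF", "ITS1"),
    length = c(817L, 617L, 765L, 828L, 555L, 351L),
    class = c(rep("plastid", 5L), "nuclear"),
    rate = c(rep(1, 5L), 2.5)
  )
  stopifnot(all(loci$length >= 100L))
  structure(list(n_species = n_species, n_per_species = n_per_species,
                 intra = intra, lineage_div = lineage_div, inter = inter,
                 deep = deep, lineages = as.integer(lineages), loci = loci,
                 kappa = kappa),
            class = "synth_config")
}

#' Evolve a sequence under the Kimura 2-parameter process
#'
#' Exact per-site substitution probabilities of the K2P model over a branch:
#' with transition rate `kappa` times each transversion rate and branch
#' length `b` in expected substitutions/site, each site moves to its
#' transition partner with probability
#' \eqn{1/4 + e^{-4\beta t}/4 - e^{-2(\alpha+\beta)t}/2} and to each
#' transversion partner with probability \eqn{1/4 - e^{-4\beta t}/4}, where
#' \eqn{\alpha t = \kappa b/(\kappa+2)} and \eqn{\beta t = b/(\kappa+2)}.
#'
#' @param seq Character vector of bases.
#' @param branch_length Expected substitutions per site (>= 0).
#' @param kappa Transition/transversion rate ratio.
#' @return The evolved character vector. Uses the current RNG stream.
#' @export
evolve_sequence <- function(seq, branch_length, kappa = 2) {
  stopifnot(branch_length >= 0)
  if (branch_length == 0) return(seq)
  bt <- branch_length / (kappa + 2)
  at <- kappa * bt
  e2 <- exp(-4 * bt)
  e1 <- exp(-2 * (at + bt))
  p_ts <- 0.25 + 0.25 * e2 - 0.5 * e1
  p_tv <- 0.25 - 0.25 * e2        # each of the two transversion targets
  p_same <- 1 - p_ts - 2 * p_tv
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv2 <- c(A = "T", G = "T", C = "G", T = "G")
  u <- runif(length(seq))
  out <- seq
  move_ts <- u >= p_same & u < p_same + p_ts
  move_v1 <- u >= p_same + p_ts & u < p_same + p_ts + p_tv
  move_v2 <- u >= p_same + p_ts + p_tv
  out[move_ts] <- ts_partner[seq[move_ts]]
  out[move_v1] <- tv1[seq[move_v1]]
  out[move_v2] <- tv2[seq[move_v2]]
  out
}

# Fixed balanced genealogy implied by the config: node heights above the
# tips are half the target pairwise divergences.
synth_structure <- function(cfg) {
  species <- sprintf("sp%02d", seq_len(cfg$n_species))
  clade <- ifelse(seq_len(cfg$n_species) <= ceiling(cfg$n_species / 2),
                  "clade1", "clade2")
  rows <- list()
  k <- 0L
  for (s in seq_len(cfg$n_species)) {
    nl <- cfg$lineages[s]
    for (i in seq_len(cfg$n_per_species)) {
      k <- k + 1L
      lin <- if (nl > 1L) paste0(species[s], "_L", ((i - 1L) %% nl) + 1L)
      else NA_character_
      rows[[k]] <- tibble::tibble(
        sample_id = sprintf("%s_s%02d", species[s], i),
        species = species[s], lineage = lin, clade = clade[s]
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate a multilocus cryptic-species dataset
#'
#' One fixed balanced genealogy (species over two deep clades, lineages
#' within species, star-like sampling within lineages) is shared by the
#' plastid loci; the nuclear loci evolve independently on the same (hence
#' congruent) genealogy at their own rate. Branch lengths are calibrated so
#' mean pairwise K2P distances hit the configured targets at rate 1, scaled
#' per locus by its rate multiplier. Deterministic for a fixed seed.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed.
#' @return A `synth_data` list: `alignments` (named list of
#'   `dna_alignment`), `metadata` (tibble: `sample_id`, `species`, `lineage`,
#'   `geography`, `habitat`), `truth` (tibble: `sample_id`, `species`,
#'   `lineage`, `clade`), `config`, `seed`.
#' @export
simulate_barcode_data <- function(cfg = synth_config(), seed = 1) {
  set.seed(seed)
  truth <- synth_structure(cfg)
  species <- unique(truth$species)
  h_root <- cfg$deep / 2
  h_clade <- cfg$inter / 2
  h_spec <- cfg$lineage_div / 2
  h_lin <- cfg$intra / 2
  regions <- c("north", "south", "east", "west", "highland", "lowland")
  alns <- list()
  for (r in seq_len(nrow(cfg$loci))) {
    L <- cfg$loci$length[r]
    rate <- cfg$loci$rate[r]
    root <- sample(ACGT, L, replace = TRUE)
    clade_seq <- list(
      clade1 = evolve_sequence(root, rate * (h_root - h_clade), cfg$kappa),
      clade2 = evolve_sequence(root, rate * (h_root - h_clade), cfg$kappa)
    )
    rows <- matrix(NA_character_, nrow(truth), L,
                   dimnames = list(truth$sample_id, NULL))
    for (s in species) {
      sub <- truth[truth$species == s, ]
      multi <- !all(is.na(sub$lineage))
      h_sp <- if (multi) h_spec else h_lin
      sp_seq <- evolve_sequence(clade_seq[[sub$clade[1L]]],
                                rate * (h_clade - h_sp), cfg$kappa)
      if (multi) {
        for (lin in unique(sub$lineage)) {
          lin_seq <- evolve_sequence(sp_seq, rate * (h_spec - h_lin),
                                     cfg$kappa)
          for (id in sub$sample_id[sub$lineage == lin]) {
            rows[id, ] <- evolve_sequence(lin_seq, rate * h_lin, cfg$kappa)
          }
        }
      } else {
        for (id in sub$sample_id) {
          rows[id, ] <- evolve_sequence(sp_seq, rate * h_lin, cfg$kappa)
        }
      }
    }
    alns[[cfg$loci$locus[r]]] <- dna_alignment(rows, cfg$loci$locus[r])
  }
  geo_pool <- setNames(
    regions[((seq_along(species) - 1L) %% length(regions)) + 1L], species)
  metadata <- dplyr::mutate(
    truth[c("sample_id", "species", "lineage")],
    geography = unname(geo_pool[truth$species]),
    habitat = NA_character_
  )
  structure(list(alignments = alns, metadata = metadata, truth = truth,
                 config = cfg, seed = seed),
            class = "synth_data")
}

#' Write a simulated dataset to disk
#'
#' Emits one aligned FASTA per locus, the metadata TSV, the truth TSV and a
#' YAML echo of the configuration.
#'
#' @param sim A `synth_data` from [simulate_barcode_data()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(sim$alignments)) {
    write_alignment(sim$alignments[[nm]],
                    file.path(dir, paste0(gsub("[^A-Za-z0-9]", "_", nm),
                                          ".fasta")))
  }
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  cfg$loci <- as.data.frame(cfg$loci)
  yaml::write_yaml(c(unclass(cfg), list(seed = sim$seed)),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Distance matrix with a planted species partition
#'
#' Fast path for delimitation tests: within-species distances are drawn from
#' `U(0, intra_max)` and between-species distances from `U(inter_min,
#' inter_max)` directly, then symmetrized with a zero diagonal (the triangle
#' inequality is not enforced; single-linkage grouping does not need it).
#'
#' @param n_species,n_per_species Planted partition shape.
#' @param intra_max Upper bound of within-species distances (`a`).
#' @param inter_min,inter_max Bounds of between-species distances; requires
#'   `intra_max < inter_min`.
#' @param seed Integer seed.
#' @return A `genetic_dist` with attribute `truth`: named vector
#'   `sample_id -> species`.
#' @export
make_planted_matrix <- function(n_species = 5, n_per_species = 8,
                                intra_max = 0.003, inter_min = 0.03,
                                inter_max = 0.05, seed = 1) {
  if (intra_max >= inter_min) {
    stop("intra_max must be below inter_min", call. = FALSE)
  }
  set.seed(seed)
  spp <- rep(sprintf("sp%02d", seq_len(n_species)), each = n_per_species)
  ids <- sprintf("%s_s%02d", spp, rep(seq_len(n_per_species), n_species))
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <- if (spp[i] == spp[j]) runif(1, 0, intra_max)
    else runif(1, inter_min, inter_max)
  }
  dm <- as_genetic_dist(d, model = "K2P")
  attr(dm, "truth") <- setNames(spp, ids)
  dm
}
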