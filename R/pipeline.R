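# Full-study orchestration: evaluate every locus, the configured locus
# combinations and the combined dataset; emit the table/figure analogues
# (site classes, divergences, gap summaries, ABGD scans, trees, haplotype
# network, PHI) plus a run manifest.

#' Pipeline run configuration
#'
#' @param locus_paths Named character vector of aligned FASTA paths, one per
#'   locus (names are locus labels).
#' @param metadata_path Path to the sample metadata TSV (see
#'   [read_metadata()]).
#' @param out_dir Output directory.
#' @param combinations List of character vectors of locus names to
#'   concatenate and evaluate jointly (two-locus combinations and the like);
#'   the all-plastid and all-locus combined datasets are added automatically
#'   when `combined = TRUE`.
#' @param nuclear Locus names treated as nuclear (PHI test targets).
#' @param combined Evaluate the combined dataset over all loci?
#' @param deletion Deletion policy for distance matrices.
#' @param exclude Species labels excluded from gap statistics (singleton
#'   taxa).
#' @param abgd_cfg An [abgd_config()]; `gap_width_override` is a named
#'   numeric vector of per-locus relative gap widths.
#' @param gap_width_override Named numeric vector, per-locus `X` override.
#' @param bootstrap_B Bootstrap replicates for the NJ tree.
#' @param consensus_threshold Majority-rule threshold for the bootstrap
#'   consensus.
#' @param phi_w,phi_n_perm PHI window and permutation count.
#' @param seed Integer seed governing bootstrap and permutation draws.
#' @return A list of class `run_config`.
#' @export
run_config <- function(locus_paths, metadata_path, out_dir,
                       combinations = list(), nuclear = character(0),
                       combined = TRUE, deletion = "pairwise",
                       exclude = NULL, abgd_cfg = abgd_config(),
                       gap_width_override = NULL, bootstrap_B = 100,
                       consensus_threshold = 0.75, phi_w = 100,
                       phi_n_perm = 1000, seed = 1) {
  stopifnot(!is.null(names(locus_paths)), file.exists(metadata_path))
  missing <- locus_paths[!file.exists(locus_paths)]
  if (length(missing) > 0L) {
    stop("missing alignment files: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(locus_paths = locus_paths, metadata_path = metadata_path,
                 out_dir = out_dir, combinations = combinations,
                 nuclear = nuclear, combined = combined, deletion = deletion,
                 exclude = exclude, abgd_cfg = abgd_cfg,
                 gap_width_override = gap_width_override,
                 bootstrap_B = bootstrap_B,
                 consensus_threshold = consensus_threshold,
                 phi_w = phi_w, phi_n_perm = phi_n_perm, seed = seed),
            class = "run_config")
}

analyse_dataset <- function(name, aln, meta, cfg, dir, is_nuclear) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  part <- as_partition(meta, "species")
  gw <- cfg$abgd_cfg$gap_width
  if (!is.null(cfg$gap_width_override) && name %in% names(cfg$gap_width_override)) {
    gw <- cfg$gap_width_override[[name]]
  }
  acfg <- cfg$abgd_cfg
  acfg$gap_width <- gw

  sites <- classify_sites(aln)
  write.table(sites, file.path(dir, "site_classes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  dm <- distance_matrix(aln, model = "K2P", deletion = cfg$deletion)
  dm_p <- distance_matrix(aln, model = "p", deletion = cfg$deletion)
  write_dist_tsv(dm, file.path(dir, "k2p_matrix.tsv"))

  gd <- group_divergence(dm, part)
  gd_p <- group_divergence(dm_p, part)
  write.table(divergence_table(gd, gd_p), file.path(dir, "divergence.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)

  gs <- gap_summary(dm, part, exclude = cfg$exclude, locus = name)
  write.table(gs, file.path(dir, "gap_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  hist_df <- gap_histogram(dm, part, exclude = cfg$exclude)
  write.table(hist_df, file.path(dir, "gap_histogram.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ab <- abgd(dm, acfg)
  write_abgd_tsv(ab, file.path(dir, "abgd_scan.tsv"),
                 file.path(dir, "abgd_partitions.tsv"))

  njb <- bootstrap_support(aln, model = "K2P", builder = "nj",
                           B = cfg$bootstrap_B, seed = cfg$seed,
                           deletion = cfg$deletion, keep_trees = TRUE)
  cons <- majority_consensus(attr(njb, "replicates"),
                             threshold = cfg$consensus_threshold)
  attr(njb, "replicates") <- NULL
  write_newick(njb, file.path(dir, "nj_bootstrap.nwk"))
  write_newick(cons, file.path(dir, "nj_consensus.nwk"))
  write_newick(upgma_tree(dm), file.path(dir, "upgma.nwk"))

  lmap <- attr(aln, "locus_map")
  if (!is.null(lmap)) {
    write.table(lmap, file.path(dir, "locus_map.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  phi <- NULL
  if (is_nuclear) {
    phi <- tryCatch(phi_test(aln, w = cfg$phi_w, n_perm = cfg$phi_n_perm,
                             seed = cfg$seed),
                    error = function(e) NULL)
    if (!is.null(phi)) write_phi_tsv(phi, file.path(dir, "phi.tsv"))
  }

  list(name = name, sites = sites, gap = gs, abgd = ab, nj = njb, phi = phi,
       divergence = gd)
}

#' Run the full barcoding-gap analysis
#'
#' Reads per-locus alignments and metadata, masks ambiguous columns, and for
#' every locus, every configured combination and the combined dataset writes:
#' site classification, K2P/p divergence tables, the barcoding-gap summary
#' and histogram, the ABGD scan and partitions, NJ (bootstrap) and UPGMA
#' trees; a median-joining haplotype network (MP-pruned) for the combined
#' dataset; a PHI report for nuclear loci; and a YAML manifest recording
#' inputs, seeds and package versions. Stage failures are isolated per
#' dataset and collected in the returned `errors` tibble.
#'
#' @param cfg A [run_config()].
#' @return A `pipeline_result` list: `datasets` (per-dataset result lists),
#'   `network`, `errors` (tibble: dataset, stage, message), `manifest_path`.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- read_metadata(cfg$metadata_path)
  alns <- purrr::imap(cfg$locus_paths,
                      function(p, nm) mask_columns(read_alignment(p, nm)))
  shared <- purrr::reduce(purrr::map(alns, sample_ids), intersect)
  meta <- meta[meta$sample_id %in% shared, ]

  datasets <- purrr::imap(alns, function(a, nm) list(aln = a, name = nm))
  for (combo in cfg$combinations) {
    nm <- paste(combo, collapse = "+")
    datasets[[nm]] <- list(aln = concatenate_loci(alns[combo],
                                                  locus_name = nm),
                           name = nm)
  }
  plastid <- setdiff(names(cfg$locus_paths), cfg$nuclear)
  if (cfg$combined && length(plastid) >= 2L) {
    datasets[["combined_cp"]] <- list(
      aln = concatenate_loci(alns[plastid], locus_name = "combined_cp"),
      name = "combined_cp")
  }
  if (cfg$combined && length(alns) >= 2L) {
    datasets[["combined"]] <- list(
      aln = concatenate_loci(alns, locus_name = "combined"),
      name = "combined")
  }

  errors <- list()
  results <- list()
  for (ds in datasets) {
    keep <- intersect(sample_ids(ds$aln), meta$sample_id)
    aln <- new_alignment(unclass(ds$aln)[keep, , drop = FALSE],
                         locus_name(ds$aln))
    attr(aln, "locus_map") <- attr(ds$aln, "locus_map")
    res <- tryCatch(
      analyse_dataset(ds$name, aln, meta[match(keep, meta$sample_id), ], cfg,
                      file.path(cfg$out_dir, gsub("[^A-Za-z0-9_+-]", "_",
                                                  ds$name)),
                      is_nuclear = ds$name %in% cfg$nuclear),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- tibble::tibble(
        dataset = ds$name, stage = "analyse", message = conditionMessage(res))
    } else {
      results[[ds$name]] <- res
    }
  }

  network <- NULL
  if (!is.null(results$combined)) {
    network <- tryCatch({
      aln <- datasets$combined$aln
      keep <- intersect(sample_ids(aln), meta$sample_id)
      aln <- new_alignment(unclass(aln)[keep, , drop = FALSE], "combined")
      haps <- collapse_haplotypes(aln, meta[match(keep, meta$sample_id), ])
      net <- mp_prune(median_joining(haps))
      write_network_graphml(net, file.path(cfg$out_dir, "network.graphml"))
      write_network_tsv(net, file.path(cfg$out_dir, "network_edges.tsv"))
      net
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<- tibble::tibble(
        dataset = "combined", stage = "network",
        message = conditionMessage(e))
      NULL
    })
  }

  manifest <- list(
    package = "barcodegap",
    version = as.character(utils::packageVersion("barcodegap")),
    r_version = R.version.string,
    seed = cfg$seed,
    deletion = cfg$deletion,
    inputs = as.list(cfg$locus_paths),
    metadata = cfg$metadata_path,
    n_samples_shared = length(shared),
    datasets = names(datasets),
    abgd = list(p_min = cfg$abgd_cfg$p_min, p_max = cfg$abgd_cfg$p_max,
                n_steps = cfg$abgd_cfg$n_steps,
                gap_width = cfg$abgd_cfg$gap_width,
                gap_width_override = as.list(cfg$gap_width_override)),
    bootstrap_B = cfg$bootstrap_B,
    phi = list(w = cfg$phi_w, n_perm = cfg$phi_n_perm),
    percentile_definition = "type 7 (linear interpolation)",
    n_errors = length(errors)
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)

  structure(list(datasets = results, network = network,
                 errors = dplyr::bind_rows(errors),
                 manifest_path = manifest_path),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", length(x$datasets), " datasets analysed, ",
      nrow(x$errors) %||% 0L, " stage errors\n", sep = "")
  invisible(x)
}

#' Discriminant power of an inferred partition
#'
#' A true group is resolved when some inferred group has exactly the same
#' membership. The overall percentage of resolved groups mirrors the
#' "discriminant power" figure barcoding studies report.
#'
#' @param part_true,part_inferred Named vectors `sample_id -> group` (or data
#'   frames with `sample_id` plus a grouping column) over the same samples.
#' @param group Grouping column name for data-frame input.
#' @return A list: `per_group` tibble (`group`, `n`, `resolved`) and
#'   `pct_resolved`.
#' @export
barcode_discrimination <- function(part_true, part_inferred,
                                   group = "species") {
  pt <- as_partition(part_true, group)
  pi_ <- as_partition(part_inferred, group)
  if (!setequal(names(pt), names(pi_))) {
    stop("partitions cover different sample sets", call. = FALSE)
  }
  true_groups <- split(names(pt), pt)
  inf_groups <- split(names(pi_), pi_[names(pi_)])
  inf_sets <- lapply(inf_groups, sort)
  per_group <- tibble::tibble(
    group = names(true_groups),
    n = unname(lengths(true_groups)),
    resolved = unname(vapply(true_groups, function(m) {
      any(vapply(inf_sets, identical, logical(1), y = sort(m)))
    }, logical(1)))
  )
  list(per_group = per_group,
       pct_resolved = 100 * mean(per_group$resolved))
}
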