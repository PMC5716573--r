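# Alignment container and I/O.
#
# An alignment is stored as an n x L uppercase character matrix with sample
# ids as rownames, plus a locus name and a map from current column indices to
# the 1-based positions of the alignment as read (so masked reports can refer
# to original coordinates).

VALID_CHARS <- c("A", "C", "G", "T", "-", "N",
                 "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

new_alignment <- function(mat, locus_name, col_map = NULL) {
  structure(mat,
            locus_name = locus_name,
            col_map = col_map %||% seq_len(ncol(mat)),
            class = c("dna_alignment", "matrix", "array"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Construct an alignment from character sequences
#'
#' @param seqs Named character vector of equal-length aligned sequences, or a
#'   character matrix (one row per sample, one column per site) with rownames.
#' @param locus_name Name of the locus the alignment covers.
#'
#' @return A `dna_alignment`: an uppercase character matrix with sample ids as
#'   rownames and attributes `locus_name` and `col_map`.
#' @export
dna_alignment <- function(seqs, locus_name = "locus") {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs))) {
      stop("sequences must be named by sample id", call. = FALSE)
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      stop("aligned sequences must all have the same length (got ",
           paste(sort(unique(lens)), collapse = ", "), ")", call. = FALSE)
    }
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(mat) <- names(seqs)
  }
  if (ncol(mat) < 1L) stop("alignment must have at least one column", call. = FALSE)
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat))) {
    stop("sample ids must be present and unique", call. = FALSE)
  }
  mat <- toupper(mat)
  mat[mat == "U"] <- "T"
  bad <- setdiff(unique(as.vector(mat)), VALID_CHARS)
  if (length(bad) > 0L) {
    stop("invalid characters in alignment: ", paste(bad, collapse = " "),
         call. = FALSE)
  }
  new_alignment(mat, locus_name)
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("<dna_alignment> locus ", locus_name(x), ": ",
      nrow(x), " sequences x ", ncol(x), " sites\n", sep = "")
  invisible(x)
}

#' Locus name and sample ids of an alignment
#' @param aln A `dna_alignment`.
#' @return `locus_name()` the locus label; `sample_ids()` the sample ids.
#' @export
locus_name <- function(aln) attr(aln, "locus_name")

#' @rdname locus_name
#' @export
sample_ids <- function(aln) rownames(aln)

#' Read an aligned FASTA file
#'
#' Sequences are uppercased and `U` is mapped to `T`. Records of unequal
#' length, duplicated ids, or an empty file are errors: the input must be a
#' multiple sequence alignment, not raw reads.
#'
#' @param path Path to an aligned FASTA file.
#' @param locus_name Locus label attached to the alignment (defaults to the
#'   file name without extension).
#' @return A [dna_alignment()].
#' @export
read_alignment <- function(path, locus_name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  locus_name <- locus_name %||% sub("\\.[^.]*$", "", basename(path))
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  chr <- as.character(dna)
  lens <- lengths(chr)
  if (length(unique(lens)) != 1L) {
    stop("sequences in ", path, " are not aligned (lengths ",
         paste(sort(unique(lens)), collapse = ", "), ")", call. = FALSE)
  }
  mat <- do.call(rbind, chr)
  rownames(mat) <- names(dna)
  dna_alignment(mat, locus_name)
}

#' Write an alignment as FASTA
#'
#' @param aln A `dna_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  lines <- as.vector(rbind(paste0(">", names(seqs)), seqs))
  writeLines(lines, path)
  invisible(path)
}

#' Mask alignment columns containing gaps or ambiguity codes
#'
#' The default (and the package-wide default upstream of site classification)
#' is complete deletion: any column holding a gap, `N`, or an IUPAC ambiguity
#' code in any row is removed, mirroring the global exclusion of incomplete
#' data that distance-based barcoding studies apply before analysis. Pairwise
#' deletion is available at the distance layer instead.
#'
#' @param aln A `dna_alignment`.
#' @param policy `"complete"` drops any column with a non-ACGT character in
#'   any row; `"keep"` returns the alignment unchanged.
#' @return A `dna_alignment` whose `col_map` attribute maps retained columns
#'   to 1-based positions of the input.
#' @export
mask_columns <- function(aln, policy = c("complete", "keep")) {
  policy <- match.arg(policy)
  if (policy == "keep") return(aln)
  ok <- matrix(unclass(aln) %in% c("A", "C", "G", "T"), nrow = nrow(aln))
  usable <- colSums(!ok) == 0L
  if (!any(usable)) {
    stop("masking removed every column of locus ", locus_name(aln),
         call. = FALSE)
  }
  new_alignment(unclass(aln)[, usable, drop = FALSE], locus_name(aln),
                col_map = attr(aln, "col_map")[usable])
}

#' Classify alignment sites
#'
#' Counts conserved, variable, parsimony-informative and singleton columns.
#' A column is variable when it holds at least two distinct unambiguous
#' states; parsimony-informative when at least two states are each carried by
#' at least two sequences; singleton when variable but not informative.
#'
#' @param aln A `dna_alignment` with at least two rows.
#' @return A one-row tibble: `locus`, `length`, `conserved`, `variable`,
#'   `informative`, `singleton`, `pct_informative` (100 * informative /
#'   length).
#' @export
classify_sites <- function(aln) {
  if (nrow(aln) < 2L) {
    stop("site classification needs at least two sequences", call. = FALSE)
  }
  L <- ncol(aln)
  cls <- apply(unclass(aln), 2L, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    tab <- table(col)
    if (length(tab) < 2L) return("conserved")
    if (sum(tab >= 2L) >= 2L) return("informative")
    "singleton"
  })
  informative <- sum(cls == "informative")
  singleton <- sum(cls == "singleton")
  tibble::tibble(
    locus = locus_name(aln),
    length = L,
    conserved = sum(cls == "conserved"),
    variable = informative + singleton,
    informative = informative,
    singleton = singleton,
    pct_informative = 100 * informative / L
  )
}

#' Concatenate per-locus alignments
#'
#' @param alns List of `dna_alignment` objects.
#' @param samples `"intersection"` keeps samples present in every locus;
#'   `"union"` keeps all samples, filling missing loci with all-`N` rows
#'   (excluded pairwise downstream).
#' @param locus_name Name for the combined alignment.
#' @return A `dna_alignment` with a `locus_map` attribute: a tibble
#'   (`locus`, `start`, `end`) of 1-based closed per-locus coordinates.
#' @export
concatenate_loci <- function(alns, samples = c("intersection", "union"),
                             locus_name = "combined") {
  samples <- match.arg(samples)
  stopifnot(length(alns) >= 1L)
  ids <- purrr::map(alns, sample_ids)
  keep <- if (samples == "intersection") purrr::reduce(ids, intersect) else
    purrr::reduce(ids, union)
  if (length(keep) == 0L) {
    stop("no sample is present in every locus", call. = FALSE)
  }
  blocks <- purrr::map(alns, function(a) {
    out <- matrix("N", nrow = length(keep), ncol = ncol(a),
                  dimnames = list(keep, NULL))
    shared <- intersect(keep, sample_ids(a))
    out[shared, ] <- unclass(a)[shared, , drop = FALSE]
    out
  })
  lens <- purrr::map_int(blocks, ncol)
  ends <- cumsum(lens)
  combined <- new_alignment(do.call(cbind, blocks), locus_name)
  attr(combined, "locus_map") <- tibble::tibble(
    locus = purrr::map_chr(alns, barcodegap::locus_name),
    start = ends - lens + 1L,
    end = ends
  )
  combined
}

#' Read or write a sample metadata table
#'
#' The metadata TSV has a header `sample_id species lineage geography
#' habitat`; empty fields are read as `NA`. A lineage label without a species
#' label is rejected.
#'
#' @param path TSV file path.
#' @return A tibble with the five metadata columns.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("", "NA"), colClasses = "character")
  need <- c("sample_id", "species", "lineage", "geography", "habitat")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("metadata lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df[need])
  if (any(!is.na(df$lineage) & is.na(df$species))) {
    stop("lineage label present without a species label", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id) || any(is.na(df$sample_id))) {
    stop("sample ids must be present and unique", call. = FALSE)
  }
  df
}

#' @rdname read_metadata
#' @param meta Metadata tibble as returned by [read_metadata()].
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

# Named character vector sample_id -> group from a metadata-like data frame.
as_partition <- function(x, group = "species") {
  if (is.data.frame(x)) {
    out <- setNames(as.character(x[[group]]), x$sample_id)
  } else {
    out <- x
  }
  if (is.null(names(out))) stop("partition must be named by sample id", call. = FALSE)
  out
}
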