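#' Read a log2 expression matrix from TSV
#'
#' Expression matrices are tab-delimited with gene identifiers in the first
#' column and a header row of sample identifiers; the body is numeric on the
#' log2 scale. Row and column order are preserved from the file.
#'
#' @param path Path to a TSV file.
#' @param drop_missing Drop genes containing any missing value instead of
#'   rejecting the file. Mutual-information estimation assumes complete
#'   per-gene vectors, so the default is to reject.
#' @return A numeric matrix (genes x samples) with unique dimnames. The number
#'   of records read (and dropped, if any) is attached as attributes
#'   `n_read` / `n_dropped`.
#' @export
read_expression <- function(path, drop_missing = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, name_repair = "minimal")
  assert_that(ncol(raw) >= 2, "expression file needs a gene column and at least one sample")
  genes <- as.character(raw[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene id(s) in ", path, ": ", paste(unique(dup), collapse = ", ")))
  }
  samples <- colnames(raw)[-1]
  dup_s <- samples[duplicated(samples)]
  if (length(dup_s) > 0) {
    abort(paste0("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", ")))
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  mat <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  dimnames(mat) <- list(genes, samples)
  bad_cell <- is.na(mat) & !is.na(body)   # present but non-numeric
  if (any(bad_cell) && !drop_missing) {
    idx <- which(bad_cell, arr.ind = TRUE)[1, ]
    abort(paste0("non-numeric value '", body[idx[1], idx[2]], "' at gene '",
                 genes[idx[1]], "', sample '", samples[idx[2]], "'"))
  }
  n_read <- nrow(mat)
  n_dropped <- 0L
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)
    if (drop_missing) {
      drop_rows <- unique(bad[, 1])
      n_dropped <- length(drop_rows)
      inform(paste0("dropping ", n_dropped, " gene(s) with missing values"))
      mat <- mat[-drop_rows, , drop = FALSE]
    } else {
      abort(paste0(
        "missing/non-numeric value at gene '", genes[bad[1, 1]],
        "', sample '", samples[bad[1, 2]], "'"
      ))
    }
  }
  structure(mat, n_read = n_read, n_dropped = n_dropped)
}

#' Write an expression matrix to TSV
#'
#' @param expr Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  df <- tibble::as_tibble(expr, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

validate_expression <- function(expr) {
  assert_that(is.matrix(expr) && is.numeric(expr), "expression must be a numeric matrix")
  assert_that(!is.null(rownames(expr)) && !is.null(colnames(expr)),
              "expression matrix needs gene rownames and sample colnames")
  assert_that(!anyDuplicated(rownames(expr)), "duplicate gene ids")
  assert_that(!anyDuplicated(colnames(expr)), "duplicate sample ids")
  assert_that(!anyNA(expr), "expression matrix contains missing values")
  invisible(expr)
}

#' Read a sample phenotype table
#'
#' Tab-delimited with header; requires columns `sample_id` and `group`.
#' Additional annotation columns are carried through.
#'
#' @param path Path to a TSV file.
#' @param groups Optional declared vocabulary; group labels outside it are
#'   rejected.
#' @return A tibble with one row per sample.
#' @export
read_phenotypes <- function(path, groups = NULL) {
  ph <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  for (col in c("sample_id", "group")) {
    if (!col %in% colnames(ph)) abort(paste0("phenotype table missing required column '", col, "'"))
  }
  dup <- ph$sample_id[duplicated(ph$sample_id)]
  if (length(dup) > 0) abort(paste0("duplicate sample id(s): ", paste(unique(dup), collapse = ", ")))
  if (!is.null(groups)) {
    bad <- setdiff(unique(ph$group), groups)
    if (length(bad) > 0) abort(paste0("group label(s) outside declared vocabulary: ",
                                      paste(bad, collapse = ", ")))
  }
  ph
}

#' Read a TSS table
#'
#' Four tab-delimited columns: `gene_id`, `chrom`, `tss` (0-based position),
#' `strand` (`+`/`-`). One row per gene.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns gene_id, chrom, tss, strand.
#' @export
read_tss_table <- function(path) {
  tss <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  for (col in c("gene_id", "chrom", "tss", "strand")) {
    if (!col %in% colnames(tss)) abort(paste0("TSS table missing required column '", col, "'"))
  }
  tss$tss <- as.integer(tss$tss)
  assert_that(!anyNA(tss$tss), "non-integer TSS position")
  assert_that(!anyDuplicated(tss$gene_id), "duplicate gene id in TSS table")
  assert_that(all(tss$tss >= 0), "TSS positions must be >= 0 (0-based)")
  assert_that(all(tss$strand %in% c("+", "-")), "strand must be + or -")
  tss
}

#' Read promoter sequences from FASTA
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A named character vector, sequence_id -> sequence (upper case).
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  assert_that(!anyDuplicated(names(out)), "duplicate sequence id in FASTA")
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a two-column ortholog map
#'
#' Tab-delimited with header columns `source` and `target`; the map must be
#' one-to-one (duplicate source or target genes are rejected).
#'
#' @param path Path to a TSV file.
#' @return A named character vector, source gene -> target gene.
#' @export
read_ortholog_map <- function(path) {
  om <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  for (col in c("source", "target")) {
    if (!col %in% colnames(om)) abort(paste0("ortholog map missing required column '", col, "'"))
  }
  if (anyDuplicated(om$source)) {
    abort(paste0("duplicate source gene(s) in ortholog map: ",
                 paste(unique(om$source[duplicated(om$source)]), collapse = ", ")))
  }
  if (anyDuplicated(om$target)) {
    abort(paste0("duplicate target gene(s) in ortholog map: ",
                 paste(unique(om$target[duplicated(om$target)]), collapse = ", ")))
  }
  setNames(om$target, om$source)
}

#' Write / read a transcriptional network as TSV
#'
#' Networks serialize as four tab-delimited columns: `tf`, `target`,
#' `mi` (nats), `mode` (+1/-1). The round trip is lossless for the edge set
#' and ids; MI survives to full double precision.
#'
#' @param net A `regulatory_network` object (see [infer_network()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "regulatory_network"))
  readr::write_tsv(net$edges, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @param universe Optional gene universe for the loaded network; defaults to
#'   the union of TFs and targets present in the file.
#' @export
read_network <- function(path, universe = NULL) {
  edges <- readr::read_tsv(path, col_types = readr::cols(
    tf = readr::col_character(), target = readr::col_character(),
    mi = readr::col_double(), mode = readr::col_integer()
  ), progress = FALSE)
  for (col in c("tf", "target", "mi", "mode")) {
    if (!col %in% colnames(edges)) abort(paste0("network file missing required column '", col, "'"))
  }
  assert_that(all(edges$mi >= 0), "network MI values must be >= 0")
  assert_that(all(edges$mode %in% c(-1L, 1L)), "mode must be +1 or -1")
  assert_that(!any(edges$tf == edges$target), "self-edges are not allowed")
  new_network(edges,
              tf_ids = unique(edges$tf),
              universe = universe %||% union(edges$tf, edges$target),
              dpi_tolerance = NA_real_)
}
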