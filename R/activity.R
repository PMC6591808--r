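# Per-sample TF activity from regulons: expression is z-scored per gene
# against a reference (cohort mean/SD by default, or an explicit reference
# sample set such as normal specimens), then each TF's activity in a sample
# is the mode-signed sum of its targets' z-scores divided by
# sqrt(regulon size). A signed-sum score is linear, analytically checkable,
# and keeps the interface open for heavier rank-based enrichment scores.

#' Infer per-sample TF activity
#'
#' @param expr Genes x samples log2 expression matrix.
#' @param net A `regulatory_network` with modes.
#' @param reference `"cohort"` (z-score against all samples) or a character
#'   vector of reference sample ids (e.g. normal specimens).
#' @param min_regulon Minimum regulon size (after intersecting targets with
#'   `expr` rows); smaller TFs are excluded and listed in attribute
#'   `excluded`.
#' @return An `activity_matrix`: TFs x samples numeric matrix (activity
#'   z-units) with attributes `reference` and `excluded`.
#' @export
infer_activity <- function(expr, net, reference = "cohort", min_regulon = 5) {
  validate_expression(expr)
  stopifnot(inherits(net, "regulatory_network"))
  if (identical(reference, "cohort")) {
    ref_idx <- seq_len(ncol(expr))
  } else {
    ref_idx <- match(reference, colnames(expr))
    assert_that(length(ref_idx) > 0 && !anyNA(ref_idx),
                "reference samples must be present in the expression matrix")
  }
  mu <- rowMeans(expr[, ref_idx, drop = FALSE])
  sdev <- apply(expr[, ref_idx, drop = FALSE], 1, sd)
  z <- (expr - mu) / pmax(sdev, 1e-8)

  edges <- net$edges[net$edges$target %in% rownames(expr), , drop = FALSE]
  sizes <- table(edges$tf)
  keep_tfs <- names(sizes)[sizes >= min_regulon]
  excluded <- setdiff(net$tf_ids, keep_tfs)
  assert_that(length(keep_tfs) > 0, "no TF has a regulon of at least min_regulon scored targets")
  act <- t(vapply(keep_tfs, function(tf) {
    e <- edges[edges$tf == tf, ]
    colSums(z[e$target, , drop = FALSE] * e$mode) / sqrt(nrow(e))
  }, numeric(ncol(expr))))
  dimnames(act) <- list(keep_tfs, colnames(expr))
  structure(act, class = c("activity_matrix", class(act)),
            reference = if (identical(reference, "cohort")) "cohort" else reference,
            excluded = excluded)
}

#' @export
tidy.activity_matrix <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "tf") |>
    tidyr::pivot_longer(-"tf", names_to = "sample_id", values_to = "activity")
}

#' Hierarchical clustering of samples by TF activity
#'
#' @param act An [infer_activity()] matrix.
#' @param k Number of clusters to cut.
#' @param tf_subset Optional restriction to a TF subset (e.g. nominated
#'   MRs).
#' @param linkage Linkage method.
#' @param distance `"correlation"` (1 - Pearson across TFs) or
#'   `"euclidean"`.
#' @return Tibble with `sample_id` and `cluster`; `hclust` tree in
#'   attribute `tree`.
#' @export
cluster_samples_by_activity <- function(act, k = 2, tf_subset = NULL,
                                        linkage = "average",
                                        distance = c("correlation", "euclidean")) {
  distance <- match.arg(distance)
  stopifnot(inherits(act, "activity_matrix"))
  m <- unclass(act)
  if (!is.null(tf_subset)) {
    tf_subset <- intersect(tf_subset, rownames(m))
    assert_that(length(tf_subset) >= 2, "tf_subset leaves < 2 TFs")
    m <- m[tf_subset, , drop = FALSE]
  }
  cluster_columns(m, k, linkage, distance)
}

#' Hierarchical clustering of samples by one regulon's expression
#'
#' Clusters samples on the expression submatrix restricted to a TF's
#' regulon genes.
#'
#' @param expr Genes x samples log2 expression matrix.
#' @param net A `regulatory_network`.
#' @param tf TF whose regulon defines the gene subset.
#' @param k Number of clusters.
#' @param linkage,distance As in [cluster_samples_by_activity()], but the
#'   default distance is Euclidean: a perturbed regulator shifts its
#'   regulon's mean expression, and a shift-sensitive distance is what
#'   separates perturbed from control samples on a single regulon.
#' @return Tibble with `sample_id` and `cluster`; `hclust` tree in
#'   attribute `tree`.
#' @export
cluster_samples_by_regulon_expression <- function(expr, net, tf, k = 2,
                                                  linkage = "average",
                                                  distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  validate_expression(expr)
  targets <- intersect(regulon(net, tf), rownames(expr))
  if (length(targets) == 0) {
    abort(paste0("TF '", tf, "' has no regulon targets in the expression matrix"))
  }
  m <- expr[targets, , drop = FALSE]
  if (distance == "correlation" && nrow(m) < 2) distance <- "euclidean"
  cluster_columns(m, k, linkage, distance)
}

cluster_columns <- function(m, k, linkage, distance) {
  assert_that(k >= 1 && k <= ncol(m), "k must be in [1, n_samples]")
  d <- if (distance == "correlation") {
    as.dist(1 - cor(m))
  } else {
    dist(t(m))
  }
  tree <- hclust(d, method = linkage)
  labels <- cutree(tree, k = k)
  out <- tibble::tibble(sample_id = colnames(m), cluster = unname(labels))
  attr(out, "tree") <- tree
  out
}

#' Differential TF activity between two groups
#'
#' Effect sizes are mean activity differences (activity z-units; activities
#' can be negative, so fold-changes are not meaningful here); p-values from
#' a two-sided Wilcoxon rank-sum test, BH-adjusted across TFs.
#'
#' @param act An [infer_activity()] matrix.
#' @param pheno Phenotype tibble with `sample_id` and `group`.
#' @param group_a,group_b Group labels to contrast.
#' @return Tibble with `tf`, `mean_diff`, `p`, `p_adj`, ordered by p.
#' @export
differential_activity <- function(act, pheno, group_a, group_b) {
  stopifnot(inherits(act, "activity_matrix"))
  ph <- pheno[match(colnames(act), pheno$sample_id), ]
  a_idx <- which(ph$group == group_a)
  b_idx <- which(ph$group == group_b)
  assert_that(length(a_idx) >= 2 && length(b_idx) >= 2,
              "both groups need at least 2 samples with activity profiles")
  m <- unclass(act)
  out <- purrr::map_dfr(rownames(m), function(tf) {
    a <- m[tf, a_idx]; b <- m[tf, b_idx]
    tibble::tibble(
      tf = tf,
      mean_diff = mean(a) - mean(b),
      p = suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    )
  })
  out$p[is.na(out$p)] <- 1   # all-tie degenerate case
  out$p_adj <- bh_adjust(out$p)
  dplyr::arrange(out, .data$p, dplyr::desc(abs(.data$mean_diff)))
}
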