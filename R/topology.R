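# Regulon topology: pairwise regulon overlap (Jaccard by default), average-
# linkage clustering of TFs into co-regulated subnetworks, and a three-mode
# margin-based synergy classification for TF pairs sharing targets.

#' Pairwise regulon overlap matrix
#'
#' @param net A `regulatory_network`.
#' @param metric `"jaccard"` (|A n B| / |A u B|, the default) or
#'   `"overlap"` (|A n B| / min(|A|, |B|)).
#' @return A `regulon_overlap` object: symmetric TF x TF matrix with unit
#'   diagonal. TFs with empty regulons are excluded with a warning.
#' @export
regulon_overlap_matrix <- function(net, metric = c("jaccard", "overlap")) {
  metric <- match.arg(metric)
  stopifnot(inherits(net, "regulatory_network"))
  regs <- regulons(net)
  empty <- setdiff(net$tf_ids, names(regs))
  if (length(empty) > 0) {
    warn(paste0("excluding ", length(empty), " TF(s) with empty regulons: ",
                paste(head(empty, 5), collapse = ", "),
                if (length(empty) > 5) ", ..."))
  }
  tfs <- names(regs)
  assert_that(length(tfs) >= 1, "no TFs with non-empty regulons")
  # Binary membership matrix -> intersection sizes by crossproduct.
  all_targets <- unique(unlist(regs, use.names = FALSE))
  memb <- matrix(0L, length(tfs), length(all_targets),
                 dimnames = list(tfs, all_targets))
  for (tf in tfs) memb[tf, regs[[tf]]] <- 1L
  inter <- tcrossprod(memb)
  sizes <- diag(inter)
  denom <- if (metric == "jaccard") {
    outer(sizes, sizes, "+") - inter
  } else {
    outer(sizes, sizes, pmin)
  }
  ov <- inter / denom
  structure(ov, class = c("regulon_overlap", class(ov)), metric = metric)
}

#' Cluster TFs into co-regulated subnetworks
#'
#' Agglomerative clustering on distance 1 - overlap, cut into k groups.
#'
#' @param overlap A [regulon_overlap_matrix()] result.
#' @param k Number of subnetworks (>= 2).
#' @param linkage Linkage method for [stats::hclust()].
#' @return Tibble with columns `tf` and `subnetwork` (labels 1..k, numbered
#'   in dendrogram order); the `hclust` tree is attached as attribute
#'   `tree`.
#' @export
cluster_subnetworks <- function(overlap, k = 3, linkage = "average") {
  stopifnot(inherits(overlap, "regulon_overlap"))
  assert_that(k >= 2 && k <= nrow(overlap), "k must be in [2, n_tfs]")
  d <- as.dist(1 - unclass(overlap))
  tree <- hclust(d, method = linkage)
  labels <- cutree(tree, k = k)
  out <- tibble::tibble(tf = names(labels), subnetwork = unname(labels))
  attr(out, "tree") <- tree
  out
}

#' Synergy analysis for one focal TF
#'
#' For each partner TF sharing at least `min_shared` targets with the focal
#' TF, compares the mean signature log2FC of the shared targets (mS) with
#' the means over the full focal regulon (mA) and full partner regulon (mB):
#' \itemize{
#'   \item synergistic_repression: mS < min(mA, mB) - margin and mS < 0 —
#'     shared targets are pushed down beyond either full regulon;
#'   \item synergistic_activation: mS > max(mA, mB) + margin and mS > 0;
#'   \item attenuation: the partner's regulon is up (mB > margin) but the
#'     shared subset is pulled back toward baseline
#'     (mS < mB - margin and mS > -margin);
#'   \item none otherwise.
#' }
#'
#' @param net A `regulatory_network`.
#' @param sig A signature tibble with `gene_id` and `log2fc`.
#' @param tf_focus Focal TF id.
#' @param min_shared Minimum shared-target count to call anything.
#' @param margin Classification margin in log2 units.
#' @return Tibble of `synergy_call` rows: `tf_a`, `tf_b`, `n_shared`,
#'   `mean_lfc_a`, `mean_lfc_b`, `mean_lfc_shared`, `call`.
#' @export
synergy_analysis <- function(net, sig, tf_focus, min_shared = 5, margin = 0.2) {
  stopifnot(inherits(net, "regulatory_network"))
  regs <- regulons(net)
  if (!tf_focus %in% names(regs)) {
    abort(paste0("focal TF '", tf_focus, "' has no regulon in the network"))
  }
  lfc <- setNames(sig$log2fc, sig$gene_id)
  reg_a <- regs[[tf_focus]]
  m_a <- mean(lfc[intersect(reg_a, names(lfc))])
  partners <- setdiff(names(regs), tf_focus)
  purrr::map_dfr(partners, function(tf_b) {
    reg_b <- regs[[tf_b]]
    shared <- intersect(reg_a, reg_b)
    shared_in_sig <- intersect(shared, names(lfc))
    m_s <- if (length(shared_in_sig) > 0) mean(lfc[shared_in_sig]) else NA_real_
    m_b <- mean(lfc[intersect(reg_b, names(lfc))])
    call <- classify_synergy(m_a, m_b, m_s, length(shared), min_shared, margin)
    tibble::tibble(tf_a = tf_focus, tf_b = tf_b, n_shared = length(shared),
                   mean_lfc_a = m_a, mean_lfc_b = m_b, mean_lfc_shared = m_s,
                   call = call)
  })
}

classify_synergy <- function(m_a, m_b, m_s, n_shared, min_shared, margin) {
  if (n_shared < min_shared || is.na(m_s) || is.na(m_a) || is.na(m_b)) {
    return("none")
  }
  if (m_s < min(m_a, m_b) - margin && m_s < 0) return("synergistic_repression")
  if (m_s > max(m_a, m_b) + margin && m_s > 0) return("synergistic_activation")
  if (m_b > margin && m_s < m_b - margin && m_s > -margin) return("attenuation")
  "none"
}
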