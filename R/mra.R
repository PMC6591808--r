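# Master regulator analysis: for each TF, a one-sided hypergeometric test of
# its regulon's overlap with the DE gene set, over the universe of genes
# scored by the network. The attributable fraction is the share of the DE
# set (within the universe) contained in the regulon; the cumulative version
# unions regulons over top-ranked MRs so shared targets are not
# double-counted.

#' Run master regulator analysis
#'
#' @param net A `regulatory_network`.
#' @param sig A [differential_signature()] result (or a tibble with
#'   `gene_id` and `is_de`).
#' @param alpha Adjusted-p significance threshold for the `significant`
#'   flag.
#' @return An `mr_report`: tibble with one row per TF with a non-empty
#'   regulon — `tf`, `regulon_size`, `overlap`, `attributable_fraction`,
#'   `p`, `p_adj`, `rank`, `significant` — ordered by rank. Ties in p are
#'   broken by larger regulon, then TF id. The DE-set size within the
#'   universe is attached as attribute `n_de_universe`.
#' @export
run_mra <- function(net, sig, alpha = 0.05) {
  stopifnot(inherits(net, "regulatory_network"))
  assert_that(all(c("gene_id", "is_de") %in% colnames(sig)),
              "signature needs gene_id and is_de columns")
  universe <- net$universe
  de_set <- intersect(sig$gene_id[sig$is_de], universe)
  if (length(de_set) == 0) {
    abort("empty DE set after intersecting with the network universe; nothing to test")
  }
  regs <- regulons(net)
  if (length(regs) == 0) abort("network has no regulons")
  N <- length(universe)
  K <- length(de_set)
  rows <- purrr::imap_dfr(regs, function(targets, tf) {
    n_reg <- length(targets)
    k <- length(intersect(targets, de_set))
    tibble::tibble(
      tf = tf, regulon_size = n_reg, overlap = k,
      attributable_fraction = k / K,
      p = hypergeometric_upper_tail(k, K, n_reg, N)
    )
  })
  rows$p_adj <- bh_adjust(rows$p)
  ord <- order(rows$p, -rows$regulon_size, rows$tf)
  rows <- rows[ord, ]
  rows$rank <- seq_len(nrow(rows))
  rows$significant <- rows$p_adj < alpha
  out <- structure(rows, class = c("mr_report", class(rows)),
                   n_de_universe = K, universe_size = N, alpha = alpha)
  out
}

#' @export
glance.mr_report <- function(x, ...) {
  tibble::tibble(
    n_tfs_tested = nrow(x),
    n_significant = sum(x$significant),
    n_de_universe = attr(x, "n_de_universe"),
    universe_size = attr(x, "universe_size"),
    top_tf = x$tf[1],
    top_attributable_fraction = x$attributable_fraction[1]
  )
}

#' Cumulative MR-attributable fraction curve
#'
#' Entry k is the fraction of the DE set (within the network universe)
#' covered by the union of the regulons of the top-k MRs ranked by
#' increasing MRA p-value. Using the union means genes shared between
#' regulons are not double-counted, so the curve is non-decreasing and
#' bounded by 1.
#'
#' @param report An [run_mra()] result.
#' @param net The `regulatory_network` the report was computed on.
#' @param sig The signature the report was computed on.
#' @param k_max Curve length (defaults to all ranked TFs).
#' @return Tibble with columns `k`, `tf` (the TF added at step k), and
#'   `cumulative_fraction`.
#' @export
cumulative_attribution <- function(report, net, sig, k_max = nrow(report)) {
  stopifnot(inherits(report, "mr_report"), inherits(net, "regulatory_network"))
  assert_that(k_max >= 1 && k_max <= nrow(report),
              "k_max must be in [1, number of ranked TFs]")
  de_set <- intersect(sig$gene_id[sig$is_de], net$universe)
  assert_that(length(de_set) > 0, "empty DE set")
  regs <- regulons(net)
  covered <- character(0)
  frac <- numeric(k_max)
  for (k in seq_len(k_max)) {
    covered <- union(covered, intersect(regs[[report$tf[k]]], de_set))
    frac[k] <- length(covered) / length(de_set)
  }
  tibble::tibble(k = seq_len(k_max), tf = report$tf[seq_len(k_max)],
                 cumulative_fraction = frac)
}

#' Compare two MR lists against a random-overlap null
#'
#' @param list_a,list_b Character vectors of TF ids.
#' @param tf_universe All TFs either list could have drawn from.
#' @param n_sims Monte-Carlo draws for the null.
#' @param seed Integer seed.
#' @return List with `overlap` (character vector of shared TFs) and `test`
#'   (an `overlap_test`).
#' @export
compare_mr_lists <- function(list_a, list_b, tf_universe, n_sims = 10000,
                             seed = NULL) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  assert_that(all(list_a %in% tf_universe) && all(list_b %in% tf_universe),
              "MR lists must be drawn from tf_universe")
  shared <- intersect(list_a, list_b)
  test <- overlap_significance(length(list_a), length(list_b),
                               length(tf_universe), length(shared),
                               n_sims = n_sims, seed = seed)
  list(overlap = shared, test = test)
}
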