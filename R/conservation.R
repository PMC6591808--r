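# Cross-cohort and cross-species validation: mean regulon log2FC profiles,
# discovery/validation correlation, conserved-MR intersection after
# ortholog mapping with an empirical overlap null, and per-MR sign
# concordance of regulon perturbation.

#' Mean regulon log2 fold-change per TF
#'
#' @param net A `regulatory_network`.
#' @param sig A signature tibble with `gene_id` and `log2fc`.
#' @param tfs TFs to profile (default: all with a regulon).
#' @return Tibble with `tf`, `regulon_size`, `n_in_signature`, `mean_lfc`
#'   (NA, flagged via `n_in_signature = 0`, when the regulon lies entirely
#'   outside the signature).
#' @export
regulon_fold_change <- function(net, sig, tfs = NULL) {
  stopifnot(inherits(net, "regulatory_network"))
  lfc <- setNames(sig$log2fc, sig$gene_id)
  regs <- regulons(net)
  tfs <- tfs %||% names(regs)
  purrr::map_dfr(tfs, function(tf) {
    targets <- regs[[tf]] %||% character(0)
    in_sig <- intersect(targets, names(lfc))
    tibble::tibble(
      tf = tf,
      regulon_size = length(targets),
      n_in_signature = length(in_sig),
      mean_lfc = if (length(in_sig) > 0) mean(lfc[in_sig]) else NA_real_
    )
  })
}

#' Cross-cohort validation of MR regulon fold-changes
#'
#' Pairs each MR's mean regulon log2FC under the discovery signature with
#' the same quantity under an independent validation signature and reports
#' Pearson and Spearman correlations.
#'
#' @param net A `regulatory_network` (shared regulon structure).
#' @param sig_discovery,sig_validation Signature tibbles.
#' @param mr_list TFs to validate.
#' @return List with `table` (per-MR paired means and regulon sizes),
#'   `pearson` and `spearman` (each a list with `estimate` and `p`).
#' @export
cross_cohort_validation <- function(net, sig_discovery, sig_validation, mr_list) {
  disc <- regulon_fold_change(net, sig_discovery, mr_list)
  val <- regulon_fold_change(net, sig_validation, mr_list)
  tab <- dplyr::inner_join(
    dplyr::select(disc, "tf", "regulon_size", mean_lfc_discovery = "mean_lfc"),
    dplyr::select(val, "tf", mean_lfc_validation = "mean_lfc"),
    by = "tf"
  )
  tab <- tab[!is.na(tab$mean_lfc_discovery) & !is.na(tab$mean_lfc_validation), ]
  assert_that(nrow(tab) >= 3, "need >= 3 MRs with defined means in both cohorts")
  pe <- cor.test(tab$mean_lfc_discovery, tab$mean_lfc_validation, method = "pearson")
  sp <- suppressWarnings(
    cor.test(tab$mean_lfc_discovery, tab$mean_lfc_validation, method = "spearman")
  )
  list(
    table = tab,
    pearson = list(estimate = unname(pe$estimate), p = pe$p.value),
    spearman = list(estimate = unname(sp$estimate), p = sp$p.value)
  )
}

#' Conserved master regulators across cohorts/species
#'
#' Maps all MR lists into the first list's namespace via the ortholog map,
#' intersects them, and tests the intersection size against a null of
#' uniformly random TF sets of the same sizes drawn from `tf_universe`.
#'
#' @param mr_sets List of >= 2 character vectors of TF ids. Lists whose TFs
#'   live in the second namespace are translated back through the map.
#' @param ortholog_map Named character vector, namespace-1 id ->
#'   namespace-2 id (one-to-one). Use `NULL` when all lists share one
#'   namespace.
#' @param tf_universe TF universe for the null (namespace-1 ids; shared
#'   orthologous TFs by default choice of caller).
#' @param n_sims Monte-Carlo draws.
#' @param seed Integer seed.
#' @return A `conserved_mr_result`: list with `mapped_sets`, `intersection`,
#'   `dropped` (per-set TFs without orthologs), and `test`
#'   (an `overlap_test`; for > 2 sets the null draws all sets and intersects
#'   them jointly).
#' @export
conserved_mrs <- function(mr_sets, ortholog_map = NULL, tf_universe,
                          n_sims = 10000, seed = NULL) {
  assert_that(is.list(mr_sets) && length(mr_sets) >= 2,
              "need at least two MR lists")
  inv_map <- if (!is.null(ortholog_map)) setNames(names(ortholog_map), ortholog_map)
  dropped <- vector("list", length(mr_sets))
  mapped_sets <- lapply(seq_along(mr_sets), function(i) {
    s <- unique(mr_sets[[i]])
    if (is.null(inv_map)) return(s)
    # translate namespace-2 ids back; namespace-1 ids pass through if mapped
    in1 <- s[s %in% names(ortholog_map)]
    in2 <- unname(inv_map[s[s %in% names(inv_map)]])
    lost <- setdiff(s, c(in1, s[s %in% names(inv_map)]))
    dropped[[i]] <<- lost
    unique(c(in1, in2))
  })
  inter <- Reduce(intersect, mapped_sets)
  universe <- unique(tf_universe)
  sizes <- lengths(mapped_sets)
  assert_that(all(sizes <= length(universe)),
              "mapped MR lists exceed the TF universe")
  observed <- length(inter)
  if (length(mapped_sets) == 2) {
    test <- overlap_significance(sizes[1], sizes[2], length(universe), observed,
                                 n_sims = n_sims, seed = seed)
  } else {
    sims <- with_seed(seed, vapply(seq_len(n_sims), function(i) {
      length(Reduce(intersect, lapply(sizes, function(sz) sample(universe, sz))))
    }, numeric(1)))
    lambda_hat <- mean(sims)
    test <- structure(list(
      observed_overlap = observed,
      simulated_overlaps = as.integer(sims),
      lambda_hat = lambda_hat,
      p_empirical = (sum(sims >= observed) + 1) / (n_sims + 1),
      p_poisson = if (observed == 0) 1 else
        ppois(observed - 1, lambda_hat, lower.tail = FALSE)
    ), class = "overlap_test")
  }
  structure(list(
    mapped_sets = mapped_sets,
    intersection = sort(inter),
    dropped = dropped,
    test = test
  ), class = "conserved_mr_result")
}

#' @export
print.conserved_mr_result <- function(x, ...) {
  cat("<conserved_mr_result> intersection of", length(x$mapped_sets), "lists:",
      length(x$intersection), "TF(s)",
      if (length(x$intersection) > 0)
        paste0("(", paste(head(x$intersection, 8), collapse = ", "), ")"),
      "| p_empirical =", signif(x$test$p_empirical, 4), "\n")
  invisible(x)
}

#' Sign concordance of conserved-MR regulon perturbation
#'
#' @param fc1,fc2 [regulon_fold_change()] tibbles for the two cohorts or
#'   species (`fc2$tf` may be in the second namespace if `ortholog_map` is
#'   given).
#' @param mrs Conserved MR ids (namespace 1).
#' @param ortholog_map Optional named map, namespace-1 -> namespace-2.
#' @return Tibble with `tf`, `mean_lfc_cohort1`, `mean_lfc_cohort2`,
#'   `sign_concordant` (strict product > 0; a zero or missing mean is not
#'   concordant and is flagged via `defined`).
#' @export
concordance_classification <- function(fc1, fc2, mrs, ortholog_map = NULL) {
  m1 <- setNames(fc1$mean_lfc, fc1$tf)
  m2 <- setNames(fc2$mean_lfc, fc2$tf)
  purrr::map_dfr(mrs, function(tf) {
    tf2 <- if (!is.null(ortholog_map) && tf %in% names(ortholog_map))
      ortholog_map[[tf]] else tf
    a <- if (tf %in% names(m1)) m1[[tf]] else NA_real_
    b <- if (tf2 %in% names(m2)) m2[[tf2]] else NA_real_
    defined <- !is.na(a) && !is.na(b) && a != 0 && b != 0
    tibble::tibble(
      tf = tf,
      mean_lfc_cohort1 = a,
      mean_lfc_cohort2 = b,
      defined = defined,
      sign_concordant = defined && (a * b > 0)
    )
  })
}
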