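# Planted ground truth: a signed, weighted TF -> target network with block
# structure, plus a subtype design assigning activity shifts (delta, in
# log2-activity units) to a small set of perturbed "master regulator" TFs per
# subtype. Everything downstream is benchmarked against this object.

#' Generate planted regulatory ground truth
#'
#' Draws a TF -> target network with block structure: TFs and targets are
#' partitioned into `overlap_blocks` blocks and each TF samples most of its
#' regulon from its own block's target pool, so TFs within a block share
#' targets at rate `within_block_rate` and form co-regulated subnetworks.
#' Each subtype receives a disjoint set of `n_perturbed` TFs whose latent
#' activity is shifted by `delta` in samples of that subtype.
#'
#' @param seed Integer seed (full determinism).
#' @param n_tfs Number of transcription factors (>= 2).
#' @param n_targets Number of non-TF target genes.
#' @param regulon_size_range Length-2 integer range of regulon sizes.
#' @param overlap_blocks Number of co-regulated blocks (>= 1).
#' @param frac_repressive Probability an edge has mode -1.
#' @param within_block_rate Fraction of a regulon drawn from the TF's own
#'   block pool (the rest is drawn from all targets).
#' @param n_subtypes Number of tumor subtypes in the design.
#' @param n_perturbed Number of perturbed (master-regulator) TFs per subtype.
#' @param delta Activity shift, log2-activity units, for perturbed TFs.
#' @param noise_sd Residual expression noise SD (log2 units).
#' @param max_indegree Maximum number of regulators per target gene. Each
#'   regulator contributes one unit of activity-driven variance to its
#'   targets, so bounding the in-degree keeps per-gene variance comparable
#'   across the universe (regulatory in-degree after interaction pruning is
#'   low in inferred networks).
#' @return A `synthetic_truth` object: list with `tf_ids`, `target_ids`,
#'   `gene_ids`, `regulons` (named list of tibbles target/mode/weight),
#'   `blocks`, `subtype_design` (named list of tibbles tf/delta),
#'   `noise_sd`, `seed`.
#' @export
generate_truth <- function(seed, n_tfs = 60, n_targets = 600,
                           regulon_size_range = c(8, 20),
                           overlap_blocks = 3, frac_repressive = 0.25,
                           within_block_rate = 0.7,
                           n_subtypes = 2, n_perturbed = 5,
                           delta = 3, noise_sd = 0.4, max_indegree = 2) {
  assert_that(n_tfs >= 2, "need at least 2 TFs")
  assert_that(length(regulon_size_range) == 2 &&
                regulon_size_range[1] >= 1 && regulon_size_range[2] <= n_targets &&
                regulon_size_range[1] <= regulon_size_range[2],
              "regulon_size_range must lie within [1, n_targets]")
  assert_that(overlap_blocks >= 1 && overlap_blocks <= n_tfs,
              "overlap_blocks must be in [1, n_tfs]")
  assert_that(frac_repressive >= 0 && frac_repressive <= 1, "frac_repressive in [0,1]")
  assert_that(n_subtypes * n_perturbed <= n_tfs,
              "not enough TFs for disjoint perturbed sets across subtypes")
  tf_ids <- sprintf("TF%03d", seq_len(n_tfs))
  target_ids <- sprintf("G%04d", seq_len(n_targets))
  with_seed(seed, {
    assert_that(n_tfs * regulon_size_range[2] <= n_targets * max_indegree,
                "max_indegree too small for the requested regulon sizes")
    tf_block <- sort(rep_len(seq_len(overlap_blocks), n_tfs))
    tgt_block <- sort(rep_len(seq_len(overlap_blocks), n_targets))
    indegree <- setNames(integer(n_targets), target_ids)
    regulons <- lapply(seq_len(n_tfs), function(i) {
      size <- sample(seq(regulon_size_range[1], regulon_size_range[2]), 1)
      open <- target_ids[indegree < max_indegree]
      pool <- intersect(target_ids[tgt_block == tf_block[i]], open)
      n_within <- min(round(within_block_rate * size), length(pool))
      within <- sample(pool, n_within)
      rest <- sample(setdiff(open, within), size - n_within)
      targets <- c(within, rest)
      indegree[targets] <<- indegree[targets] + 1L
      tibble::tibble(
        target = targets,
        mode = ifelse(runif(size) < frac_repressive, -1L, 1L),
        weight = runif(size, 1.0, 1.3)
      )
    })
    names(regulons) <- tf_ids
    perturbable <- sample(tf_ids)
    subtype_design <- lapply(seq_len(n_subtypes), function(s) {
      tfs <- perturbable[seq((s - 1) * n_perturbed + 1, s * n_perturbed)]
      tibble::tibble(tf = sort(tfs), delta = delta)
    })
    names(subtype_design) <- paste0("S", seq_len(n_subtypes))
    structure(list(
      tf_ids = tf_ids,
      target_ids = target_ids,
      gene_ids = c(target_ids, tf_ids),
      regulons = regulons,
      blocks = setNames(tf_block, tf_ids),
      subtype_design = subtype_design,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ), class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", length(x$tf_ids), " TFs, ", length(x$target_ids),
      " targets, ", length(x$subtype_design), " subtype(s), noise_sd = ",
      x$noise_sd, "\n", sep = "")
  invisible(x)
}

#' Planted master regulators of a subtype
#'
#' @param truth A `synthetic_truth` object.
#' @param subtype Subtype label (e.g. `"S1"`).
#' @return Character vector of perturbed TF ids.
#' @export
planted_mrs <- function(truth, subtype = "S1") {
  stopifnot(inherits(truth, "synthetic_truth"))
  design <- truth$subtype_design[[subtype]]
  if (is.null(design)) abort(paste0("unknown subtype '", subtype, "'"))
  design$tf
}

#' Convert planted truth to a regulatory network object
#'
#' Useful for benchmarking downstream stages (activity, topology, MRA) in
#' isolation from network inference: the edge "MI" is the generative weight
#' (a positive stand-in) and the mode is the true sign.
#'
#' @param truth A `synthetic_truth` object.
#' @return A `regulatory_network`.
#' @export
as_network <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  edges <- purrr::imap_dfr(truth$regulons, function(reg, tf) {
    tibble::tibble(tf = tf, target = reg$target, mi = reg$weight, mode = reg$mode)
  })
  new_network(edges, tf_ids = truth$tf_ids, universe = truth$gene_ids,
              dpi_tolerance = NA_real_)
}
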