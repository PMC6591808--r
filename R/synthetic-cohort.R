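# Linear-Gaussian expression cohorts on the log2 scale. Per sample, each TF
# has a latent activity a_t ~ Normal(mu, 1), with mu = delta for TFs
# perturbed in the sample's subtype and 0 otherwise. A target's expression is
# the signed weighted sum of its regulators' activities plus Normal(0,
# noise_sd) noise; a TF's own expression is a noisy readout of its activity
# (noise SD halved), which is what makes the planted network recoverable
# from expression alone. Values are shifted by +8 to a positive log2 scale.

#' Generate an expression cohort from planted truth
#'
#' @param truth A [generate_truth()] object.
#' @param n_per_group Named integer vector, group label -> sample count.
#'   Labels matching a subtype in `truth$subtype_design` receive that
#'   subtype's activity shifts; any other label (e.g. `"normal"`,
#'   `"cohort"`) is baseline.
#' @param seed Integer seed.
#' @param sample_prefix Prefix for generated sample ids (keeps id namespaces
#'   of independent cohorts disjoint).
#' @param baseline_shift Constant added to put values on a positive log2
#'   scale.
#' @return A `synthetic_bundle`: list with `expression` (genes x samples
#'   matrix), `phenotypes` (tibble sample_id/group), `activity` (true latent
#'   TF activity matrix, for benchmarking), and `truth`.
#' @export
generate_cohort <- function(truth, n_per_group, seed, sample_prefix = "",
                            baseline_shift = 8) {
  stopifnot(inherits(truth, "synthetic_truth"))
  assert_that(length(n_per_group) >= 1 && !is.null(names(n_per_group)) &&
                all(nzchar(names(n_per_group))),
              "n_per_group must be a named vector of sample counts")
  assert_that(all(n_per_group >= 1), "each group needs at least one sample")
  groups <- names(n_per_group)
  unknown <- setdiff(groups, c(names(truth$subtype_design), "normal", "cohort",
                               "baseline", "control"))
  if (length(unknown) > 0) {
    abort(paste0("unknown group(s) not in the subtype design and not a ",
                 "recognized baseline label: ", paste(unknown, collapse = ", ")))
  }
  n_tfs <- length(truth$tf_ids)
  n_targets <- length(truth$target_ids)
  sample_group <- rep(groups, times = n_per_group)
  n_samples <- length(sample_group)
  sample_ids <- sprintf("%sS%03d_%s", sample_prefix, seq_len(n_samples), sample_group)

  # Per-TF mean activity per group
  mu <- matrix(0, n_tfs, length(groups), dimnames = list(truth$tf_ids, groups))
  for (g in groups) {
    design <- truth$subtype_design[[g]]
    if (!is.null(design)) mu[design$tf, g] <- design$delta
  }

  with_seed(seed, {
    act <- matrix(rnorm(n_tfs * n_samples), n_tfs, n_samples,
                  dimnames = list(truth$tf_ids, sample_ids))
    act <- act + mu[, sample_group, drop = FALSE]
    # Signed weight matrix targets x TFs
    W <- matrix(0, n_targets, n_tfs, dimnames = list(truth$target_ids, truth$tf_ids))
    for (tf in truth$tf_ids) {
      reg <- truth$regulons[[tf]]
      W[reg$target, tf] <- W[reg$target, tf] + reg$mode * reg$weight
    }
    target_expr <- W %*% act +
      matrix(rnorm(n_targets * n_samples, sd = truth$noise_sd), n_targets, n_samples)
    tf_expr <- act +
      matrix(rnorm(n_tfs * n_samples, sd = 0.5 * truth$noise_sd), n_tfs, n_samples)
    expr <- rbind(target_expr, tf_expr) + baseline_shift
    rownames(expr) <- c(truth$target_ids, truth$tf_ids)
    colnames(expr) <- sample_ids
    structure(list(
      expression = expr,
      phenotypes = tibble::tibble(sample_id = sample_ids, group = sample_group),
      activity = act,
      truth = truth
    ), class = "synthetic_bundle")
  })
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  counts <- table(x$phenotypes$group)
  cat("<synthetic_bundle> ", nrow(x$expression), " genes x ", ncol(x$expression),
      " samples (", paste(names(counts), counts, sep = "=", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Generate independent discovery and validation cohorts
#'
#' Mirrors the asymmetric designs of a discovery analysis (tumor vs normal)
#' and an independent validation cohort (tumor vs other tumors): both share
#' the same planted truth but have independent samples and noise, with
#' disjoint sample id namespaces.
#'
#' @param truth A [generate_truth()] object with at least 2 subtypes.
#' @param seed Integer seed (the two cohorts use seeds derived from it).
#' @param n_normal,n_tumor Samples per group.
#' @return List with elements `discovery` (groups normal + S1) and
#'   `validation` (groups S1 + S2).
#' @export
generate_paired_cohorts <- function(truth, seed, n_normal = 10, n_tumor = 20) {
  stopifnot(inherits(truth, "synthetic_truth"))
  assert_that(length(truth$subtype_design) >= 2,
              "paired cohorts need at least 2 subtypes in the design")
  discovery <- generate_cohort(
    truth, c(normal = n_normal, S1 = n_tumor),
    seed = derive_seed(seed, 1), sample_prefix = "D"
  )
  validation <- generate_cohort(
    truth, c(S1 = n_tumor, S2 = n_tumor),
    seed = derive_seed(seed, 2), sample_prefix = "V"
  )
  list(discovery = discovery, validation = validation)
}

#' Generate a second-species cohort and ortholog map
#'
#' Builds a second gene universe with prefixed ids related to the first by a
#' one-to-one ortholog map covering `ortholog_fraction` of genes. A fraction
#' `conserved_tf_fraction` of each subtype's perturbed TFs is perturbed in
#' the second species with the same sign and magnitude; the remaining
#' perturbed slots are filled with other (species-specific) TFs so MR list
#' sizes stay comparable. Perturbed conserved TFs are always included in the
#' ortholog map.
#'
#' @param truth A [generate_truth()] object (species 1).
#' @param ortholog_fraction Fraction of genes covered by the ortholog map.
#' @param conserved_tf_fraction Fraction of perturbed TFs conserved.
#' @param seed Integer seed.
#' @param prefix Gene id prefix for the second species.
#' @param n_per_group Group design for the second-species cohort (defaults
#'   to a control vs S1 contrast, the cell-line style design).
#' @return List with `truth2`, `bundle2` (a `synthetic_bundle`), and
#'   `ortholog_map` (named character, species1 id -> species2 id).
#' @export
generate_cross_species <- function(truth, ortholog_fraction = 1,
                                   conserved_tf_fraction = 1, seed,
                                   prefix = "m_",
                                   n_per_group = c(control = 10, S1 = 20)) {
  stopifnot(inherits(truth, "synthetic_truth"))
  assert_that(ortholog_fraction >= 0 && ortholog_fraction <= 1,
              "ortholog_fraction in [0,1]")
  assert_that(conserved_tf_fraction >= 0 && conserved_tf_fraction <= 1,
              "conserved_tf_fraction in [0,1]")
  with_seed(seed, {
    map_full <- setNames(paste0(prefix, truth$gene_ids), truth$gene_ids)
    truth2 <- truth
    truth2$tf_ids <- unname(map_full[truth$tf_ids])
    truth2$target_ids <- unname(map_full[truth$target_ids])
    truth2$gene_ids <- c(truth2$target_ids, truth2$tf_ids)
    truth2$regulons <- lapply(truth$regulons, function(reg) {
      tibble::tibble(target = unname(map_full[reg$target]),
                     mode = reg$mode, weight = reg$weight)
    })
    names(truth2$regulons) <- truth2$tf_ids
    names(truth2$blocks) <- truth2$tf_ids

    conserved <- list()
    truth2$subtype_design <- lapply(truth$subtype_design, function(design) {
      n_keep <- round(conserved_tf_fraction * nrow(design))
      keep <- if (n_keep > 0) sort(sample(design$tf, n_keep)) else character(0)
      pool <- setdiff(truth$tf_ids, design$tf)
      swap <- if (nrow(design) - n_keep > 0) sample(pool, nrow(design) - n_keep) else character(0)
      conserved[[length(conserved) + 1]] <<- keep
      tibble::tibble(tf = unname(map_full[sort(c(keep, swap))]),
                     delta = design$delta[1])
    })
    names(truth2$subtype_design) <- names(truth$subtype_design)
    conserved_tfs <- unique(unlist(conserved))

    n_map <- round(ortholog_fraction * length(truth$gene_ids))
    must_keep <- conserved_tfs
    extra <- setdiff(truth$gene_ids, must_keep)
    n_extra <- max(0, n_map - length(must_keep))
    in_map <- c(must_keep, if (n_extra > 0) sample(extra, min(n_extra, length(extra))))
    ortholog_map <- map_full[sort(in_map)]

    bundle2 <- generate_cohort(truth2, n_per_group, seed = derive_seed(seed, 3),
                               sample_prefix = "X")
    list(truth2 = truth2, bundle2 = bundle2, ortholog_map = ortholog_map,
         conserved_tfs = conserved_tfs)
  })
}

#' Write a synthetic bundle's files to a directory
#'
#' Emits the expression TSV and phenotype TSV for a bundle, the fixture set
#' downstream file-based stages read.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @param stem File name stem.
#' @return Named character vector of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir, stem = "cohort") {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, paste0(stem, "_expression.tsv")),
    phenotypes = file.path(dir, paste0(stem, "_phenotypes.tsv"))
  )
  write_expression(bundle$expression, paths[["expression"]])
  readr::write_tsv(bundle$phenotypes, paths[["phenotypes"]], progress = FALSE)
  invisible(paths)
}
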