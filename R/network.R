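# Transcriptional network inference: pairwise TF-gene mutual information,
# a pooled permutation null for the retention threshold, mode of regulation
# from the sign of the Spearman correlation, and data processing inequality
# (DPI) pruning of the weakest edge in each triangle.

new_network <- function(edges, tf_ids, universe, dpi_tolerance = NA_real_) {
  structure(list(
    edges = tibble::as_tibble(edges),
    tf_ids = tf_ids,
    universe = universe,
    dpi_tolerance = dpi_tolerance
  ), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("<regulatory_network> ", nrow(x$edges), " edges, ", length(x$tf_ids),
      " TFs, universe ", length(x$universe), " genes",
      if (!is.na(x$dpi_tolerance)) paste0(", DPI tolerance ", x$dpi_tolerance),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.regulatory_network <- function(x, ...) x$edges

#' @export
glance.regulatory_network <- function(x, ...) {
  tibble::tibble(
    n_edges = nrow(x$edges),
    n_tfs = length(x$tf_ids),
    n_tfs_with_regulon = dplyr::n_distinct(x$edges$tf),
    universe_size = length(x$universe),
    median_regulon_size = if (nrow(x$edges) > 0)
      stats::median(table(x$edges$tf)) else NA_real_,
    dpi_tolerance = x$dpi_tolerance
  )
}

#' Regulon of a TF
#'
#' @param net A `regulatory_network`.
#' @param tf TF id.
#' @return Character vector of target gene ids (empty if none).
#' @export
regulon <- function(net, tf) {
  stopifnot(inherits(net, "regulatory_network"))
  net$edges$target[net$edges$tf == tf]
}

#' Regulons of all TFs
#'
#' @param net A `regulatory_network`.
#' @return Named list of character vectors, one per TF with >= 1 target.
#' @export
regulons <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  split(net$edges$target, net$edges$tf)
}

#' Permutation-null MI retention threshold
#'
#' Computes MI between each TF and sample-permuted target profiles, pools
#' the null values over `n_permutations` rounds, and returns the
#' (1 - alpha_perm) quantile.
#'
#' @param expr Genes x samples log2 expression matrix.
#' @param tf_ids TFs present in `expr`.
#' @param n_permutations Permutation rounds to pool (default 10).
#' @param alpha_perm Null tail probability (default 0.01).
#' @param n_bins MI bin count; default `floor(sqrt(n_samples))`.
#' @param seed Integer seed.
#' @return Threshold in nats (0 when `alpha_perm = 1`).
#' @export
mi_threshold <- function(expr, tf_ids, n_permutations = 10, alpha_perm = 0.01,
                         n_bins = NULL, seed = NULL) {
  validate_expression(expr)
  missing_tf <- setdiff(tf_ids, rownames(expr))
  if (length(missing_tf) > 0) {
    abort(paste0("TF(s) absent from expression matrix: ",
                 paste(missing_tf, collapse = ", ")))
  }
  assert_that(alpha_perm > 0 && alpha_perm <= 1, "alpha_perm in (0,1]")
  if (alpha_perm == 1) return(0)
  n <- ncol(expr)
  n_bins <- n_bins %||% floor(sqrt(n))
  binned <- binned_matrix(expr, n_bins)
  target_rows <- setdiff(rownames(expr), tf_ids)
  with_seed(seed, {
    null_mi <- unlist(lapply(seq_len(n_permutations), function(r) {
      perm <- sample.int(n)
      gb <- binned$bins[target_rows, perm, drop = FALSE]
      const <- binned$constant[target_rows]
      unlist(lapply(tf_ids, function(tf) {
        mi_batch(binned$bins[tf, ], gb, n_bins, constant = const)
      }))
    }))
    unname(quantile(null_mi, 1 - alpha_perm, type = 7))
  })
}

binned_matrix <- function(expr, n_bins) {
  bins <- t(apply(expr, 1, ef_bins, n_bins = n_bins))
  constant <- apply(expr, 1, sd) == 0
  list(bins = bins, constant = constant)
}

#' Infer a TF -> target network by mutual information
#'
#' Retains edge (tf, g) iff MI(tf, g) >= threshold and g != tf; the mode of
#' regulation is the sign of the Spearman correlation between the TF and the
#' target (+1 on ties). The result is an un-pruned (pre-DPI) network; apply
#' [apply_dpi()] to remove likely-indirect edges.
#'
#' @inheritParams mi_threshold
#' @param threshold MI retention threshold in nats; `NULL` computes it via
#'   [mi_threshold()] with the given permutation parameters.
#' @return A `regulatory_network` with edge MI and mode, universe = all
#'   genes scored.
#' @export
infer_network <- function(expr, tf_ids, threshold = NULL, n_permutations = 10,
                          alpha_perm = 0.01, n_bins = NULL, seed = NULL) {
  validate_expression(expr)
  missing_tf <- setdiff(tf_ids, rownames(expr))
  if (length(missing_tf) > 0) {
    abort(paste0("TF(s) absent from expression matrix: ",
                 paste(missing_tf, collapse = ", ")))
  }
  n <- ncol(expr)
  assert_that(n >= 8, "need at least 8 samples")
  n_bins <- n_bins %||% floor(sqrt(n))
  if (is.null(threshold)) {
    threshold <- mi_threshold(expr, tf_ids, n_permutations, alpha_perm,
                              n_bins, seed = seed)
  }
  binned <- binned_matrix(expr, n_bins)
  genes <- rownames(expr)
  rank_mat <- t(apply(expr, 1, rank))   # for Spearman signs
  edges <- purrr::map_dfr(tf_ids, function(tf) {
    mi <- mi_batch(binned$bins[tf, ], binned$bins, n_bins,
                   constant = binned$constant)
    keep <- which(mi >= threshold & genes != tf)
    if (length(keep) == 0) {
      return(tibble::tibble(tf = character(), target = character(),
                            mi = numeric(), mode = integer()))
    }
    rho <- suppressWarnings(
      cor(rank_mat[tf, ], t(rank_mat[keep, , drop = FALSE]))[1, ]
    )
    rho[is.na(rho)] <- 0
    tibble::tibble(tf = tf, target = genes[keep], mi = mi[keep],
                   mode = ifelse(rho < 0, -1L, 1L))
  })
  net <- new_network(edges, tf_ids = tf_ids, universe = genes)
  attr(net, "threshold") <- threshold
  net
}

#' Data processing inequality pruning
#'
#' For every triangle of retained edges (a,b), (a,c), (b,c) — TF-TF-target
#' or TF-TF-TF — an edge is marked for removal when its MI is below
#' `min(other two) * (1 - tolerance)`. All marked edges are removed
#' simultaneously after scanning every triangle, so the result does not
#' depend on scan order. TF-TF edges present in both directions are treated
#' as one undirected interaction and removed together.
#'
#' @param net A `regulatory_network`.
#' @param tolerance DPI tolerance in [0, 1); 0 is the stringent setting,
#'   0.05 the sensitivity-enhancing one.
#' @return The pruned `regulatory_network` with `dpi_tolerance` recorded.
#' @export
apply_dpi <- function(net, tolerance = 0) {
  stopifnot(inherits(net, "regulatory_network"))
  assert_that(is.numeric(tolerance) && tolerance >= 0 && tolerance < 1,
              "tolerance must be in [0, 1)")
  edges <- net$edges
  if (nrow(edges) == 0) {
    net$dpi_tolerance <- tolerance
    return(net)
  }
  # Undirected edge table keyed by unordered node pair; MI is symmetric so
  # duplicated TF-TF directions carry the same weight.
  key <- ifelse(edges$tf < edges$target,
                paste(edges$tf, edges$target, sep = "\r"),
                paste(edges$target, edges$tf, sep = "\r"))
  und <- tibble::tibble(key = key, mi = edges$mi)
  und <- und[!duplicated(und$key), ]
  parts <- strsplit(und$key, "\r", fixed = TRUE)
  u_a <- vapply(parts, `[`, character(1), 1)
  u_b <- vapply(parts, `[`, character(1), 2)
  mi_of <- setNames(und$mi, und$key)

  # Neighbors per node over undirected edges
  nbr <- split(c(u_b, u_a), c(u_a, u_b))
  tf_set <- intersect(net$tf_ids, names(nbr))
  drop_keys <- character(0)
  seen_pairs <- character(0)
  for (a in tf_set) {
    bs <- intersect(nbr[[a]], tf_set)
    for (b in bs) {
      if (a >= b) next
      pair_key <- paste(a, b, sep = "\r")
      common <- intersect(nbr[[a]], nbr[[b]])
      for (cc in common) {
        k_ab <- pair_key
        k_ac <- if (a < cc) paste(a, cc, sep = "\r") else paste(cc, a, sep = "\r")
        k_bc <- if (b < cc) paste(b, cc, sep = "\r") else paste(cc, b, sep = "\r")
        mis <- c(mi_of[[k_ab]], mi_of[[k_ac]], mi_of[[k_bc]])
        keys <- c(k_ab, k_ac, k_bc)
        for (e in 1:3) {
          if (mis[e] < min(mis[-e]) * (1 - tolerance)) {
            drop_keys <- c(drop_keys, keys[e])
          }
        }
      }
    }
  }
  drop_keys <- unique(drop_keys)
  keep <- !(key %in% drop_keys)
  out <- new_network(edges[keep, , drop = FALSE], tf_ids = net$tf_ids,
                     universe = net$universe, dpi_tolerance = tolerance)
  attr(out, "n_removed") <- sum(!keep)
  out
}
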