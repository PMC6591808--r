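# Shared fixtures, built once per test run. Sizes are kept small for module
# tests; the acceptance tests build the full-size default bundle themselves.

fixture_env <- new.env(parent = emptyenv())

# Small planted truth: 20 TFs, 120 targets, feasible under the in-degree cap.
small_truth <- function() {
  if (is.null(fixture_env$truth)) {
    fixture_env$truth <- generate_truth(
      seed = 42, n_tfs = 20, n_targets = 120,
      regulon_size_range = c(5, 10), overlap_blocks = 2
    )
  }
  fixture_env$truth
}

small_pair <- function() {
  if (is.null(fixture_env$pair)) {
    fixture_env$pair <- generate_paired_cohorts(small_truth(), seed = 7)
  }
  fixture_env$pair
}

small_signature <- function() {
  if (is.null(fixture_env$sig)) {
    pair <- small_pair()
    fixture_env$sig <- differential_signature(
      pair$discovery$expression, pair$discovery$phenotypes, "S1", "normal"
    )
  }
  fixture_env$sig
}

# Random regulatory network over a handful of nodes, for DPI oracle tests.
random_test_network <- function(seed, n_tfs = 6, n_targets = 10,
                                p_edge = 0.35) {
  set.seed(seed)
  tfs <- paste0("t", seq_len(n_tfs))
  targets <- paste0("g", seq_len(n_targets))
  edges <- list()
  for (a in tfs) {
    for (b in c(setdiff(tfs, a), targets)) {
      if (a < b || b %in% targets) {   # one direction per TF pair
        if (runif(1) < p_edge) {
          edges[[length(edges) + 1]] <- tibble::tibble(
            tf = a, target = b, mi = runif(1), mode = sample(c(-1L, 1L), 1)
          )
        }
      }
    }
  }
  net <- regulonmra:::new_network(dplyr::bind_rows(edges), tf_ids = tfs,
                                  universe = c(targets, tfs))
  net
}

# Exhaustive DPI oracle: enumerate every node triple, require all three
# undirected edges, mark the rule violations, remove simultaneously.
dpi_oracle <- function(net, tolerance) {
  edges <- net$edges
  ukey <- function(a, b) ifelse(a < b, paste(a, b), paste(b, a))
  key <- ukey(edges$tf, edges$target)
  mi_of <- tapply(edges$mi, key, max)
  nodes <- unique(c(edges$tf, edges$target))
  drop <- character(0)
  if (length(nodes) >= 3) {
    combs <- utils::combn(sort(nodes), 3)
    for (i in seq_len(ncol(combs))) {
      a <- combs[1, i]; b <- combs[2, i]; cc <- combs[3, i]
      ks <- c(ukey(a, b), ukey(a, cc), ukey(b, cc))
      if (!all(ks %in% names(mi_of))) next
      mis <- unname(mi_of[ks])
      for (e in 1:3) {
        if (mis[e] < min(mis[-e]) * (1 - tolerance)) drop <- c(drop, ks[e])
      }
    }
  }
  edges[!(key %in% drop), , drop = FALSE]
}

# Direct log-space hypergeometric upper-tail summation (independent of
# stats::phyper), for oracle comparisons.
hyper_tail_oracle <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

expect_no_error <- function(expr) expect_error(expr, NA)
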