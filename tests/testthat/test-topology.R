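block_network <- function() {
  # two planted blocks with zero between-block overlap
  edges <- tibble::tibble(
    tf = rep(c("A1", "A2", "A3", "B1", "B2"), each = 4),
    target = c("x1", "x2", "x3", "x4",
               "x1", "x2", "x3", "x5",
               "x2", "x3", "x4", "x5",
               "y1", "y2", "y3", "y4",
               "y1", "y2", "y4", "y5"),
    mi = 1, mode = 1L
  )
  regulonmra:::new_network(edges, tf_ids = unique(edges$tf),
                           universe = unique(c(edges$tf, edges$target)))
}

test_that("regulon overlap is exact Jaccard with unit diagonal", {
  edges <- tibble::tibble(
    tf = c(rep("T1", 3), rep("T2", 3), rep("T3", 2)),
    target = c("a", "b", "c", "b", "c", "d", "e", "f"),
    mi = 1, mode = 1L
  )
  net <- regulonmra:::new_network(edges, tf_ids = c("T1", "T2", "T3"),
                                  universe = letters[1:6])
  ov <- regulon_overlap_matrix(net)
  expect_equal(unname(diag(unclass(ov))), rep(1, 3))
  expect_equal(ov["T1", "T2"], 0.5)   # {a,b,c} vs {b,c,d}
  expect_equal(ov["T1", "T3"], 0)
  expect_identical(unclass(ov), t(unclass(ov)))
  # J = 1 implies identical regulons
  expect_true(all(ov[ov == 1] == 1 & row(ov)[ov == 1] == col(ov)[ov == 1]))
})

test_that("TFs with empty regulons are excluded with a warning", {
  edges <- tibble::tibble(tf = "T1", target = c("a", "b"), mi = 1, mode = 1L)
  net <- regulonmra:::new_network(edges, tf_ids = c("T1", "T2"),
                                  universe = c("a", "b"))
  expect_warning(ov <- regulon_overlap_matrix(net), "empty regulons")
  expect_identical(rownames(ov), "T1")
})

test_that("clustering recovers planted blocks and respects permutations", {
  net <- block_network()
  ov <- regulon_overlap_matrix(net)
  labels <- cluster_subnetworks(ov, k = 2)
  by_block <- split(labels$subnetwork, substr(labels$tf, 1, 1))
  expect_length(unique(by_block$A), 1)
  expect_length(unique(by_block$B), 1)
  expect_false(by_block$A[1] == by_block$B[1])

  singletons <- cluster_subnetworks(ov, k = nrow(ov))
  expect_length(unique(singletons$subnetwork), nrow(ov))

  # permuting the TF order changes nothing about the partition
  perm <- c(4, 2, 5, 1, 3)
  ov_perm <- structure(unclass(ov)[perm, perm], class = class(ov),
                       metric = attr(ov, "metric"))
  lab_perm <- cluster_subnetworks(ov_perm, k = 2)
  merged <- dplyr::inner_join(labels, lab_perm, by = "tf")
  tab <- table(merged$subnetwork.x, merged$subnetwork.y)
  expect_equal(sum(tab > 0), 2)   # one-to-one label correspondence
})

test_that("the overlap-coefficient metric is available behind the flag", {
  edges <- tibble::tibble(
    tf = c(rep("T1", 4), rep("T2", 2)),
    target = c("a", "b", "c", "d", "a", "b"),
    mi = 1, mode = 1L
  )
  net <- regulonmra:::new_network(edges, tf_ids = c("T1", "T2"),
                                  universe = letters[1:4])
  ov <- regulon_overlap_matrix(net, metric = "overlap")
  expect_equal(ov["T1", "T2"], 1)   # {a,b} fully inside {a,b,c,d}
})

test_that("synergy calls reproduce the worked rule evaluations", {
  expect_identical(regulonmra:::classify_synergy(-0.5, -0.4, -1.2, 10, 5, 0.2),
                   "synergistic_repression")
  expect_identical(regulonmra:::classify_synergy(-0.2, 1.0, 0.1, 10, 5, 0.2),
                   "attenuation")
  expect_identical(regulonmra:::classify_synergy(0, 0, 0, 10, 5, 0.2), "none")
  expect_identical(regulonmra:::classify_synergy(0.3, 0.4, 1.1, 10, 5, 0.2),
                   "synergistic_activation")
  expect_identical(regulonmra:::classify_synergy(-0.5, -0.4, -1.2, 3, 5, 0.2),
                   "none")   # below min_shared
})

test_that("synergy calls are mutually exclusive on random mean triples", {
  set.seed(3)
  for (i in 1:200) {
    m <- stats::runif(3, -2, 2)
    call <- regulonmra:::classify_synergy(m[1], m[2], m[3], 10, 5, 0.2)
    n_rules <- sum(
      m[3] < min(m[1], m[2]) - 0.2 && m[3] < 0,
      m[3] > max(m[1], m[2]) + 0.2 && m[3] > 0,
      m[2] > 0.2 && m[3] < m[2] - 0.2 && m[3] > -0.2
    )
    if (n_rules == 0) expect_identical(call, "none")
    if (n_rules >= 1) expect_false(call == "none")
  }
})

test_that("a planted co-repressed shared-target pair is called synergistic repression", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    shared <- sprintf("s%02d", 1:8)
    only_a <- sprintf("a%02d", 1:8)
    only_b <- sprintf("b%02d", 1:8)
    edges <- tibble::tibble(
      tf = rep(c("TFA", "TFB"), each = 16),
      target = c(shared, only_a, shared, only_b),
      mi = 1, mode = 1L
    )
    net <- regulonmra:::new_network(edges, tf_ids = c("TFA", "TFB"),
                                    universe = c(shared, only_a, only_b))
    sig <- tibble::tibble(
      gene_id = c(shared, only_a, only_b),
      log2fc = c(rnorm(8, -2.5, 0.3), rnorm(8, -0.5, 0.3), rnorm(8, -0.4, 0.3))
    )
    calls <- synergy_analysis(net, sig, "TFA")
    calls$call[calls$tf_b == "TFB"] == "synergistic_repression"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("synergy analysis rejects an absent focal TF", {
  net <- block_network()
  sig <- tibble::tibble(gene_id = net$universe, log2fc = 0)
  expect_error(synergy_analysis(net, sig, "NOPE"), "NOPE")
})
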