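test_that("truth generation is deterministic and respects mode settings", {
  t1 <- generate_truth(seed = 5, n_tfs = 10, n_targets = 60,
                       regulon_size_range = c(4, 8))
  t2 <- generate_truth(seed = 5, n_tfs = 10, n_targets = 60,
                       regulon_size_range = c(4, 8))
  expect_identical(t1, t2)

  t3 <- generate_truth(seed = 5, n_tfs = 10, n_targets = 60,
                       regulon_size_range = c(4, 8), frac_repressive = 0)
  expect_true(all(unlist(lapply(t3$regulons, `[[`, "mode")) == 1L))
  expect_true(all(unlist(lapply(t1$regulons, `[[`, "weight")) > 0))
  expect_error(generate_truth(seed = 1, n_tfs = 10, n_targets = 5,
                              regulon_size_range = c(2, 30)),
               "regulon_size_range")
})

test_that("block structure yields higher within-block regulon overlap", {
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  within <- between <- numeric(0)
  for (s in 1:15) {
    tr <- generate_truth(seed = s, n_tfs = 12, n_targets = 120,
                         regulon_size_range = c(8, 12), overlap_blocks = 2)
    regs <- lapply(tr$regulons, `[[`, "target")
    for (i in seq_along(regs)) for (j in seq_len(i - 1)) {
      v <- jacc(regs[[i]], regs[[j]])
      if (tr$blocks[i] == tr$blocks[j]) within <- c(within, v)
      else between <- c(between, v)
    }
  }
  expect_gt(mean(within), mean(between))
})

test_that("cohorts are deterministic, group-structured, and null when delta = 0", {
  truth <- small_truth()
  b1 <- generate_cohort(truth, c(normal = 5, S1 = 7), seed = 3)
  b2 <- generate_cohort(truth, c(normal = 5, S1 = 7), seed = 3)
  expect_identical(b1$expression, b2$expression)
  expect_identical(table(b1$phenotypes$group)[["S1"]], 7L)
  expect_error(generate_cohort(truth, c(whatgroup = 5), seed = 1), "unknown group")

  # delta = 0: two-group t-tests flag about alpha * n_genes genes
  t0 <- generate_truth(seed = 9, n_tfs = 20, n_targets = 120,
                       regulon_size_range = c(5, 10), delta = 0)
  n_flagged <- vapply(1:5, function(s) {
    b <- generate_cohort(t0, c(normal = 10, S1 = 10), seed = s)
    p <- apply(b$expression, 1, function(x) stats::t.test(x[1:10], x[11:20])$p.value)
    sum(p < 0.05)
  }, numeric(1))
  expect_lte(mean(n_flagged), 1.5 * 0.05 * nrow(b1$expression))
})

test_that("positive-mode targets of a perturbed TF shift upward", {
  hits <- vapply(1:5, function(s) {
    tr <- generate_truth(seed = s, n_tfs = 20, n_targets = 120,
                         regulon_size_range = c(5, 10))
    b <- generate_cohort(tr, c(normal = 10, S1 = 10), seed = s + 20)
    mr <- planted_mrs(tr, "S1")[1]
    reg <- tr$regulons[[mr]]
    up_targets <- reg$target[reg$mode == 1L]
    grp <- b$phenotypes$group
    lfc <- rowMeans(b$expression[up_targets, grp == "S1", drop = FALSE]) -
      rowMeans(b$expression[up_targets, grp == "normal", drop = FALSE])
    all(lfc > 0)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("paired cohorts are independent, disjoint, and sign-consistent", {
  truth <- small_truth()
  pair <- generate_paired_cohorts(truth, seed = 11)
  expect_length(intersect(colnames(pair$discovery$expression),
                          colnames(pair$validation$expression)), 0)
  expect_false(identical(pair$discovery$expression[, 1],
                         pair$validation$expression[, 1]))
  sigD <- differential_signature(pair$discovery$expression,
                                 pair$discovery$phenotypes, "S1", "normal")
  sigV <- differential_signature(pair$validation$expression,
                                 pair$validation$phenotypes, "S1", "S2")
  net <- as_network(truth)
  mrs <- planted_mrs(truth, "S1")
  fcD <- regulon_fold_change(net, sigD, mrs)
  fcV <- regulon_fold_change(net, sigV, mrs)
  agree <- sign(fcD$mean_lfc) == sign(fcV$mean_lfc)
  expect_gte(mean(agree), 0.8)
})

test_that("cross-species generation honors the ortholog and conservation dials", {
  truth <- small_truth()
  full <- generate_cross_species(truth, ortholog_fraction = 1,
                                 conserved_tf_fraction = 1, seed = 4)
  expect_length(full$ortholog_map, length(truth$gene_ids))
  mapped <- unname(full$ortholog_map[planted_mrs(truth, "S1")])
  expect_setequal(mapped, planted_mrs(full$truth2, "S1"))

  none <- generate_cross_species(truth, conserved_tf_fraction = 0, seed = 4)
  mapped0 <- unname(none$ortholog_map[planted_mrs(truth, "S1")])
  expect_length(intersect(mapped0, planted_mrs(none$truth2, "S1")), 0)

  again <- generate_cross_species(truth, conserved_tf_fraction = 0, seed = 4)
  expect_identical(none$bundle2$expression, again$bundle2$expression)
  expect_identical(none$ortholog_map, again$ortholog_map)
})

test_that("promoter fixtures plant instances as configured", {
  truth <- small_truth()
  tf <- planted_mrs(truth, "S1")[1]
  pwm <- make_test_pwm("m", length = 8, seed = 2)
  pw_set <- setNames(list(pwm), tf)

  always <- generate_promoters(truth, pw_set, window_bp = 2000, plant_rate = 1,
                               plant_max_dist = 0, seed = 3)
  consensus <- regulonmra:::pwm_consensus(pwm)
  tssoff <- 1000
  for (g in always$planted$gene) {
    start <- tssoff - (8 - 1) %/% 2
    expect_identical(substr(always$sequences[[g]], start + 1, start + 8), consensus)
  }
  expect_identical(nrow(always$planted), nrow(truth$regulons[[tf]]))

  never <- generate_promoters(truth, pw_set, window_bp = 2000, plant_rate = 0,
                              plant_max_dist = 0, seed = 3)
  expect_identical(nrow(never$planted), 0L)
})

test_that("promoter background composition is near-uniform", {
  truth <- small_truth()
  tf <- planted_mrs(truth, "S1")[1]
  pwm <- make_test_pwm("m", length = 8, seed = 2)
  prom <- generate_promoters(truth, setNames(list(pwm), tf), window_bp = 5000,
                             plant_rate = 0, seed = 6,
                             genes = truth$target_ids[1:40])
  gc <- vapply(prom$sequences, function(s) {
    mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  }, numeric(1))
  expect_lt(abs(mean(gc) - 0.5), 0.02)
})

test_that("generated bundles survive a write/read cycle intact", {
  truth <- small_truth()
  b <- generate_cohort(truth, c(normal = 4, S1 = 4), seed = 8)
  dir <- withr::local_tempdir()
  paths <- write_bundle(b, dir)
  expr <- read_expression(paths[["expression"]])
  expect_lt(max(abs(expr - b$expression)), 1e-9)
  ph <- read_phenotypes(paths[["phenotypes"]])
  expect_identical(ph$sample_id, b$phenotypes$sample_id)
})
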