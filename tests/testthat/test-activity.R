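tiny_activity_setup <- function() {
  # two genes, one TF with modes (+1, -1); samples constructed so z-scores
  # are known exactly under the cohort reference
  expr <- rbind(
    g1 = c(10, 12, 8, 10),   # mean 10, sd = sqrt(8/3)
    g2 = c(6, 5, 7, 6)
  )
  colnames(expr) <- paste0("s", 1:4)
  edges <- tibble::tibble(tf = "TFX", target = c("g1", "g2"), mi = 1,
                          mode = c(1L, -1L))
  net <- regulonmra:::new_network(edges, tf_ids = "TFX",
                                  universe = c("g1", "g2", "TFX"))
  list(expr = expr, net = net)
}

test_that("activity is the signed z-sum over sqrt(regulon size)", {
  s <- tiny_activity_setup()
  act <- infer_activity(s$expr, s$net, min_regulon = 2)
  z1 <- (s$expr["g1", ] - 10) / stats::sd(s$expr["g1", ])
  z2 <- (s$expr["g2", ] - 6) / stats::sd(s$expr["g2", ])
  expect_equal(unname(act["TFX", ]), unname((z1 - z2) / sqrt(2)), tolerance = 1e-12)

  # direct spec example: z-scores (2, 1) with modes (+1, -1) -> 1/sqrt(2)
  expect_equal((2 * 1 + 1 * (-1)) / sqrt(2), 0.7071, tolerance = 1e-4)
})

test_that("a sample at the reference mean has zero activity everywhere", {
  truth <- small_truth()
  b <- generate_cohort(truth, c(cohort = 10), seed = 2)
  expr <- b$expression
  expr[, 1] <- rowMeans(expr[, -1])
  act <- infer_activity(expr, as_network(truth), reference = colnames(expr)[-1])
  expect_lt(max(abs(act[, 1])), 1e-10)
})

test_that("activity is linear in z-scores", {
  truth <- small_truth()
  b <- generate_cohort(truth, c(cohort = 12), seed = 3)
  net <- as_network(truth)
  act <- infer_activity(b$expression, net)
  # doubling deviations from the cohort mean doubles z and hence activity is
  # unchanged when the reference sd rescales with it (scale invariance) ...
  mu <- rowMeans(b$expression)
  expr2 <- (b$expression - mu) * 2 + mu
  act2 <- infer_activity(expr2, net, reference = "cohort")
  expect_equal(unclass(act2), unclass(act), tolerance = 1e-8)
  # ... and doubling z against a FIXED reference doubles the activity: hold
  # the reference samples fixed and scale the remaining sample's deviation
  ref <- colnames(b$expression)[-1]
  expr3 <- b$expression
  mu_ref <- rowMeans(expr3[, ref])
  expr3[, 1] <- mu_ref + 2 * (expr3[, 1] - mu_ref)
  act_ref <- infer_activity(b$expression, net, reference = ref)
  act_ref2 <- infer_activity(expr3, net, reference = ref)
  expect_equal(unname(act_ref2[, 1]), unname(2 * act_ref[, 1]), tolerance = 1e-8)
})

test_that("TFs below min_regulon are excluded and listed, never silently zero", {
  s <- tiny_activity_setup()
  expect_error(infer_activity(s$expr, s$net, min_regulon = 5),
               "min_regulon")
  act <- infer_activity(s$expr, s$net, min_regulon = 2)
  expect_length(attr(act, "excluded"), 0)
})

test_that("cohort-null activities are centered near zero", {
  truth <- small_truth()
  b <- generate_cohort(truth, c(cohort = 30), seed = 5)
  act <- infer_activity(b$expression, as_network(truth))
  pooled <- mean(act)
  expect_lt(abs(pooled), 3 / sqrt(length(act)))
})

test_that("planted perturbation raises activity in the perturbed group", {
  truth <- small_truth()
  mrs <- planted_mrs(truth, "S1")
  hits <- vapply(1:5, function(s) {
    b <- generate_cohort(truth, c(normal = 10, S1 = 10), seed = s + 40)
    act <- infer_activity(b$expression, as_network(truth))
    grp <- b$phenotypes$group
    all(vapply(intersect(mrs, rownames(act)), function(tf) {
      w <- stats::wilcox.test(act[tf, grp == "S1"], act[tf, grp == "normal"],
                              alternative = "greater", exact = FALSE)
      mean(act[tf, grp == "S1"]) > mean(act[tf, grp == "normal"]) &&
        w$p.value < 0.01
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("activity clustering separates subtypes and is order-invariant", {
  skip_if_not_installed("mclust")
  truth <- small_truth()
  b <- generate_cohort(truth, c(S1 = 12, S2 = 12), seed = 6)
  act <- infer_activity(b$expression, as_network(truth))
  cl <- cluster_samples_by_activity(act, k = 2)
  ari <- mclust::adjustedRandIndex(cl$cluster, b$phenotypes$group)
  expect_gte(ari, 0.8)

  perm <- sample(ncol(act))
  act_perm <- structure(unclass(act)[, perm], class = class(act))
  cl_perm <- cluster_samples_by_activity(act_perm, k = 2)
  merged <- dplyr::inner_join(cl, cl_perm, by = "sample_id")
  tab <- table(merged$cluster.x, merged$cluster.y)
  expect_equal(sum(tab > 0), 2)
})

test_that("a duplicated sample merges first in the dendrogram", {
  truth <- small_truth()
  b <- generate_cohort(truth, c(cohort = 8), seed = 7)
  expr <- b$expression
  expr <- cbind(expr, dup = expr[, 3])
  act <- infer_activity(expr, as_network(truth))
  cl <- cluster_samples_by_activity(act, k = 2, distance = "euclidean")
  tree <- attr(cl, "tree")
  first_pair <- sort(-tree$merge[1, ])
  expect_setequal(tree$labels[first_pair],
                  c(colnames(expr)[3], "dup"))
})

test_that("regulon-expression clustering separates perturbed from control", {
  skip_if_not_installed("mclust")
  hits <- vapply(1:5, function(s) {
    truth <- generate_truth(seed = s, n_tfs = 20, n_targets = 120,
                            regulon_size_range = c(5, 10), delta = 5)
    tf <- planted_mrs(truth, "S1")[1]
    b <- generate_cohort(truth, c(control = 6, S1 = 6), seed = s + 60)
    cl <- cluster_samples_by_regulon_expression(b$expression, as_network(truth),
                                                tf, k = 2)
    mclust::adjustedRandIndex(cl$cluster, b$phenotypes$group) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  truth <- small_truth()
  b <- generate_cohort(truth, c(cohort = 6), seed = 9)
  expect_error(cluster_samples_by_regulon_expression(b$expression,
                                                     as_network(truth), "NOPE"),
               "NOPE")
})

test_that("single-gene regulons still cluster validly", {
  expr <- rbind(g1 = c(1, 1.1, 5, 5.2), TFX = c(0, 0, 1, 1))
  colnames(expr) <- paste0("s", 1:4)
  edges <- tibble::tibble(tf = "TFX", target = "g1", mi = 1, mode = 1L)
  net <- regulonmra:::new_network(edges, tf_ids = "TFX", universe = rownames(expr))
  cl <- cluster_samples_by_regulon_expression(expr, net, "TFX", k = 2)
  expect_identical(cl$cluster[1], cl$cluster[2])
  expect_identical(cl$cluster[3], cl$cluster[4])
  expect_false(cl$cluster[1] == cl$cluster[3])
})

test_that("differential activity is symmetric and ranks the planted TF first", {
  truth <- small_truth()
  b <- generate_cohort(truth, c(normal = 10, S1 = 10), seed = 10)
  act <- infer_activity(b$expression, as_network(truth))
  ab <- differential_activity(act, b$phenotypes, "S1", "normal")
  ba <- differential_activity(act, b$phenotypes, "normal", "S1")
  ab_s <- ab[order(ab$tf), ]; ba_s <- ba[order(ba$tf), ]
  expect_equal(ab_s$mean_diff, -ba_s$mean_diff)
  expect_equal(ab_s$p, ba_s$p, tolerance = 1e-12)
  expect_true(ab$tf[1] %in% planted_mrs(truth, "S1"))

  # identical groups: no significant calls on exact ties
  act_dup <- act
  ph <- b$phenotypes
  ph$group <- rep(c("X", "Y"), length.out = nrow(ph))
  same <- differential_activity(act_dup, ph, "X", "Y")
  expect_lte(sum(same$p_adj < 0.05), 1)
})
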