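# Brute-force both-strand log-odds scanner used as the oracle for pwm_scan.
brute_scan <- function(sequence, pwm, threshold_frac = 0.8, pseudocount = 1e-3) {
  sequence <- toupper(sequence)
  sm <- regulonmra:::pwm_score_matrix(pwm, pseudocount)
  L <- ncol(sm)
  threshold <- threshold_frac * sum(apply(sm, 2, max))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(sequence, "")[[1]]
  hits <- list()
  for (pos in 0:(nchar(sequence) - L)) {
    win <- chars[(pos + 1):(pos + L)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    base_idx <- c(A = 1, C = 2, G = 3, T = 4)
    fwd <- sum(sm[cbind(base_idx[win], 1:L)])
    rc <- rev(unname(comp[win]))
    rev_score <- sum(sm[cbind(base_idx[rc], 1:L)])
    best <- max(fwd, rev_score)
    if (best >= threshold) {
      hits[[length(hits) + 1]] <- tibble::tibble(
        position = pos, strand = if (fwd >= rev_score) "+" else "-",
        score = best
      )
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(position = integer(), strand = character(),
                          score = numeric()))
  }
  dplyr::bind_rows(hits)
}

test_that("a deterministic consensus PWM finds its single planted site", {
  pwm <- regulonmra:::new_pwm("cons", matrix(c(1, 0, 0, 0, 0, 1, 0, 0,
                                               0, 0, 1, 0, 0, 0, 0, 1), 4))
  hits <- pwm_scan("TTACGTTT", pwm)
  expect_identical(hits$position, 2L)
  # reverse complement of ACGT is ACGT: palindromic, deduplicated to one row
  expect_identical(nrow(hits), 1L)
})

test_that("impossible consensus yields no matches; empty input rejected", {
  pwm <- regulonmra:::new_pwm("needsA", matrix(c(1, 0, 0, 0), 4, 3))
  expect_identical(nrow(pwm_scan("TTGGTTGGTT", pwm)), 0L)
  expect_error(pwm_scan("", pwm), "non-empty")
  expect_error(pwm_scan("AC", pwm), "shorter")
})

test_that("pwm_scan agrees with the brute-force both-strand oracle", {
  set.seed(21)
  for (i in 1:8) {
    pwm <- make_test_pwm(paste0("m", i), length = 6, sharp = 0.8, seed = i)
    seq <- paste0(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    got <- pwm_scan(seq, pwm, threshold_frac = 0.7)
    want <- brute_scan(seq, pwm, threshold_frac = 0.7)
    expect_identical(got$position, as.integer(want$position))
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("scanning is case-insensitive and skips N windows", {
  pwm <- make_test_pwm("m", length = 6, seed = 4)
  cons <- regulonmra:::pwm_consensus(pwm)
  seq <- paste0("TTTT", tolower(cons), "TTTT")
  hits <- pwm_scan(seq, pwm)
  expect_identical(hits$position, 4L)
  seq_n <- paste0("TTTT", sub("^.", "N", cons), "TTTT")
  expect_identical(nrow(pwm_scan(seq_n, pwm)), 0L)
})

test_that("nearest-match distances and the proximal fraction follow planting", {
  truth <- small_truth()
  tf <- planted_mrs(truth, "S1")[1]
  pwm <- make_test_pwm("m", seed = 2)
  prom <- generate_promoters(truth, setNames(list(pwm), tf), window_bp = 4000,
                             plant_rate = 1, plant_max_dist = 0, seed = 3)
  res <- nearest_match_fraction(truth$regulons[[tf]]$target, prom$sequences,
                                prom$tss, pwm, proximal = 100)
  expect_true(all(res$distances$distance <= 1))   # centered instance
  expect_equal(res$f_obs, 1)

  # genes without promoters are warned about and skipped
  expect_warning(
    res2 <- nearest_match_fraction(c(truth$regulons[[tf]]$target, "ghost"),
                                   prom$sequences, prom$tss, pwm),
    "without promoter"
  )
  expect_identical(res2$n_missing_promoter, 1L)

  # a decoy PWM finds nothing: undefined fraction, flagged
  decoy <- make_test_pwm("decoy", seed = 9)
  res3 <- nearest_match_fraction(truth$regulons[[tf]]$target, prom$sequences,
                                 prom$tss, decoy)
  expect_true(is.na(res3$f_obs))
  expect_identical(res3$n_no_match, nrow(res3$distances))
})

test_that("column scrambling preserves the column multiset", {
  pwm <- make_test_pwm("m", length = 10, seed = 5)
  set.seed(1)
  scr <- regulonmra:::new_pwm("scr", pwm$prob[, sample.int(10)])
  key <- function(m) sort(apply(m, 2, paste, collapse = ","))
  expect_identical(key(scr$prob), key(pwm$prob))
})

test_that("the scrambled-motif test is powered on planted fixtures and calibrated on decoys", {
  truth <- small_truth()
  tf <- planted_mrs(truth, "S1")[1]
  pwm <- make_test_pwm("m", seed = 6)
  prom <- generate_promoters(truth, setNames(list(pwm), tf), window_bp = 20000,
                             plant_rate = 0.8, plant_max_dist = 1000, seed = 7)
  targets <- truth$regulons[[tf]]$target
  res <- scrambled_motif_test(targets, prom$sequences, prom$tss, pwm,
                              n_scrambles = 50, seed = 8)
  expect_equal(res$p_empirical, 1 / 51)
  expect_true(all(res$scrambled_fractions >= 0 & res$scrambled_fractions <= 1))
  expect_gte(res$f_obs, 0.5)

  res_same <- scrambled_motif_test(targets, prom$sequences, prom$tss, pwm,
                                   n_scrambles = 50, seed = 8)
  expect_identical(res_same$scrambled_fractions, res$scrambled_fractions)

  decoy <- make_test_pwm("decoy", seed = 10)
  res_d <- scrambled_motif_test(targets, prom$sequences, prom$tss, decoy,
                                n_scrambles = 50, seed = 9)
  expect_gt(res_d$p_empirical, 0.05)
  expect_true(res_d$no_match)

  onecol <- regulonmra:::new_pwm("one", matrix(c(1, 0, 0, 0), 4, 1))
  expect_warning(
    scrambled_motif_test(targets, prom$sequences, prom$tss, onecol,
                         n_scrambles = 2, seed = 1),
    "identity"
  )
})
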