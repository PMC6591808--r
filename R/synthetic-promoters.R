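# Promoter fixture generation: per gene a uniform-composition random window
# centered on the TSS, with consensus-sampled motif instances planted near
# the TSSs of a TF's true targets. Decoy motifs are never planted, giving a
# matched negative control for the scrambled-motif validation test.

#' Build a sharp synthetic PWM
#'
#' Columns put probability `sharp` on a randomly chosen consensus base and
#' spread the remainder uniformly. With the default scoring threshold (80%
#' of the maximum achievable log-odds score) only exact-consensus windows
#' match at these defaults, which keeps the background match rate
#' negligible over 50-kbp windows.
#'
#' @param motif_id Motif identifier.
#' @param length Number of positions (default 16).
#' @param sharp Consensus base probability per column.
#' @param seed Integer seed.
#' @return A `pwm` object.
#' @export
make_test_pwm <- function(motif_id, length = 16, sharp = 0.97, seed = NULL) {
  assert_that(length >= 1, "PWM length must be >= 1")
  assert_that(sharp > 0.25 && sharp <= 1, "sharp must be in (0.25, 1]")
  with_seed(seed, {
    consensus <- sample(4, length, replace = TRUE)
    prob <- matrix((1 - sharp) / 3, 4, length)
    prob[cbind(consensus, seq_len(length))] <- sharp
    new_pwm(motif_id, prob)
  })
}

pwm_consensus <- function(pwm) {
  paste0(PWM_BASES[apply(pwm$prob, 2, which.max)], collapse = "")
}

random_dna <- function(n) {
  paste0(sample(PWM_BASES, n, replace = TRUE), collapse = "")
}

#' Generate promoter FASTA and TSS table with planted motif instances
#'
#' For every requested gene a uniform-composition random sequence of
#' `window_bp` is generated with the TSS at its center. For true targets of
#' a TF with an assigned PWM, an exact consensus instance of the motif is
#' planted with probability `plant_rate`, its midpoint within
#' `plant_max_dist` bp of the TSS. Decoy PWMs are never planted.
#'
#' @param truth A [generate_truth()] object.
#' @param pwm_set Named list, TF id -> `pwm` object.
#' @param window_bp Promoter window length (bp), TSS at center.
#' @param plant_rate Per-target planting probability.
#' @param plant_max_dist Maximum |midpoint - TSS| distance of a planted
#'   instance (bp).
#' @param seed Integer seed.
#' @param genes Genes to emit promoters for; default = union of the regulon
#'   targets of the TFs in `pwm_set`.
#' @return List with `sequences` (named character vector), `tss` (tibble
#'   gene_id/chrom/tss/strand; `tss` is the 0-based offset of the TSS within
#'   each sequence), and `planted` (tibble tf/gene/position of planted
#'   instances).
#' @export
generate_promoters <- function(truth, pwm_set, window_bp = 50000,
                               plant_rate = 0.8, plant_max_dist = 1000,
                               seed = NULL, genes = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  assert_that(length(pwm_set) >= 1 && !is.null(names(pwm_set)),
              "pwm_set must be a named list (TF id -> pwm)")
  assert_that(plant_rate >= 0 && plant_rate <= 1, "plant_rate in [0,1]")
  assert_that(plant_max_dist >= 0 && plant_max_dist <= window_bp / 2 - 1,
              "plant_max_dist must fit inside the window")
  tfs <- intersect(names(pwm_set), truth$tf_ids)
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(tfs, function(tf) truth$regulons[[tf]]$target))))
  }
  assert_that(length(genes) >= 1, "no genes to generate promoters for")
  tss_offset <- window_bp %/% 2L
  with_seed(seed, {
    seqs <- vapply(genes, function(g) random_dna(window_bp), character(1))
    planted <- list()
    for (tf in tfs) {
      pwm <- pwm_set[[tf]]
      L <- ncol(pwm$prob)
      for (g in intersect(truth$regulons[[tf]]$target, genes)) {
        if (runif(1) <= plant_rate && plant_rate > 0) {
          midpoint <- tss_offset + sample(seq(-plant_max_dist, plant_max_dist), 1)
          start <- midpoint - (L - 1L) %/% 2L   # 0-based start
          inst <- pwm_consensus(pwm)
          substr(seqs[[g]], start + 1L, start + L) <- inst
          planted[[length(planted) + 1]] <-
            tibble::tibble(tf = tf, gene = g, position = start)
        }
      }
    }
    list(
      sequences = seqs,
      tss = tibble::tibble(gene_id = genes, chrom = genes,
                           tss = as.integer(tss_offset), strand = "+"),
      planted = if (length(planted) > 0) dplyr::bind_rows(planted) else
        tibble::tibble(tf = character(), gene = character(), position = integer())
    )
  })
}

#' Emit a complete synthetic fixture set to a directory
#'
#' Writes everything a file-based end-to-end run needs: network cohort,
#' discovery and validation cohorts, a second-species cohort with ortholog
#' map, truth JSON, promoter FASTA + TSS table, and a HOMER-format motif
#' file (one true motif per focal TF plus a decoy).
#'
#' @param truth A [generate_truth()] object.
#' @param dir Output directory.
#' @param seed Integer master seed.
#' @param n_network_samples Samples in the network-inference cohort.
#' @param promoter_window_bp Promoter window for the motif fixture.
#' @param motif_tfs TFs given a planted motif (default: first planted MR of
#'   subtype S1).
#' @return Named list of written paths, invisibly.
#' @export
simulate_fixture_set <- function(truth, dir, seed,
                                 n_network_samples = 120,
                                 promoter_window_bp = 10000,
                                 motif_tfs = planted_mrs(truth, "S1")[1]) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  network <- generate_cohort(truth, c(cohort = n_network_samples),
                             seed = derive_seed(seed, 11), sample_prefix = "N")
  pair <- generate_paired_cohorts(truth, seed = derive_seed(seed, 12))
  xsp <- generate_cross_species(truth, seed = derive_seed(seed, 13))
  pwm_set <- setNames(lapply(seq_along(motif_tfs), function(i) {
    make_test_pwm(paste0("MOTIF_", motif_tfs[i]), seed = derive_seed(seed, 20 + i))
  }), motif_tfs)
  decoy <- make_test_pwm("MOTIF_DECOY", seed = derive_seed(seed, 30))
  prom <- generate_promoters(truth, pwm_set, window_bp = promoter_window_bp,
                             seed = derive_seed(seed, 14),
                             plant_max_dist = min(1000, promoter_window_bp %/% 4))
  paths <- c(
    write_bundle(network, dir, "network"),
    setNames(write_bundle(pair$discovery, dir, "discovery"), c("disc_expr", "disc_pheno")),
    setNames(write_bundle(pair$validation, dir, "validation"), c("val_expr", "val_pheno")),
    setNames(write_bundle(xsp$bundle2, dir, "species2"), c("sp2_expr", "sp2_pheno"))
  )
  paths[["ortholog_map"]] <- file.path(dir, "ortholog_map.tsv")
  readr::write_tsv(tibble::tibble(source = names(xsp$ortholog_map),
                                  target = unname(xsp$ortholog_map)),
                   paths[["ortholog_map"]], progress = FALSE)
  paths[["promoters"]] <- file.path(dir, "promoters.fasta")
  write_fasta(prom$sequences, paths[["promoters"]])
  paths[["tss"]] <- file.path(dir, "tss.tsv")
  readr::write_tsv(prom$tss, paths[["tss"]], progress = FALSE)
  paths[["motifs"]] <- file.path(dir, "motifs.homer")
  write_pwm_homer(c(pwm_set, list(decoy = decoy)), paths[["motifs"]])
  paths[["truth"]] <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    tf_ids = truth$tf_ids,
    regulons = lapply(truth$regulons, function(r) as.list(r)),
    subtype_design = lapply(truth$subtype_design, function(d) as.list(d)),
    noise_sd = truth$noise_sd,
    seed = truth$seed,
    motif_tfs = motif_tfs
  ), paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(as.list(paths))
}
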