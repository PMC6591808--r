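# End-to-end orchestration from a single config (YAML file or R list):
# signatures -> network inference (per DPI tolerance) -> MRA -> topology ->
# activity -> motif validation (optional) -> cross-cohort validation
# (optional). Each stage's outputs are written before the next begins and a
# manifest records every artifact with an md5 content hash, so a run is
# fully reproducible from the resolved config snapshot alone.

pipeline_defaults <- list(
  lfc_threshold = 1.5,
  alpha = 0.05,
  moderation = "none",
  dpi_tolerance = c(0, 0.05),
  n_permutations = 10,
  alpha_perm = 0.01,
  window_bp = 50000,
  proximal_bp = 2500,
  n_scrambles = 200,
  n_sims = 10000,
  k_subnetworks = 3,
  min_regulon = 5,
  seed = 1
)

validate_config <- function(config) {
  cfg <- modifyList(pipeline_defaults, config)
  for (p in c("expr", "pheno")) {
    if (is.null(cfg[[p]])) abort(paste0("config missing required path '", p, "'"))
  }
  path_keys <- intersect(names(cfg), c("expr", "pheno", "network_expr",
                                       "promoters", "tss", "motifs",
                                       "expr_validation", "pheno_validation"))
  for (p in path_keys) {
    if (!file.exists(cfg[[p]])) abort(paste0("config path '", p, "' does not exist: ", cfg[[p]]))
  }
  assert_that(cfg$alpha > 0 && cfg$alpha <= 1, "alpha must be in (0, 1]")
  assert_that(cfg$lfc_threshold >= 0, "lfc_threshold must be >= 0")
  assert_that(all(cfg$dpi_tolerance >= 0 & cfg$dpi_tolerance < 1),
              "dpi_tolerance values must be in [0, 1)")
  assert_that(cfg$alpha_perm > 0 && cfg$alpha_perm <= 1, "alpha_perm in (0, 1]")
  assert_that(cfg$n_scrambles >= 1, "n_scrambles must be >= 1")
  assert_that(cfg$n_sims >= 100, "n_sims must be >= 100")
  assert_that(is.null(cfg$group_a) || is.character(cfg$group_a),
              "group_a must be a group label")
  if (is.null(cfg$group_a)) abort("config missing 'group_a' (contrast group)")
  cfg$group_b <- cfg$group_b %||% "rest"
  cfg$tfs <- cfg$tfs %||% NULL
  cfg
}

#' Run the full analysis pipeline from a config
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Required entries: `expr`, `pheno` (signature cohort), `group_a`
#'   (contrast group; `group_b` defaults to `"rest"`), and `tfs` (character
#'   vector of TF ids, or a file with one id per line). Optional:
#'   `network_expr` (separate network-inference cohort; defaults to `expr`),
#'   `expr_validation`/`pheno_validation`/`group_a_validation` for
#'   cross-cohort validation, `promoters`/`tss`/`motifs` for motif
#'   validation, and any parameter in the defaults (lfc_threshold 1.5,
#'   alpha 0.05, dpi_tolerance c(0, 0.05), window 50000, proximal 2500,
#'   n_scrambles 200, n_sims 10000).
#' @param out_dir Output run directory (created; existing files
#'   overwritten).
#' @return Invisibly, a list with the key in-memory results and `manifest`
#'   (tibble of artifact paths and md5 hashes). All artifacts are also
#'   written under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(stage, msg) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage, "] ", msg)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
  }
  artifacts <- character(0)
  emit <- function(obj, name, writer = readr::write_tsv) {
    path <- file.path(out_dir, name)
    writer(tibble::as_tibble(obj), path)
    artifacts <<- c(artifacts, path)
    path
  }
  on_stage_error <- function(stage) {
    function(e) {
      log_line(stage, paste0("FAILED: ", conditionMessage(e)))
      abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
    }
  }

  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                   file.path(out_dir, "resolved_config.yaml"))
  artifacts <- c(artifacts, file.path(out_dir, "resolved_config.yaml"))

  # --- signatures ---------------------------------------------------------
  stage <- "signature"
  results <- list()
  tryCatch({
    expr <- read_expression(cfg$expr)
    pheno <- read_phenotypes(cfg$pheno)
    log_line(stage, paste0("expression ", nrow(expr), " genes x ", ncol(expr), " samples"))
    sig <- differential_signature(expr, pheno, cfg$group_a, cfg$group_b,
                                  lfc_threshold = cfg$lfc_threshold,
                                  alpha = cfg$alpha,
                                  moderation = cfg$moderation)
    emit(sig, "signature.tsv")
    log_line(stage, paste0("DE genes: ", sum(sig$is_de)))
    results$signature <- sig
  }, error = on_stage_error(stage))

  # --- network inference (per DPI tolerance) ------------------------------
  stage <- "network"
  tryCatch({
    net_expr <- if (!is.null(cfg$network_expr)) read_expression(cfg$network_expr) else expr
    tfs <- cfg$tfs
    if (length(tfs) == 1 && file.exists(tfs)) tfs <- readLines(tfs)
    tfs <- intersect(tfs, rownames(net_expr))
    assert_that(length(tfs) >= 2, "need at least 2 TFs present in the network cohort")
    raw_net <- infer_network(net_expr, tfs,
                             n_permutations = cfg$n_permutations,
                             alpha_perm = cfg$alpha_perm,
                             seed = derive_seed(cfg$seed, 1))
    log_line(stage, paste0("pre-DPI edges: ", nrow(raw_net$edges)))
    results$networks <- lapply(cfg$dpi_tolerance, function(tol) {
      net <- apply_dpi(raw_net, tol)
      write_network(net, file.path(out_dir, sprintf("network_dpi%s.tsv", tol)))
      artifacts <<- c(artifacts, file.path(out_dir, sprintf("network_dpi%s.tsv", tol)))
      log_line(stage, paste0("DPI ", tol, ": ", nrow(net$edges), " edges"))
      net
    })
    names(results$networks) <- paste0("dpi_", cfg$dpi_tolerance)
  }, error = on_stage_error(stage))

  # --- MRA ----------------------------------------------------------------
  stage <- "mra"
  tryCatch({
    results$mra <- purrr::imap(results$networks, function(net, label) {
      report <- run_mra(net, results$signature, alpha = cfg$alpha)
      emit(report, paste0("mra_", label, ".tsv"))
      curve <- cumulative_attribution(report, net, results$signature,
                                      k_max = min(20, nrow(report)))
      emit(curve, paste0("cumulative_", label, ".tsv"))
      log_line(stage, paste0(label, ": ", sum(report$significant),
                             " significant MRs of ", nrow(report)))
      list(report = report, curve = curve)
    })
  }, error = on_stage_error(stage))

  # --- topology -----------------------------------------------------------
  stage <- "topology"
  tryCatch({
    net0 <- results$networks[[1]]
    ov <- regulon_overlap_matrix(net0)
    emit(tibble::as_tibble(unclass(ov), rownames = "tf"), "regulon_overlap.tsv")
    if (nrow(ov) > cfg$k_subnetworks) {
      labels <- cluster_subnetworks(ov, k = cfg$k_subnetworks)
      emit(labels, "subnetworks.tsv")
      log_line(stage, paste0(cfg$k_subnetworks, " subnetworks over ", nrow(ov), " TFs"))
    }
    results$overlap <- ov
  }, error = on_stage_error(stage))

  # --- activity -----------------------------------------------------------
  stage <- "activity"
  tryCatch({
    act <- infer_activity(expr, results$networks[[1]],
                          min_regulon = cfg$min_regulon)
    emit(tidy(act), "activity.tsv")
    da <- differential_activity(act, pheno, cfg$group_a,
                                group_b = if (identical(cfg$group_b, "rest"))
                                  setdiff(unique(pheno$group), cfg$group_a)[1]
                                else cfg$group_b)
    emit(da, "differential_activity.tsv")
    log_line(stage, paste0(nrow(act), " TF activity profiles"))
    results$activity <- act
  }, error = on_stage_error(stage))

  # --- motif validation (optional) ---------------------------------------
  if (!is.null(cfg$promoters) && !is.null(cfg$tss) && !is.null(cfg$motifs)) {
    stage <- "motif_validation"
    tryCatch({
      promoters <- read_fasta(cfg$promoters)
      tss <- read_tss_table(cfg$tss)
      pwms <- read_pwm(cfg$motifs, dialect = cfg$motif_dialect %||% "homer")
      motif_tfs <- intersect(sub("^MOTIF_", "", names(pwms)), results$networks[[1]]$tf_ids)
      results$motif <- purrr::map_dfr(motif_tfs, function(tf) {
        res <- scrambled_motif_test(
          regulon(results$networks[[1]], tf), promoters, tss,
          pwms[[paste0("MOTIF_", tf)]],
          n_scrambles = cfg$n_scrambles, seed = derive_seed(cfg$seed, 5),
          proximal = cfg$proximal_bp
        )
        glance(res)
      })
      if (nrow(results$motif) > 0) emit(results$motif, "motif_validation.tsv")
      log_line(stage, paste0(nrow(results$motif), " motif(s) tested"))
    }, error = on_stage_error(stage))
  }

  # --- cross-cohort validation (optional) --------------------------------
  if (!is.null(cfg$expr_validation) && !is.null(cfg$pheno_validation)) {
    stage <- "validation"
    tryCatch({
      expr_v <- read_expression(cfg$expr_validation)
      pheno_v <- read_phenotypes(cfg$pheno_validation)
      sig_v <- differential_signature(expr_v, pheno_v,
                                      cfg$group_a_validation %||% cfg$group_a,
                                      cfg$group_b_validation %||% "rest",
                                      lfc_threshold = cfg$lfc_threshold,
                                      alpha = cfg$alpha)
      emit(sig_v, "signature_validation.tsv")
      mr_list <- results$mra[[length(results$mra)]]$report |>
        dplyr::filter(.data$significant) |>
        dplyr::pull("tf")
      if (length(mr_list) >= 3) {
        cv <- cross_cohort_validation(results$networks[[length(results$networks)]],
                                      results$signature, sig_v, mr_list)
        emit(cv$table, "cross_cohort_validation.tsv")
        log_line(stage, paste0("Pearson r = ", signif(cv$pearson$estimate, 3)))
        results$cross_cohort <- cv
      }
    }, error = on_stage_error(stage))
  }

  manifest <- tibble::tibble(
    path = basename(artifacts),
    md5 = unname(tools::md5sum(artifacts))
  )
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  log_line("done", paste0(nrow(manifest), " artifacts"))
  results$manifest <- manifest
  invisible(results)
}
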