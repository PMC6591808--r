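# Two-group differential-expression signatures on log2 expression.
# log2FC is the raw mean difference groupA - groupB. p-values come from a
# two-sided two-sample t statistic: Welch (moderation = "none") or a
# single-parameter moderated test that shrinks per-gene pooled variances
# toward the across-gene mean with prior weight d0 (moderation = "shrink"),
# a deliberately simple stand-in for full empirical-Bayes machinery.

#' Derive a two-group differential-expression signature
#'
#' @param expr Numeric genes x samples matrix on the log2 scale.
#' @param pheno Phenotype tibble with `sample_id` and `group` columns
#'   covering the columns of `expr`.
#' @param group_a,group_b Group labels to contrast (A vs B). `group_b =
#'   "rest"` contrasts `group_a` against all other samples.
#' @param lfc_threshold Absolute log2 fold-change threshold for DE calls
#'   (default 1.5; use 2.0 for the stricter cell-line style analysis).
#' @param alpha Adjusted-p threshold for DE calls.
#' @param moderation `"none"` for Welch, `"shrink"` for moderated pooled
#'   variance.
#' @param d0 Prior degrees of freedom for `moderation = "shrink"`.
#' @return A `de_signature`: tibble with columns `gene_id`, `log2fc`, `p`,
#'   `p_adj`, `is_de`, `direction`, carrying the contrast metadata as
#'   attributes.
#' @export
differential_signature <- function(expr, pheno, group_a, group_b = "rest",
                                   lfc_threshold = 1.5, alpha = 0.05,
                                   moderation = c("none", "shrink"), d0 = 4) {
  moderation <- match.arg(moderation)
  validate_expression(expr)
  assert_that(all(c("sample_id", "group") %in% colnames(pheno)),
              "phenotypes need sample_id and group columns")
  assert_that(lfc_threshold >= 0, "lfc_threshold must be >= 0")
  assert_that(alpha > 0 && alpha <= 1, "alpha must be in (0, 1]")
  ph <- pheno[match(colnames(expr), pheno$sample_id), ]
  assert_that(!anyNA(ph$sample_id), "every expression sample needs a phenotype row")
  a_idx <- which(ph$group == group_a)
  b_idx <- if (identical(group_b, "rest")) {
    setdiff(seq_len(ncol(expr)), a_idx)
  } else {
    which(ph$group == group_b)
  }
  if (length(a_idx) < 2) abort(paste0("group '", group_a, "' has < 2 samples"))
  if (length(b_idx) < 2) abort(paste0("group '", group_b, "' has < 2 samples"))

  xa <- expr[, a_idx, drop = FALSE]
  xb <- expr[, b_idx, drop = FALSE]
  na <- length(a_idx); nb <- length(b_idx)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, stats::var); vb <- apply(xb, 1, stats::var)
  log2fc <- ma - mb

  if (moderation == "none") {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    tstat <- log2fc / sqrt(pmax(se2, 1e-12))
    df[!is.finite(df)] <- na + nb - 2
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    s0 <- mean(sp2)
    sp2_mod <- (d0 * s0 + (na + nb - 2) * sp2) / (d0 + na + nb - 2)
    se2 <- sp2_mod * (1 / na + 1 / nb)
    tstat <- log2fc / sqrt(pmax(se2, 1e-12))
    df <- rep(d0 + na + nb - 2, length(tstat))
  }
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # Degenerate genes: no variance in either group and no mean difference.
  degenerate <- se2 < 1e-12 & abs(log2fc) < 1e-12
  p[degenerate] <- 1
  p_adj <- bh_adjust(p)

  sig <- tibble::tibble(
    gene_id = rownames(expr),
    log2fc = unname(log2fc),
    p = unname(p),
    p_adj = unname(p_adj),
    is_de = abs(log2fc) > lfc_threshold & p_adj < alpha,
    direction = dplyr::case_when(
      abs(log2fc) > lfc_threshold & p_adj < alpha & log2fc > 0 ~ "up",
      abs(log2fc) > lfc_threshold & p_adj < alpha & log2fc < 0 ~ "down",
      TRUE ~ "none"
    )
  )
  structure(sig,
            class = c("de_signature", class(sig)),
            group_a = group_a, group_b = group_b,
            n_a = na, n_b = nb,
            lfc_threshold = lfc_threshold, alpha = alpha,
            moderation = moderation)
}

#' Summarize a signature's DE calls
#'
#' @param sig A [differential_signature()] result.
#' @return One-row tibble: `n_de`, `n_up`, `n_down`, `frac_down` (NA with
#'   `empty = TRUE` flag when there are no DE genes).
#' @export
signature_summary <- function(sig) {
  stopifnot(inherits(sig, "de_signature"))
  n_up <- sum(sig$direction == "up")
  n_down <- sum(sig$direction == "down")
  n_de <- n_up + n_down
  tibble::tibble(
    n_de = n_de, n_up = n_up, n_down = n_down,
    frac_down = if (n_de > 0) n_down / n_de else NA_real_,
    empty = n_de == 0
  )
}

#' Genes called differentially expressed
#'
#' @param sig A `de_signature`.
#' @return Character vector of DE gene ids.
#' @export
de_genes <- function(sig) {
  stopifnot(inherits(sig, "de_signature"))
  sig$gene_id[sig$is_de]
}

#' @export
glance.de_signature <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(group_a = attr(x, "group_a"), group_b = attr(x, "group_b"),
                   n_a = attr(x, "n_a"), n_b = attr(x, "n_b"),
                   lfc_threshold = attr(x, "lfc_threshold"),
                   alpha = attr(x, "alpha"), moderation = attr(x, "moderation")),
    signature_summary(x)
  )
}

#' Write / read a signature TSV
#'
#' @param sig A `de_signature`.
#' @param path Output path.
#' @return `path` invisibly (writer); a plain tibble (reader).
#' @export
write_signature <- function(sig, path) {
  readr::write_tsv(tibble::as_tibble(sig), path, progress = FALSE)
  invisible(path)
}
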