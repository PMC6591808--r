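# Network validation by motif proximity: scan regulon targets' promoter
# windows for a TF's PWM, take the nearest match to the TSS per gene, and
# compare the fraction of nearest matches within a proximal window (2.5 kbp
# by default) to the same quantity for column-scrambled versions of the
# motif. Scoring is log-odds against a uniform 0.25 background with a small
# pseudocount; a window matches when its score reaches `threshold_frac` of
# the maximum achievable score. Scanning runs through Biostrings::matchPWM
# with an absolute score threshold, on both strands via the
# reverse-complemented score matrix so positions stay in forward
# coordinates.

pwm_score_matrix <- function(pwm, pseudocount = 1e-3) {
  p <- (pwm$prob + pseudocount) / (1 + 4 * pseudocount)
  log2(p / 0.25)
}

revcomp_matrix <- function(s) {
  out <- s[c("T", "G", "C", "A"), rev(seq_len(ncol(s))), drop = FALSE]
  rownames(out) <- PWM_BASES
  out
}

#' Scan a sequence for PWM matches
#'
#' @param sequence A DNA string over A/C/G/T/N (case-insensitive).
#' @param pwm A `pwm` object.
#' @param threshold_frac Match threshold as a fraction of the maximum
#'   achievable log-odds score.
#' @param pseudocount Probability pseudocount applied at scoring time.
#' @return Tibble with `position` (0-based window start on the forward
#'   strand), `strand`, `score`; forward and reverse matches at the same
#'   window are deduplicated to one row (the higher-scoring strand).
#'   N-containing windows are skipped.
#' @export
pwm_scan <- function(sequence, pwm, threshold_frac = 0.8, pseudocount = 1e-3) {
  assert_that(is.character(sequence) && length(sequence) == 1 && nzchar(sequence),
              "sequence must be a non-empty string")
  sequence <- toupper(sequence)
  L <- ncol(pwm$prob)
  assert_that(nchar(sequence) >= L, "sequence shorter than the PWM")
  scan_subject(Biostrings::DNAString(sequence), pwm, threshold_frac, pseudocount)
}

# Both-strand matchPWM on a prebuilt DNAString; 0-based positions, matches
# whose window overlaps an N are dropped, forward/reverse hits at the same
# window deduplicated to the higher-scoring strand.
scan_subject <- function(dna, pwm, threshold_frac, pseudocount) {
  s_fwd <- pwm_score_matrix(pwm, pseudocount)
  threshold <- threshold_frac * sum(apply(s_fwd, 2, max))
  one_strand <- function(score_matrix, strand) {
    # matchPWM warns about non-ACGT letters (N separators/windows) and
    # scores them 0; those matches are dropped explicitly below.
    m <- suppressWarnings(
      Biostrings::matchPWM(score_matrix, dna, min.score = threshold,
                           with.score = TRUE)
    )
    if (length(m) == 0) {
      return(tibble::tibble(position = integer(), strand = character(),
                            score = numeric()))
    }
    seqs <- as.character(m)
    ok <- !grepl("N", seqs, fixed = TRUE)
    tibble::tibble(position = BiocGenerics::start(m)[ok] - 1L,
                   strand = strand,
                   score = S4Vectors::mcols(m)$score[ok])
  }
  hits <- dplyr::bind_rows(
    one_strand(s_fwd, "+"),
    one_strand(revcomp_matrix(s_fwd), "-")
  )
  if (nrow(hits) == 0) return(hits)
  hits <- dplyr::arrange(hits, .data$position, dplyr::desc(.data$score))
  hits[!duplicated(hits$position), ]
}

# Promoters concatenated once into a single DNAString with long-N
# separators; scans over scrambled motifs reuse the same subject, turning
# genes x scrambles x strands scans into scrambles x strands scans (matches
# overlapping the N separators are dropped, so hits cannot straddle genes).
promoter_subject <- function(promoters, sep_len = 32) {
  lens <- nchar(promoters)
  starts0 <- cumsum(c(0, head(lens + sep_len, -1)))   # 0-based gene starts
  list(
    dna = Biostrings::DNAString(paste(toupper(promoters),
                                      collapse = strrep("N", sep_len))),
    starts0 = starts0,
    genes = names(promoters)
  )
}

scan_promoters <- function(promoters, pwm, threshold_frac, pseudocount,
                           subject = NULL) {
  subject <- subject %||% promoter_subject(promoters)
  hits <- scan_subject(subject$dna, pwm, threshold_frac, pseudocount)
  if (nrow(hits) == 0) {
    return(tibble::tibble(gene = character(), position = integer()))
  }
  idx <- findInterval(hits$position, subject$starts0)
  tibble::tibble(gene = subject$genes[idx],
                 position = hits$position - subject$starts0[idx])
}

#' Nearest-match TSS distances and proximal fraction for a regulon
#'
#' @param targets Character vector of regulon target gene ids.
#' @param promoters Named character vector, gene id -> promoter sequence
#'   (window centered on the TSS).
#' @param tss TSS table tibble (`gene_id`, `tss` = 0-based TSS offset within
#'   the promoter sequence).
#' @param pwm A `pwm` object.
#' @param proximal Proximal window half-width in bp (default 2500).
#' @param threshold_frac,pseudocount Passed to [pwm_scan()].
#' @return List with `distances` (tibble gene/n_matches/distance; `distance`
#'   is NA for genes without any match), `f_obs` (fraction of genes with a
#'   match whose nearest match lies within `proximal`; NA when no gene has
#'   a match), `n_no_match`, and `n_missing_promoter`.
#' @export
nearest_match_fraction <- function(targets, promoters, tss, pwm,
                                   proximal = 2500, threshold_frac = 0.8,
                                   pseudocount = 1e-3, .subject = NULL) {
  tss_of <- setNames(tss$tss, tss$gene_id)
  missing <- setdiff(targets, names(promoters))
  if (length(missing) > 0) {
    warn(paste0("skipping ", length(missing), " target(s) without promoter sequence"))
  }
  present <- intersect(targets, names(promoters))
  assert_that(length(present) > 0, "no targets with promoter sequences")
  all_hits <- scan_promoters(promoters[present], pwm, threshold_frac, pseudocount,
                             subject = .subject)
  rows <- purrr::map_dfr(present, function(g) {
    pos <- all_hits$position[all_hits$gene == g]
    if (length(pos) == 0) {
      return(tibble::tibble(gene = g, n_matches = 0L, distance = NA_real_))
    }
    mid <- pos + (ncol(pwm$prob) - 1) / 2
    tibble::tibble(gene = g, n_matches = length(pos),
                   distance = min(abs(mid - tss_of[[g]])))
  })
  matched <- rows[!is.na(rows$distance), , drop = FALSE]
  f_obs <- if (nrow(matched) > 0) mean(matched$distance <= proximal) else NA_real_
  list(distances = rows, f_obs = f_obs,
       n_no_match = sum(is.na(rows$distance)),
       n_missing_promoter = length(missing))
}

#' Scrambled-motif empirical test of motif-TSS proximity
#'
#' Recomputes the proximal nearest-match fraction for `n_scrambles`
#' column-order permutations of the PWM (composition and information
#' content preserved) and reports the empirical p-value
#' `(#\{f_scr >= f_obs\} + 1) / (n_scrambles + 1)`. A scramble (or the
#' observed motif) with no matched genes contributes a fraction of 0; if
#' the observed motif itself matches nothing, `f_obs` is NA and the test is
#' flagged with p = 1.
#'
#' @inheritParams nearest_match_fraction
#' @param n_scrambles Number of scrambled motifs (>= 1; 200 is the
#'   standard).
#' @param seed Integer seed.
#' @return A `motif_scan_result`: list with `motif_id`, `distances`,
#'   `f_obs`, `scrambled_fractions`, `p_empirical`, `n_scrambles`,
#'   `no_match` flag.
#' @export
scrambled_motif_test <- function(targets, promoters, tss, pwm,
                                 n_scrambles = 200, seed = NULL,
                                 proximal = 2500, threshold_frac = 0.8,
                                 pseudocount = 1e-3) {
  assert_that(n_scrambles >= 1, "n_scrambles must be >= 1")
  L <- ncol(pwm$prob)
  if (L == 1) warn("single-column PWM: scrambling is the identity")
  present <- intersect(targets, names(promoters))
  subject <- if (length(present) > 0) promoter_subject(promoters[present])
  obs <- nearest_match_fraction(targets, promoters, tss, pwm, proximal,
                                threshold_frac, pseudocount, .subject = subject)
  f_scr <- with_seed(seed, vapply(seq_len(n_scrambles), function(i) {
    scr <- new_pwm(paste0(pwm$motif_id, "_scr", i),
                   pwm$prob[, sample.int(L), drop = FALSE])
    res <- suppressWarnings(
      nearest_match_fraction(targets, promoters, tss, scr, proximal,
                             threshold_frac, pseudocount, .subject = subject)
    )
    if (is.na(res$f_obs)) 0 else res$f_obs
  }, numeric(1)))
  no_match <- is.na(obs$f_obs)
  p_empirical <- if (no_match) 1 else (sum(f_scr >= obs$f_obs) + 1) / (n_scrambles + 1)
  structure(list(
    motif_id = pwm$motif_id,
    distances = obs$distances,
    f_obs = obs$f_obs,
    scrambled_fractions = f_scr,
    p_empirical = p_empirical,
    n_scrambles = n_scrambles,
    no_match = no_match
  ), class = "motif_scan_result")
}

#' @export
print.motif_scan_result <- function(x, ...) {
  cat("<motif_scan_result> ", x$motif_id, ": f_obs = ",
      if (is.na(x$f_obs)) "NA (no matches)" else signif(x$f_obs, 3),
      ", p_empirical = ", signif(x$p_empirical, 4),
      " (", x$n_scrambles, " scrambles)\n", sep = "")
  invisible(x)
}

#' @export
glance.motif_scan_result <- function(x, ...) {
  tibble::tibble(
    motif_id = x$motif_id,
    n_genes = nrow(x$distances),
    n_matched = sum(!is.na(x$distances$distance)),
    f_obs = x$f_obs,
    mean_f_scrambled = mean(x$scrambled_fractions),
    p_empirical = x$p_empirical,
    n_scrambles = x$n_scrambles
  )
}
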