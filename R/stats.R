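#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` genes from a
#' universe of `N` of which `K` are "marked", the probability of observing at
#' least `k` marked genes. This is the enrichment p-value used throughout
#' master-regulator analysis.
#'
#' @param k Observed overlap (integer >= 0).
#' @param K Size of the first set (e.g. the DE signature within the universe).
#' @param n Size of the second set (e.g. a regulon).
#' @param N Universe size.
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  assert_that(is_count(k) && is_count(K) && is_count(n) && is_count(N),
              "k, K, n, N must be non-negative integers")
  assert_that(K <= N && n <= N, "set sizes cannot exceed the universe")
  assert_that(k <= min(K, n), "overlap cannot exceed the smaller set")
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p Vector of p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Monte-Carlo gene-set overlap significance with Poisson extrapolation
#'
#' Tests whether the observed overlap between two gene sets exceeds what is
#' expected for uniformly random sets of the same sizes. `n_sims` random
#' set pairs are drawn and their intersection sizes recorded; a Poisson
#' distribution is fitted to the simulated overlaps by its mean, giving a
#' tail p-value with resolution beyond the 1/(n_sims+1) floor of the
#' empirical p-value (needed when the truth is many orders of magnitude
#' beyond the simulation).
#'
#' @param size1,size2 Sizes of the two sets.
#' @param universe_size Size of the universe both sets are drawn from.
#' @param observed Observed intersection size.
#' @param n_sims Number of Monte-Carlo draws (>= 100).
#' @param seed Integer seed.
#' @return An `overlap_test` object: list with `observed_overlap`,
#'   `simulated_overlaps`, `lambda_hat`, `p_empirical`, `p_poisson`.
#' @export
overlap_significance <- function(size1, size2, universe_size, observed,
                                 n_sims = 10000, seed = NULL) {
  assert_that(is_count(size1) && is_count(size2) && is_count(universe_size),
              "sizes must be non-negative integers")
  assert_that(size1 <= universe_size && size2 <= universe_size,
              "set sizes cannot exceed the universe")
  assert_that(is_count(observed) && observed <= min(size1, size2),
              "observed overlap cannot exceed the smaller set")
  assert_that(n_sims >= 100, "n_sims must be >= 100")
  # |A n B| for independent uniform subsets is hypergeometric: condition on
  # A (size1 marked genes) and draw B (size2 genes) without replacement.
  sims <- with_seed(seed, rhyper(n_sims, size1, universe_size - size1, size2))
  lambda_hat <- mean(sims)
  p_empirical <- (sum(sims >= observed) + 1) / (n_sims + 1)
  p_poisson <- if (observed == 0) 1 else ppois(observed - 1, lambda_hat, lower.tail = FALSE)
  structure(list(
    observed_overlap = as.integer(observed),
    simulated_overlaps = as.integer(sims),
    lambda_hat = lambda_hat,
    p_empirical = p_empirical,
    p_poisson = p_poisson
  ), class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("<overlap_test> observed =", x$observed_overlap,
      "| lambda_hat =", signif(x$lambda_hat, 4),
      "| p_empirical =", signif(x$p_empirical, 4),
      "| p_poisson =", format(x$p_poisson, digits = 4), "\n")
  invisible(x)
}

#' @export
glance.overlap_test <- function(x, ...) {
  tibble::tibble(
    observed_overlap = x$observed_overlap,
    lambda_hat = x$lambda_hat,
    n_sims = length(x$simulated_overlaps),
    p_empirical = x$p_empirical,
    p_poisson = x$p_poisson
  )
}
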