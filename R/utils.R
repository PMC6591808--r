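# Internal helpers shared across modules.

# Deterministic local RNG scope: runs `code` under `seed` and restores the
# caller's RNG state afterwards, so package functions never perturb user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# Stage seeds derived from one master seed; kept below 2^31.
derive_seed <- function(master_seed, stage_index) {
  as.integer((as.numeric(master_seed) + 10007 * as.numeric(stage_index)) %% 2147483647)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == floor(x) && x >= 0
}
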