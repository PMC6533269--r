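# Internal helpers shared across modules.

# Deterministic sub-seed for a named stage, derived from one top-level seed.
# Keeps independent stages decoupled: adding draws to one stage does not
# shift the stream of another. Result is a valid 32-bit integer seed.
.substream <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(name) * seq_len(nchar(name)))
  as.integer((abs(as.numeric(seed)) * 1009 + h * 131) %% 2147483647)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

.assert_count <- function(x, name, min = 2L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d (got %s)",
                 name, min, deparse(x)), call. = FALSE)
  }
  invisible(as.integer(x))
}

.assert_nonneg_scalar <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("`%s` must be a single finite value >= 0 (got %s)",
                 name, deparse(x)), call. = FALSE)
  }
  invisible(as.numeric(x))
}

.assert_finite_scalar <- function(x, name) {
  if (length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite value (got %s)",
                 name, deparse(x)), call. = FALSE)
  }
  invisible(as.numeric(x))
}

# Sample (n-1) standard deviation column-wise, without dispatch overhead.
.col_sds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt((colSums(x * x) - n * mu^2) / (n - 1))
}
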