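# Shared fixture builders; everything is generated in code under fixed seeds.

tiny_config <- function(...) {
  defaults <- list(n_voxels = 80L, n_states = 6L, n_targets = 10L,
                   n_state_participants = 4L, n_person_participants = 5L,
                   n_raters = 10L, n_behavior_participants = 8L,
                   trials_per_participant = 30L, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(generator_config, args)
}

# condensed similarity from a plain numeric vector
cs <- function(values, kind = "neural", labels = NULL) {
  n <- (1 + sqrt(1 + 8 * length(values))) / 2
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  condensed_similarity(values, labels, kind)
}

# textbook Pearson correlation, written independently of stats::cor
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

random_pattern <- function(v, k, seed, labels = paste0("c", seq_len(k))) {
  set.seed(seed)
  pattern_matrix(matrix(rnorm(v * k), v, k), condition_labels = labels)
}
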