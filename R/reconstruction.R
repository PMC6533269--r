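#' Construct a state-frequency weight matrix
#'
#' A `weight_matrix` holds the targets-by-states non-negative matrix of how
#' often each target person is judged to experience each mental state --
#' either raw averaged frequency ratings, or their dual-normalized form used
#' as reconstruction weights.
#'
#' @param values Non-negative numeric matrix, targets in rows, states in
#'   columns.
#' @param target_labels,state_labels Unique row / column names; default to
#'   the dimnames of `values`.
#' @param normalized Logical flag; `TRUE` only for matrices produced by
#'   [normalize_weights()].
#' @return A numeric matrix of class `"weight_matrix"`.
#' @export
weight_matrix <- function(values, target_labels = rownames(values),
                          state_labels = colnames(values),
                          normalized = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("weight values must be finite numeric", call. = FALSE)
  }
  if (any(values < 0)) stop("weight values must be non-negative", call. = FALSE)
  if (is.null(target_labels)) target_labels <- paste0("t", seq_len(nrow(values)))
  if (is.null(state_labels)) state_labels <- paste0("s", seq_len(ncol(values)))
  target_labels <- as.character(target_labels)
  state_labels <- as.character(state_labels)
  if (anyDuplicated(target_labels) || anyDuplicated(state_labels)) {
    stop("duplicate target or state labels", call. = FALSE)
  }
  stopifnot(length(target_labels) == nrow(values),
            length(state_labels) == ncol(values))
  dimnames(values) <- list(target_labels, state_labels)
  structure(values, class = c("weight_matrix", "matrix", "array"),
            normalized = isTRUE(normalized))
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix> %d targets x %d states%s\n", nrow(x), ncol(x),
              if (isTRUE(attr(x, "normalized"))) " (dual-normalized)" else " (raw)"))
  invisible(x)
}

#' Dual-normalize a frequency rating matrix
#'
#' Converts raw averaged state-frequency ratings into reconstruction weights
#' by sum-normalizing first with respect to states and then to targets: each
#' state column is divided by its column sum, then each target row of the
#' result is divided by its row sum. The column step equates states on
#' overall rated frequency; the row step makes each target's weights a
#' convex combination, so every row of the output sums to 1.
#'
#' @param raw A non-negative [weight_matrix()] (raw ratings).
#' @return A `weight_matrix` with `normalized = TRUE`; all entries lie in
#'   `[0, 1]` and every row sums to 1.
#' @export
#' @examples
#' w <- weight_matrix(rbind(c(2, 1), c(2, 3)))
#' normalize_weights(w)  # rows (2/3, 1/3) and (0.4, 0.6)
normalize_weights <- function(raw) {
  stopifnot(inherits(raw, "weight_matrix"))
  v <- as.matrix(unclass(raw))
  cs <- colSums(v)
  if (any(cs == 0)) {
    stop(sprintf("cannot normalize: state column(s) sum to zero: %s",
                 paste(colnames(v)[cs == 0], collapse = ", ")), call. = FALSE)
  }
  v <- sweep(v, 2L, cs, "/")
  rs <- rowSums(v)
  if (any(rs == 0)) {
    stop(sprintf("cannot normalize: target row(s) sum to zero: %s",
                 paste(rownames(v)[rs == 0], collapse = ", ")), call. = FALSE)
  }
  v <- sweep(v, 1L, rs, "/")
  weight_matrix(v, rownames(v), colnames(v), normalized = TRUE)
}

#' Reconstruct target patterns as weighted sums of state patterns
#'
#' The direct test of the summed-state account: each target person's
#' predicted multivoxel pattern is the sum of the group-level mental-state
#' patterns, each multiplied by the dual-normalized frequency with which the
#' target experiences that state.
#'
#' @param state_patterns Group-level [pattern_matrix()] with one column per
#'   mental state.
#' @param w A dual-normalized [weight_matrix()] (see [normalize_weights()])
#'   whose state labels match the state pattern's condition labels
#'   (order-insensitive, matched by name).
#' @return A `pattern_matrix` with one reconstructed column per target.
#' @export
reconstruct_targets <- function(state_patterns, w) {
  stopifnot(inherits(state_patterns, "pattern_matrix"),
            inherits(w, "weight_matrix"))
  if (!isTRUE(attr(w, "normalized"))) {
    stop("weights must be dual-normalized; call normalize_weights() first",
         call. = FALSE)
  }
  states <- colnames(w)
  miss <- setdiff(states, colnames(state_patterns))
  if (length(miss)) {
    stop(sprintf("state labels missing from state patterns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  s <- as.matrix(state_patterns)[, states, drop = FALSE]
  recon <- s %*% t(unclass(w)) # voxels x targets
  pattern_matrix(recon, condition_labels = rownames(w),
                 voxel_ids = rownames(state_patterns))
}

#' Score reconstructions by the matched/unmatched correlation contrast
#'
#' Within each participant, every reconstructed target pattern is Pearson-
#' correlated with every actual target pattern. The "matched" correlation
#' pairs a reconstruction with its own target; the "unmatched" correlations
#' pair it with the remaining targets and are averaged (as raw r, or on the
#' Fisher z scale with `fisher = TRUE`) and subtracted from the matched
#' value. Subtracting the unmatched baseline removes any generic
#' person-pattern shared across targets, so the residual accuracy is
#' target-specific. Per-target differences are averaged within participant
#' and the participant means are tested against zero with a two-sided
#' one-sample t-test; Cohen's d is the one-sample mean/sd of those means.
#'
#' @param recon Reconstructed [pattern_matrix()] (voxels x targets).
#' @param person_sets List of per-participant actual person-pattern matrices;
#'   each must contain all reconstructed targets among its conditions.
#' @param fisher Average unmatched correlations on the Fisher z scale instead
#'   of raw r before subtracting (default `FALSE`, the literal printed
#'   procedure).
#' @return Object of class `"reconstruction_result"`: per-participant matched,
#'   unmatched, and difference summaries plus `group_t`, `group_p`,
#'   `cohens_d`, and `n_participants`. With a single participant the group
#'   statistics are `NA` and flagged unavailable.
#' @export
score_reconstruction <- function(recon, person_sets, fisher = FALSE) {
  stopifnot(inherits(recon, "pattern_matrix"))
  if (!is.list(person_sets) || length(person_sets) == 0L) {
    stop("`person_sets` must be a non-empty list", call. = FALSE)
  }
  if (nrow(recon) < 3L) stop("need at least 3 voxels", call. = FALSE)
  targets <- colnames(recon)
  n_t <- length(targets)
  if (n_t < 2L) stop("need at least 2 targets", call. = FALSE)
  rmat <- as.matrix(recon)
  if (any(.col_sds(rmat) <= 0)) {
    stop("degenerate pattern: constant reconstruction column", call. = FALSE)
  }
  avg <- if (fisher) function(x) tanh(mean(atanh(x))) else mean

  n_p <- length(person_sets)
  matched <- unmatched <- diffs <- numeric(n_p)
  for (p in seq_len(n_p)) {
    a <- .align_pattern_subset(person_sets[[p]], rownames(recon), targets)
    if (any(.col_sds(a) <= 0)) {
      stop(sprintf("degenerate pattern: constant target column in participant %d", p),
           call. = FALSE)
    }
    cc <- stats::cor(rmat, a) # rows: reconstructions, cols: actual targets
    m <- diag(cc)
    u <- (rowSums(cc) - m) / (n_t - 1)
    if (fisher) u <- vapply(seq_len(n_t),
                            function(i) avg(cc[i, -i]), numeric(1))
    matched[p] <- mean(m)
    unmatched[p] <- mean(u)
    diffs[p] <- mean(m - u)
  }
  if (n_p >= 2L && stats::sd(diffs) > 0) {
    tt <- stats::t.test(diffs, mu = 0, alternative = "two.sided")
    group_t <- unname(tt$statistic)
    group_p <- tt$p.value
    d <- mean(diffs) / stats::sd(diffs)
  } else {
    group_t <- group_p <- d <- NA_real_
  }
  structure(list(per_participant_matched = matched,
                 per_participant_unmatched = unmatched,
                 per_participant_difference = diffs,
                 mean_difference = mean(diffs),
                 group_t = group_t, group_p = group_p, cohens_d = d,
                 n_participants = n_p, n_targets = n_t,
                 fisher = fisher),
            class = "reconstruction_result")
}

# Align like .align_pattern but tolerate extra conditions in the participant
# matrix (reconstruction targets may be a subset of measured conditions).
.align_pattern_subset <- function(m, voxel_ids, condition_labels) {
  miss_v <- setdiff(voxel_ids, rownames(m))
  miss_c <- setdiff(condition_labels, colnames(m))
  if (length(miss_v) || length(miss_c)) {
    stop(sprintf("pattern alignment failed; missing: %s",
                 paste(utils::head(c(miss_v, miss_c), 5L), collapse = ", ")),
         call. = FALSE)
  }
  as.matrix(m)[voxel_ids, condition_labels, drop = FALSE]
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf(
    "<reconstruction_result> %d participants, %d targets\n  mean matched r %.4f, mean unmatched r %.4f\n  mean r difference %.4f (t = %.3f, p = %.3g, d = %.3f)\n",
    x$n_participants, x$n_targets,
    mean(x$per_participant_matched), mean(x$per_participant_unmatched),
    x$mean_difference, x$group_t, x$group_p, x$cohens_d))
  invisible(x)
}
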