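#' Construct a condensed pairwise similarity vector
#'
#' The common currency of all interpersonal similarity measures: the strict
#' lower triangle of a symmetric targets-by-targets similarity matrix,
#' vectorized in the canonical pair order -- pairs `(i, j)` with `i < j`,
#' ordered first by `i` and then by `j` (the same ordering as
#' `M[lower.tri(M)]` and [stats::dist()]).
#'
#' @param values Numeric vector of length `T * (T - 1) / 2`.
#' @param target_labels Character vector of the `T` target names, in the
#'   order defining the pairing.
#' @param kind One of `"neural"`, `"state"`, `"trait"`, `"text"`, `"rating"`.
#' @return Numeric vector of class `"condensed_similarity"` with attributes
#'   `target_labels` and `kind`.
#' @export
condensed_similarity <- function(values, target_labels,
                                 kind = c("neural", "state", "trait",
                                          "text", "rating")) {
  kind <- match.arg(kind)
  target_labels <- as.character(target_labels)
  n <- length(target_labels)
  if (n < 2L) stop("need at least 2 targets", call. = FALSE)
  if (anyDuplicated(target_labels)) stop("duplicate target labels", call. = FALSE)
  if (length(values) != n * (n - 1L) / 2L) {
    stop(sprintf("expected %d pair values for %d targets, got %d",
                 n * (n - 1L) / 2L, n, length(values)), call. = FALSE)
  }
  if (any(!is.finite(values))) stop("non-finite similarity values", call. = FALSE)
  structure(as.numeric(values), class = "condensed_similarity",
            target_labels = target_labels, kind = kind)
}

#' @export
print.condensed_similarity <- function(x, ...) {
  cat(sprintf("<condensed_similarity> kind '%s', %d targets (%d pairs)\n",
              attr(x, "kind"), length(attr(x, "target_labels")), length(x)))
  invisible(x)
}

#' Condense a symmetric similarity matrix / expand a condensed vector
#'
#' `condense_matrix()` extracts the strict lower triangle of a symmetric
#' matrix in canonical pair order; `similarity_matrix()` rebuilds the full
#' square matrix (with `diag_value` on the diagonal). The two are inverse to
#' one another.
#'
#' @param m Symmetric numeric matrix with target labels as dimnames.
#' @param kind Similarity kind passed to [condensed_similarity()].
#' @return `condense_matrix()`: a `condensed_similarity`;
#'   `similarity_matrix()`: a square matrix.
#' @export
condense_matrix <- function(m, kind = "neural") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    stop("matrix must be square and symmetric", call. = FALSE)
  }
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(m)))
  condensed_similarity(m[lower.tri(m)], labs, kind)
}

#' @rdname condense_matrix
#' @param cs A `condensed_similarity`.
#' @param diag_value Value placed on the diagonal (default `NA`).
#' @export
similarity_matrix <- function(cs, diag_value = NA_real_) {
  stopifnot(inherits(cs, "condensed_similarity"))
  labs <- attr(cs, "target_labels")
  n <- length(labs)
  m <- matrix(diag_value, n, n, dimnames = list(labs, labs))
  m[lower.tri(m)] <- as.numeric(cs)
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

#' Pair labels of a condensed similarity vector
#'
#' @param cs A `condensed_similarity`.
#' @return Data frame with columns `target_i`, `target_j`, `value`, `kind`,
#'   one row per pair in canonical order.
#' @export
similarity_pairs <- function(cs) {
  stopifnot(inherits(cs, "condensed_similarity"))
  labs <- attr(cs, "target_labels")
  n <- length(labs)
  idx <- which(lower.tri(diag(n)), arr.ind = TRUE)
  ord <- order(idx[, 2L], idx[, 1L]) # column-major already, keep explicit
  idx <- idx[ord, , drop = FALSE]
  data.frame(target_i = labs[idx[, 2L]], target_j = labs[idx[, 1L]],
             value = as.numeric(cs), kind = attr(cs, "kind"),
             stringsAsFactors = FALSE)
}

.check_aligned <- function(...) {
  css <- list(...)
  labs <- lapply(css, attr, "target_labels")
  lens <- lengths(css)
  if (length(unique(lens)) != 1L ||
      !all(vapply(labs[-1L], identical, logical(1), labs[[1L]]))) {
    stop("condensed similarities are not aligned (labels or length differ)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Neural similarity between target patterns
#'
#' Pearson correlation between every pair of target-specific voxel patterns.
#'
#' @param person A [pattern_matrix()] with one column per target.
#' @return A `condensed_similarity` of kind `"neural"`.
#' @export
neural_similarity <- function(person) {
  stopifnot(inherits(person, "pattern_matrix"))
  v <- as.matrix(person)
  if (ncol(v) < 2L) stop("need at least 2 targets", call. = FALSE)
  sds <- .col_sds(v)
  if (any(sds <= 0)) {
    stop(sprintf("degenerate pattern: constant column(s) %s",
                 paste(colnames(v)[sds <= 0], collapse = ", ")), call. = FALSE)
  }
  condense_matrix(stats::cor(v), kind = "neural")
}

#' Summed-state similarity from frequency ratings
#'
#' The summed-state account's prediction of interpersonal similarity: the
#' Pearson correlation between every pair of target rows of the raw
#' (averaged) state-frequency rating matrix.
#'
#' @param ratings A [weight_matrix()] of raw averaged ratings.
#' @return A `condensed_similarity` of kind `"state"`.
#' @export
state_similarity <- function(ratings) {
  stopifnot(inherits(ratings, "weight_matrix"))
  v <- t(unclass(ratings)) # states x targets; correlate target columns
  if (nrow(v) < 2L) stop("need at least 2 states", call. = FALSE)
  sds <- .col_sds(v)
  if (any(sds <= 0)) {
    stop(sprintf("degenerate rating row for target(s): %s",
                 paste(colnames(v)[sds <= 0], collapse = ", ")), call. = FALSE)
  }
  cc <- stats::cor(v)
  dimnames(cc) <- list(rownames(ratings), rownames(ratings))
  condense_matrix(cc, kind = "state")
}

#' Reduce trait ratings to a low-dimensional trait space
#'
#' Standardizes each trait scale (mean 0, sd 1) and extracts the leading
#' principal components -- by convention a three-dimensional synthesis
#' labelled power, valence, and sociality when `n_components = 3`. Component
#' signs are fixed so that each component's largest-magnitude loading is
#' positive, making the decomposition deterministic.
#'
#' @param trait_ratings Numeric targets-by-traits matrix or data frame with
#'   target row names.
#' @param n_components Number of components to retain (default 3).
#' @return Object of class `"trait_space"`: `scores` (targets x components),
#'   `loadings`, `component_labels`, and `explained_variance` (percent of
#'   total variance, non-increasing).
#' @export
trait_pca <- function(trait_ratings, n_components = 3L) {
  x <- as.matrix(trait_ratings)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("trait ratings must be finite numeric", call. = FALSE)
  }
  n_components <- .assert_count(n_components, "n_components", min = 1L)
  if (ncol(x) < n_components) {
    stop("fewer trait scales than requested components", call. = FALSE)
  }
  if (nrow(x) < n_components + 1L) {
    stop("too few targets for the requested number of components", call. = FALSE)
  }
  sds <- .col_sds(x)
  if (any(sds <= 0)) {
    stop(sprintf("constant trait column(s): %s",
                 paste(colnames(x)[sds <= 0], collapse = ", ")), call. = FALSE)
  }
  xs <- scale(x)
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  tol <- pc$sdev[1L] * 1e-8
  rank <- sum(pc$sdev > tol)
  if (rank < n_components) {
    stop(sprintf("trait ratings have rank %d < %d requested components",
                 rank, n_components), call. = FALSE)
  }
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  loads <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    if (loads[which.max(abs(loads[, k])), k] < 0) {
      loads[, k] <- -loads[, k]
      scores[, k] <- -scores[, k]
    }
  }
  labs <- if (n_components == 3L) c("power", "valence", "sociality")
          else paste0("PC", seq_len(n_components))
  colnames(scores) <- colnames(loads) <- labs
  rownames(scores) <- rownames(x)
  ev <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loads, component_labels = labs,
                 explained_variance = ev[seq_len(n_components)]),
            class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat(sprintf("<trait_space> %d targets x %d components (%s); %% variance: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(x$component_labels, collapse = ", "),
              paste(sprintf("%.1f", x$explained_variance), collapse = ", ")))
  invisible(x)
}

#' Trait similarity as reverse-coded Euclidean distance
#'
#' The trait account's prediction of interpersonal similarity: the negated
#' Euclidean distance between each pair of targets in the reduced trait
#' space. Values are at most 0, with 0 only for identical coordinates;
#' negation (rather than any other reversal) is used because downstream
#' correlations are invariant to the affine choice.
#'
#' @param space A `trait_space` from [trait_pca()], or any numeric
#'   targets-by-dimensions score matrix.
#' @return A `condensed_similarity` of kind `"trait"`.
#' @export
trait_similarity <- function(space) {
  scores <- if (inherits(space, "trait_space")) space$scores else as.matrix(space)
  labs <- rownames(scores)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(scores)))
  d <- stats::dist(scores, method = "euclidean")
  condensed_similarity(-as.numeric(d), labs, "trait")
}

#' Text similarity from bag-of-words token counts
#'
#' Measures biographical similarity between targets by comparing word
#' frequency profiles: stopwords are removed, counts are converted to
#' within-document relative frequencies over the shared vocabulary, and the
#' similarity of a pair is the negated sum of absolute frequency differences
#' (so 0 means identical profiles).
#'
#' @param counts Non-negative targets-by-vocabulary count matrix with target
#'   row names and word column names.
#' @param stopwords Character vector of words to discard (default none).
#' @return A `condensed_similarity` of kind `"text"`.
#' @export
text_similarity <- function(counts, stopwords = character()) {
  x <- as.matrix(counts)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("token counts must be finite and non-negative", call. = FALSE)
  }
  if (is.null(colnames(x))) stop("count matrix needs word column names", call. = FALSE)
  labs <- rownames(x)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(x)))
  keep <- !(colnames(x) %in% stopwords)
  if (!any(keep)) stop("no vocabulary left after stopword removal", call. = FALSE)
  x <- x[, keep, drop = FALSE]
  totals <- rowSums(x)
  if (any(totals == 0)) {
    stop(sprintf("empty document after filtering for target(s): %s",
                 paste(labs[totals == 0], collapse = ", ")), call. = FALSE)
  }
  freq <- x / totals
  d <- stats::dist(freq, method = "manhattan")
  condensed_similarity(-as.numeric(d), labs, "text")
}
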