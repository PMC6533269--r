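#' Construct a multivoxel pattern matrix
#'
#' A `pattern_matrix` holds the voxels-by-conditions matrix of regression
#' coefficients that one imaging participant (or a group average) exhibits
#' for a set of conditions -- either mental states or target people. It is
#' the unit of neural data throughout the package.
#'
#' @param values Numeric matrix, voxels in rows, conditions in columns. All
#'   entries must be finite.
#' @param condition_labels Character vector of unique condition names;
#'   defaults to `colnames(values)`.
#' @param voxel_ids Character vector of unique voxel identifiers; defaults to
#'   `rownames(values)` or `"v1"`, `"v2"`, ... when absent.
#' @param participant_id Optional single identifier for the participant the
#'   patterns belong to; `NULL` for group-level matrices.
#'
#' @return A numeric matrix of class `"pattern_matrix"` with voxel ids as row
#'   names, condition labels as column names, and a `participant_id`
#'   attribute.
#' @export
#' @examples
#' m <- pattern_matrix(matrix(rnorm(12), 4, 3),
#'                     condition_labels = c("joy", "anger", "calm"))
#' dim(m)
pattern_matrix <- function(values, condition_labels = colnames(values),
                           voxel_ids = rownames(values),
                           participant_id = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("pattern values must be numeric", call. = FALSE)
  if (any(!is.finite(values))) {
    stop("pattern values contain non-finite entries", call. = FALSE)
  }
  if (is.null(condition_labels)) {
    condition_labels <- paste0("c", seq_len(ncol(values)))
  }
  if (is.null(voxel_ids)) voxel_ids <- paste0("v", seq_len(nrow(values)))
  condition_labels <- as.character(condition_labels)
  voxel_ids <- as.character(voxel_ids)
  if (length(condition_labels) != ncol(values)) {
    stop("condition_labels length does not match number of columns", call. = FALSE)
  }
  if (length(voxel_ids) != nrow(values)) {
    stop("voxel_ids length does not match number of rows", call. = FALSE)
  }
  if (anyDuplicated(condition_labels)) {
    stop(sprintf("duplicate condition labels: %s",
                 paste(unique(condition_labels[duplicated(condition_labels)]),
                       collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(voxel_ids)) {
    stop("duplicate voxel ids", call. = FALSE)
  }
  dimnames(values) <- list(voxel_ids, condition_labels)
  structure(values, class = c("pattern_matrix", "matrix", "array"),
            participant_id = participant_id)
}

#' @export
print.pattern_matrix <- function(x, ...) {
  pid <- attr(x, "participant_id")
  cat(sprintf("<pattern_matrix> %d voxels x %d conditions%s\n",
              nrow(x), ncol(x),
              if (is.null(pid)) "" else sprintf(" (participant %s)", pid)))
  cat("conditions:", paste(utils::head(colnames(x), 8L), collapse = ", "),
      if (ncol(x) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
as.matrix.pattern_matrix <- function(x, ...) {
  attr(x, "participant_id") <- NULL
  class(x) <- c("matrix", "array")
  x
}

#' Z-score each condition pattern across voxels
#'
#' Standardizes every condition column to mean 0 and sample (n-1) standard
#' deviation 1 across voxels, so that downstream pattern correlations reflect
#' pattern shape rather than overall amplitude. This is the within-participant
#' standardization applied to state- and person-specific coefficient patterns
#' before any averaging or reconstruction.
#'
#' @param m A [pattern_matrix()].
#' @return A `pattern_matrix` of the same shape with standardized columns.
#'   The operation is idempotent.
#' @export
#' @examples
#' zscore_pattern(pattern_matrix(cbind(a = c(1, 2, 3), b = c(2, 4, 9))))
zscore_pattern <- function(m) {
  stopifnot(inherits(m, "pattern_matrix"))
  v <- as.matrix(m)
  if (nrow(v) < 2L) stop("need at least 2 voxels to z-score", call. = FALSE)
  sds <- .col_sds(v)
  bad <- !is.finite(sds) | sds <= 0
  if (any(bad)) {
    stop(sprintf("degenerate pattern: condition(s) %s constant across voxels",
                 paste(colnames(v)[bad], collapse = ", ")), call. = FALSE)
  }
  z <- sweep(sweep(v, 2L, colMeans(v), "-"), 2L, sds, "/")
  pattern_matrix(z, condition_labels = colnames(v), voxel_ids = rownames(v),
                 participant_id = attr(m, "participant_id"))
}

# Align a pattern matrix to reference voxel ids / condition labels (by name).
.align_pattern <- function(m, voxel_ids, condition_labels) {
  miss_v <- setdiff(voxel_ids, rownames(m))
  miss_c <- setdiff(condition_labels, colnames(m))
  if (length(miss_v) || length(miss_c)) {
    stop(sprintf(
      "pattern alignment failed; missing %s%s",
      if (length(miss_v)) sprintf("voxel ids: %s",
                                  paste(utils::head(miss_v, 5L), collapse = ", "))
      else "",
      if (length(miss_c)) sprintf("%scondition labels: %s",
                                  if (length(miss_v)) "; " else "",
                                  paste(miss_c, collapse = ", "))
      else ""), call. = FALSE)
  }
  extra_c <- setdiff(colnames(m), condition_labels)
  if (length(extra_c)) {
    stop(sprintf("pattern alignment failed; unexpected condition labels: %s",
                 paste(extra_c, collapse = ", ")), call. = FALSE)
  }
  as.matrix(m)[voxel_ids, condition_labels, drop = FALSE]
}

#' Average patterns across participants
#'
#' Element-wise mean of per-participant pattern matrices sharing the same
#' voxels and conditions, producing a single group-level set of patterns
#' (e.g., one canonical pattern per mental state). Matrices are aligned by
#' voxel id and condition label, so column order may differ across inputs.
#'
#' @param ms Non-empty list of [pattern_matrix()] objects.
#' @return A `pattern_matrix` with `participant_id = NULL`.
#' @export
average_across_participants <- function(ms) {
  if (!is.list(ms) || length(ms) == 0L) {
    stop("`ms` must be a non-empty list of pattern matrices", call. = FALSE)
  }
  stopifnot(all(vapply(ms, inherits, logical(1), "pattern_matrix")))
  ref <- ms[[1L]]
  vox <- rownames(ref)
  conds <- colnames(ref)
  acc <- matrix(0, nrow(ref), ncol(ref))
  for (m in ms) acc <- acc + .align_pattern(m, vox, conds)
  pattern_matrix(acc / length(ms), condition_labels = conds, voxel_ids = vox,
                 participant_id = NULL)
}
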