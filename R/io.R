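# CSV readers/writers for the pipeline's tabular interchange formats.
# All formats are plain text with header rows; matrices carry their row
# identifier in the first column.

#' Read and write pattern matrices as CSV
#'
#' The on-disk format is a CSV with the voxel id in the first column
#' (`voxel_id`) and one column per condition.
#'
#' @param path File path.
#' @param participant_id Optional participant identifier to attach on load.
#' @return `load_pattern_csv()`: a [pattern_matrix()];
#'   `write_pattern_csv()`: the path, invisibly.
#' @export
load_pattern_csv <- function(path, participant_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop(sprintf("%s: expected a voxel-id column plus condition columns", path),
         call. = FALSE)
  }
  labs <- names(df)[-1L]
  if (anyDuplicated(labs)) {
    stop(sprintf("%s: duplicated condition column(s): %s", path,
                 paste(unique(labs[duplicated(labs)]), collapse = ", ")),
         call. = FALSE)
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    stop(sprintf("%s: non-numeric cells in condition columns", path),
         call. = FALSE)
  }
  pattern_matrix(vals, condition_labels = labs,
                 voxel_ids = as.character(df[[1L]]),
                 participant_id = participant_id)
}

#' @rdname load_pattern_csv
#' @param m A [pattern_matrix()].
#' @export
write_pattern_csv <- function(m, path) {
  stopifnot(inherits(m, "pattern_matrix"))
  df <- data.frame(voxel_id = rownames(m), as.matrix(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Labelled numeric matrix <-> CSV with an id first column.
.load_labelled_csv <- function(path, id_col) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(names(df)[-1L])) {
    stop(sprintf("%s: duplicated column labels", path), call. = FALSE)
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop(sprintf("%s: non-numeric cells", path), call. = FALSE)
  rownames(vals) <- as.character(df[[1L]])
  vals
}

.write_labelled_csv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), as.matrix(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write weight (rating) matrices as CSV
#'
#' Targets in rows (first column `target`), states in columns.
#'
#' @param path File path.
#' @param normalized Flag to attach on load (default `FALSE`: raw ratings).
#' @return `load_weights_csv()`: a [weight_matrix()].
#' @export
load_weights_csv <- function(path, normalized = FALSE) {
  weight_matrix(.load_labelled_csv(path, "target"), normalized = normalized)
}

#' @rdname load_weights_csv
#' @param w A [weight_matrix()].
#' @export
write_weights_csv <- function(w, path) {
  stopifnot(inherits(w, "weight_matrix"))
  .write_labelled_csv(unclass(w), path, "target")
}

#' Read and write condensed similarity vectors as CSV
#'
#' Long format with columns `target_i`, `target_j`, `value`, `kind`, one row
#' per pair in canonical order.
#'
#' @param path File path.
#' @return `load_similarity_csv()`: a [condensed_similarity()].
#' @export
load_similarity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("target_i", "target_j", "value", "kind")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")),
         call. = FALSE)
  }
  labs <- c(unique(df$target_i), df$target_j[nrow(df)])
  condensed_similarity(df$value, labs, unique(df$kind)[1L])
}

#' @rdname load_similarity_csv
#' @param cs A [condensed_similarity()].
#' @export
write_similarity_csv <- function(cs, path) {
  stopifnot(inherits(cs, "condensed_similarity"))
  utils::write.csv(similarity_pairs(cs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write choice trial tables as CSV
#'
#' Six columns: `participant_id`, `reference`, `option_a`, `option_b`,
#' `choice` (A/B), `rt_ms`.
#'
#' @param path File path.
#' @return `load_choice_csv()`: a [choice_trial_table()].
#' @export
load_choice_csv <- function(path) {
  choice_trial_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname load_choice_csv
#' @param t A [choice_trial_table()].
#' @export
write_choice_csv <- function(t, path) {
  stopifnot(inherits(t, "choice_trial_table"))
  utils::write.csv(as.data.frame(t), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to a run directory
#'
#' Serializes every pipeline input of a [generate_dataset()] result as CSV
#' (per-participant pattern files, ratings, traits, token counts, choice
#' table, rating similarity) plus the ground truth (weights and state
#' patterns as CSV, scalar metadata as JSON). The returned path list can be
#' fed directly to [run_pipeline_files()].
#'
#' @param data A `"synthetic_dataset"`.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  state_files <- vapply(seq_along(data$state_patterns), function(i) {
    write_pattern_csv(data$state_patterns[[i]],
                      p(sprintf("state_patterns_p%02d.csv", i)))
  }, character(1))
  person_files <- vapply(seq_along(data$person_patterns), function(i) {
    write_pattern_csv(data$person_patterns[[i]],
                      p(sprintf("person_patterns_p%02d.csv", i)))
  }, character(1))
  write_weights_csv(data$ratings, p("ratings.csv"))
  .write_labelled_csv(data$traits, p("traits.csv"), "target")
  .write_labelled_csv(data$text_counts, p("text_counts.csv"), "target")
  write_choice_csv(data$trials, p("trials.csv"))
  write_similarity_csv(data$rating_similarity, p("rating_similarity.csv"))
  write_weights_csv(data$truth$true_weights, p("truth_weights.csv"))
  write_pattern_csv(data$truth$true_state_patterns, p("truth_state_patterns.csv"))
  write_similarity_csv(data$truth$true_state_similarity,
                       p("truth_state_similarity.csv"))
  jsonlite::write_json(unclass(data$config), p("config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(state_pattern_files = state_files,
                 person_pattern_files = person_files,
                 ratings = p("ratings.csv"),
                 traits = p("traits.csv"),
                 text_counts = p("text_counts.csv"),
                 trials = p("trials.csv"),
                 rating_similarity = p("rating_similarity.csv")))
}
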