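#' Run the full summed-state analysis pipeline
#'
#' End-to-end orchestration on synthetic data: generate all inputs with known
#' ground truth, prepare patterns (within-participant z-scoring, group
#' averaging, optional reliability-based voxel selection), dual-normalize
#' the frequency ratings, reconstruct target patterns as weighted state sums
#' and score them with the matched/unmatched contrast, build the five
#' interpersonal similarity measures, and compare the summed-state and trait
#' accounts with item-level and group-level correlations, semi-partial
#' coefficients, dependent-correlation difference tests, BIC, reliability
#' disattenuation, and choice/reaction-time models with participant-
#' bootstrap contrasts.
#'
#' All stochastic analysis stages (voxel-selection splits, reliability
#' splits, bootstrap resampling) draw their seeds deterministically from
#' `config$seed` via named substreams, so a fixed configuration yields an
#' identical report on every run.
#'
#' @param config A [generator_config()].
#' @param select_voxels Run split-half voxel selection on the person
#'   patterns and restrict all neural analyses to the selected mask
#'   (default `FALSE`).
#' @param n_boot Bootstrap resamples for the behavioral coefficient
#'   contrasts (default 200).
#' @param n_reliability_splits Half-splits for the neural reliability
#'   estimate (default 20).
#' @param fisher Average unmatched reconstruction correlations on the Fisher
#'   scale (default `FALSE`).
#' @param output_dir If non-`NULL`, write `report.json`, `comparison.csv`,
#'   and `per_participant.csv` there.
#' @return Object of class `"run_report"`; see [write_report()].
#' @export
run_pipeline <- function(config = generator_config(), select_voxels = FALSE,
                         n_boot = 200L, n_reliability_splits = 20L,
                         fisher = FALSE, output_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  data <- generate_dataset(config)
  inputs <- list(state_patterns = data$state_patterns,
                 person_patterns = data$person_patterns,
                 ratings = data$ratings,
                 traits = data$traits,
                 text_counts = data$text_counts,
                 trials = data$trials,
                 rating_similarity = data$rating_similarity)
  report <- .analyze(inputs, seed = config$seed,
                     select_voxels = select_voxels, n_boot = n_boot,
                     n_reliability_splits = n_reliability_splits,
                     fisher = fisher)
  report$provenance$mode <- "synthetic"
  report$provenance$config <- unclass(config)
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' Run the pipeline on files exported from a run directory
#'
#' Files mode: loads the CSV inputs written by [write_dataset()] (or
#' hand-prepared files in the same formats) and executes the identical
#' analysis, so a file round-trip reproduces the in-memory statistics
#' exactly.
#'
#' @param paths Named list with `state_pattern_files`, `person_pattern_files`
#'   (character vectors of per-participant pattern CSVs), `ratings`,
#'   `traits`, `text_counts`, `trials`, and optionally `rating_similarity`.
#' @param seed Integer seed for the stochastic analysis stages.
#' @inheritParams run_pipeline
#' @return Object of class `"run_report"`.
#' @export
run_pipeline_files <- function(paths, seed = 1L, select_voxels = FALSE,
                               n_boot = 200L, n_reliability_splits = 20L,
                               fisher = FALSE, output_dir = NULL) {
  need <- c("state_pattern_files", "person_pattern_files", "ratings",
            "traits", "text_counts", "trials")
  miss <- setdiff(need, names(paths))
  if (length(miss)) {
    stop(sprintf("`paths` missing element(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  inputs <- list(
    state_patterns = lapply(seq_along(paths$state_pattern_files), function(i)
      load_pattern_csv(paths$state_pattern_files[[i]],
                       participant_id = sprintf("state_p%02d", i))),
    person_patterns = lapply(seq_along(paths$person_pattern_files), function(i)
      load_pattern_csv(paths$person_pattern_files[[i]],
                       participant_id = sprintf("person_p%02d", i))),
    ratings = load_weights_csv(paths$ratings),
    traits = .load_labelled_csv(paths$traits, "target"),
    text_counts = .load_labelled_csv(paths$text_counts, "target"),
    trials = load_choice_csv(paths$trials),
    rating_similarity = if (!is.null(paths$rating_similarity))
      load_similarity_csv(paths$rating_similarity) else NULL)
  report <- .analyze(inputs, seed = seed, select_voxels = select_voxels,
                     n_boot = n_boot,
                     n_reliability_splits = n_reliability_splits,
                     fisher = fisher)
  report$provenance$mode <- "files"
  report$provenance$paths <- lapply(paths, as.character)
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

# Shared analysis core for synthetic and files mode.
.analyze <- function(inputs, seed, select_voxels, n_boot,
                     n_reliability_splits, fisher) {
  # -- pattern preparation ---------------------------------------------------
  state_z <- lapply(inputs$state_patterns, zscore_pattern)
  person_z <- lapply(inputs$person_patterns, zscore_pattern)
  mask <- NULL
  if (select_voxels) {
    mask <- select_reliable_voxels(person_z,
                                   seed = .substream(seed, "voxel_select"))
    state_z <- lapply(state_z, apply_voxel_mask, mask = mask)
    person_z <- lapply(person_z, apply_voxel_mask, mask = mask)
  }
  state_avg <- average_across_participants(state_z)

  # -- reconstruction --------------------------------------------------------
  weights <- normalize_weights(inputs$ratings)
  recon <- reconstruct_targets(state_avg, weights)
  recon_result <- score_reconstruction(recon, person_z, fisher = fisher)

  # -- similarity construction ----------------------------------------------
  neural_per_p <- lapply(person_z, neural_similarity)
  neural_mean <- condensed_similarity(
    rowMeans(vapply(neural_per_p, as.numeric,
                    numeric(length(neural_per_p[[1L]])))),
    attr(neural_per_p[[1L]], "target_labels"), "neural")
  state_pred <- state_similarity(inputs$ratings)
  tspace <- trait_pca(inputs$traits)
  trait_pred <- trait_similarity(tspace)
  text_dv <- text_similarity(inputs$text_counts)

  dvs <- list(neural = neural_mean, text = text_dv)
  if (!is.null(inputs$rating_similarity)) {
    dvs$ratings <- inputs$rating_similarity
  }

  # -- item-level comparison (correlational measures) ------------------------
  comparison <- do.call(rbind, lapply(names(dvs), function(measure) {
    dv <- dvs[[measure]]
    r_s <- item_correlation(dv, state_pred)
    r_t <- item_correlation(dv, trait_pred)
    sr_s <- semi_partial(dv, state_pred, trait_pred)
    sr_t <- semi_partial(dv, trait_pred, state_pred)
    diff <- paired_correlation_difference(dv, state_pred, trait_pred)
    data.frame(
      measure = measure, model = c("states", "traits"),
      coefficient = c(r_s$r, r_t$r), p = c(r_s$p, r_t$p),
      semi_partial = c(sr_s$sr, sr_t$sr),
      semi_partial_p = c(sr_s$p, sr_t$p),
      difference = c(sprintf("p=%.3g", diff$p), ""),
      bic = c(model_bic(dv, state_pred), model_bic(dv, trait_pred)),
      stringsAsFactors = FALSE)
  }))

  # -- group-level RSA and disattenuation (neural) ---------------------------
  rsa_states <- group_level_rsa(neural_per_p, state_pred)
  rsa_traits <- group_level_rsa(neural_per_p, trait_pred)
  reliability <- similarity_reliability(neural_per_p,
                                        n_splits = n_reliability_splits,
                                        seed = .substream(seed, "reliability"))
  share_states <- disattenuate(
    item_correlation(neural_mean, state_pred)$r, reliability)

  # -- behavioral models -----------------------------------------------------
  trials <- filter_trials(inputs$trials)
  ps <- trial_predictor(trials, state_pred)
  pt <- trial_predictor(trials, trait_pred)
  choice_states <- choice_model(trials, list(states = ps))
  choice_traits <- choice_model(trials, list(traits = pt))
  choice_both <- choice_model(trials, list(states = ps, traits = pt))
  choice_ci <- coefficient_difference_ci(trials, ps, pt, type = "choice",
                                         n_boot = n_boot,
                                         seed = .substream(seed, "boot_choice"))
  rt_states <- rt_model(trials, list(states = ps))
  rt_traits <- rt_model(trials, list(traits = pt))
  rt_both <- rt_model(trials, list(states = ps, traits = pt))
  rt_ci <- coefficient_difference_ci(trials, ps, pt, type = "rt",
                                     n_boot = n_boot,
                                     seed = .substream(seed, "boot_rt"))
  acc_states <- unfitted_choice_accuracy(trials, state_pred)
  acc_traits <- unfitted_choice_accuracy(trials, trait_pred)

  ci_str <- function(ci) sprintf("[%.3g, %.3g]", ci[1L], ci[2L])
  comparison <- rbind(comparison, data.frame(
    measure = c("choices", "choices", "rt", "rt"),
    model = c("states", "traits", "states", "traits"),
    coefficient = c(choice_states$exponentiated[[1L]],
                    choice_traits$exponentiated[[1L]],
                    rt_states$coefficients[[1L]],
                    rt_traits$coefficients[[1L]]),
    p = c(choice_states$p[[1L]], choice_traits$p[[1L]],
          rt_states$p[[1L]], rt_traits$p[[1L]]),
    semi_partial = c(choice_both$exponentiated[["states"]],
                     choice_both$exponentiated[["traits"]],
                     rt_both$coefficients[["states"]],
                     rt_both$coefficients[["traits"]]),
    semi_partial_p = c(choice_both$p[["states"]], choice_both$p[["traits"]],
                       rt_both$p[["states"]], rt_both$p[["traits"]]),
    difference = c(ci_str(choice_ci), "", ci_str(rt_ci), ""),
    bic = NA_real_, stringsAsFactors = FALSE))
  rownames(comparison) <- NULL

  structure(list(
    reconstruction = recon_result,
    comparison = comparison,
    neural_group = list(states = rsa_states, traits = rsa_traits),
    neural_reliability = reliability,
    reliable_variance_share_states = share_states,
    behavior = list(choice = list(states = choice_states,
                                  traits = choice_traits, both = choice_both,
                                  difference_ci = choice_ci),
                    rt = list(states = rt_states, traits = rt_traits,
                              both = rt_both, difference_ci = rt_ci),
                    unfitted_accuracy = list(states = as.numeric(acc_states),
                                             traits = as.numeric(acc_traits))),
    similarities = list(neural = neural_mean, state = state_pred,
                        trait = trait_pred, text = text_dv,
                        rating = dvs$ratings,
                        neural_per_participant = neural_per_p),
    voxel_mask = mask,
    trait_space = tspace,
    provenance = list(seed = seed,
                      package_version = as.character(
                        utils::packageVersion("summedstates")),
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("== summed-state pipeline report ==\n")
  print(x$reconstruction)
  cat(sprintf("neural reliability %.3f; states explain %.1f%% of reliable neural variance\n",
              x$neural_reliability, 100 * x$reliable_variance_share_states))
  cat(sprintf("unfitted choice accuracy: states %.3f, traits %.3f\n",
              x$behavior$unfitted_accuracy$states,
              x$behavior$unfitted_accuracy$traits))
  cat("\ncomparison table:\n")
  print(x$comparison, digits = 3)
  invisible(x)
}

#' Serialize a run report
#'
#' Writes `report.json` (the full report, minus the bulky per-participant
#' similarity vectors), `comparison.csv` (the model-comparison table), and
#' `per_participant.csv` (reconstruction summaries per participant).
#'
#' @param report A `"run_report"` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$comparison, file.path(dir, "comparison.csv"),
                   row.names = FALSE)
  rec <- report$reconstruction
  utils::write.csv(data.frame(
    participant = seq_len(rec$n_participants),
    matched = rec$per_participant_matched,
    unmatched = rec$per_participant_unmatched,
    difference = rec$per_participant_difference),
    file.path(dir, "per_participant.csv"), row.names = FALSE)
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Convert a run report to a plain list for serialization
#'
#' @param report A `"run_report"`.
#' @param include_timestamp Keep the provenance timestamp (set `FALSE` when
#'   comparing reports across invocations).
#' @return A nested list of plain vectors suitable for JSON encoding.
#' @export
report_to_list <- function(report, include_timestamp = TRUE) {
  stopifnot(inherits(report, "run_report"))
  strip <- function(x) {
    if (inherits(x, "condensed_similarity")) return(NULL)
    if (is.list(x)) {
      out <- lapply(x, strip)
      out[!vapply(out, is.null, logical(1))]
    } else if (is.numeric(x) || is.character(x) || is.logical(x)) {
      attributes(x) <- attributes(x)["names"]
      x
    } else {
      NULL
    }
  }
  out <- list(
    reconstruction = strip(unclass(report$reconstruction)),
    comparison = report$comparison,
    neural_group = lapply(report$neural_group,
                          function(g) strip(unclass(g))),
    neural_reliability = report$neural_reliability,
    reliable_variance_share_states = report$reliable_variance_share_states,
    behavior = strip(lapply(report$behavior, function(b) {
      if (is.list(b)) lapply(b, function(e) {
        if (inherits(e, "behavior_model_result")) unclass(e) else e
      }) else b
    })),
    provenance = report$provenance)
  if (!include_timestamp) out$provenance$timestamp <- NULL
  out
}
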