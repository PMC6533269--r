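#' Construct a triadic similarity choice trial table
#'
#' One row per trial of the triadic similarity task: a reference target and
#' two options, the side chosen as more similar to the reference, and the
#' response time in milliseconds.
#'
#' @param x Data frame with columns `participant_id`, `reference`,
#'   `option_a`, `option_b`, `choice` (`"A"` or `"B"`), `rt_ms` (finite,
#'   positive).
#' @return The validated data frame with class `"choice_trial_table"`.
#' @export
choice_trial_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("participant_id", "reference", "option_a", "option_b",
            "choice", "rt_ms")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(sprintf("choice table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(x) == 0L) stop("choice table is empty", call. = FALSE)
  if (!all(x$choice %in% c("A", "B"))) {
    stop("`choice` must be 'A' or 'B'", call. = FALSE)
  }
  if (any(!is.finite(x$rt_ms)) || any(x$rt_ms <= 0)) {
    stop("`rt_ms` must be finite and positive", call. = FALSE)
  }
  same <- x$reference == x$option_a | x$reference == x$option_b |
    x$option_a == x$option_b
  if (any(same)) {
    stop(sprintf("%d trial(s) have non-distinct targets", sum(same)),
         call. = FALSE)
  }
  class(x) <- c("choice_trial_table", "data.frame")
  x
}

#' Filter implausibly fast trials and inattentive participants
#'
#' First drops entire participants whose fraction of trials faster than
#' `rt_floor_ms` (computed before any trial removal) exceeds
#' `fast_fraction_cutoff`, then drops individual trials with response times
#' strictly below `rt_floor_ms`. A trial at exactly the floor is retained.
#'
#' @param t A [choice_trial_table()].
#' @param rt_floor_ms Minimum plausible response time in ms (default 500).
#' @param fast_fraction_cutoff Participants with a larger fraction of
#'   too-fast trials are removed entirely (default 0.9).
#' @return The filtered table, with attributes `n_participants_removed` and
#'   `n_trials_removed`.
#' @export
filter_trials <- function(t, rt_floor_ms = 500, fast_fraction_cutoff = 0.9) {
  stopifnot(inherits(t, "choice_trial_table"))
  fast <- t$rt_ms < rt_floor_ms
  frac <- tapply(fast, t$participant_id, mean)
  bad_p <- names(frac)[frac > fast_fraction_cutoff]
  keep_p <- !(t$participant_id %in% bad_p)
  out <- t[keep_p & !fast, , drop = FALSE]
  if (nrow(out) == 0L) stop("no trials left after filtering", call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("choice_trial_table", "data.frame")
  attr(out, "n_participants_removed") <- length(bad_p)
  attr(out, "n_trials_removed") <- nrow(t) - nrow(out)
  out
}

#' Per-trial similarity-difference predictor
#'
#' For each trial, the similarity of option A to the reference minus the
#' similarity of option B to the reference, under a given similarity model.
#' Returned raw; models standardize it across trials before fitting.
#'
#' @param t A [choice_trial_table()].
#' @param sim A [condensed_similarity()] covering all targets in the table.
#' @return Numeric vector, one raw predictor value per trial.
#' @export
trial_predictor <- function(t, sim) {
  stopifnot(inherits(t, "choice_trial_table"),
            inherits(sim, "condensed_similarity"))
  labs <- attr(sim, "target_labels")
  used <- unique(c(t$reference, t$option_a, t$option_b))
  miss <- setdiff(used, labs)
  if (length(miss)) {
    stop(sprintf("targets missing from similarity labels: %s",
                 paste(utils::head(miss, 5L), collapse = ", ")), call. = FALSE)
  }
  m <- similarity_matrix(sim, diag_value = NA_real_)
  m[cbind(t$option_a, t$reference)] - m[cbind(t$option_b, t$reference)]
}

.standardize_predictors <- function(predictors, n_trials) {
  if (is.numeric(predictors)) predictors <- list(predictor = predictors)
  stopifnot(is.list(predictors), length(predictors) >= 1L,
            length(predictors) <= 2L)
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    names(predictors) <- paste0("pred", seq_along(predictors))
  }
  X <- do.call(cbind, predictors)
  if (nrow(X) != n_trials) {
    stop("predictor length does not match number of trials", call. = FALSE)
  }
  sds <- .col_sds(X)
  if (any(sds <= 0)) stop("constant predictor", call. = FALSE)
  if (ncol(X) == 2L && abs(stats::cor(X[, 1L], X[, 2L])) > 0.999) {
    stop("predictors are collinear", call. = FALSE)
  }
  scale(X)
}

#' Logistic model of triadic similarity choices
#'
#' Binomial regression with logit link of choosing option A on one or two
#' standardized similarity-difference predictors, fitted across all trials
#' (fixed effects; group-level uncertainty is handled by the participant
#' bootstrap, see [coefficient_difference_ci()]). Coefficients are reported
#' raw and exponentiated (odds per predictor SD), with large-sample normal
#' p-values.
#'
#' @param t A filtered [choice_trial_table()] with at least 2 participants.
#' @param predictors Numeric vector, or named list of one or two numeric
#'   vectors (one value per trial), typically from [trial_predictor()].
#' @return Object of class `"behavior_model_result"`.
#' @export
choice_model <- function(t, predictors) {
  stopifnot(inherits(t, "choice_trial_table"))
  if (length(unique(t$participant_id)) < 2L) {
    stop("need at least 2 participants", call. = FALSE)
  }
  X <- .standardize_predictors(predictors, nrow(t))
  y <- as.integer(t$choice == "A")
  dat <- data.frame(y = y, X)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  if (sep || any(abs(stats::coef(fit)[-1L]) > 15)) {
    stop(paste("complete (or quasi-complete) separation in the choice model;",
               "consider unfitted_choice_accuracy() instead"), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  coefs <- sm[-1L, "Estimate"]
  names(coefs) <- colnames(X)
  ps <- sm[-1L, "Pr(>|z|)"]
  names(ps) <- colnames(X)
  structure(list(model = if (ncol(X) == 2L) "both" else colnames(X)[1L],
                 type = "choice",
                 coefficients = coefs,
                 exponentiated = exp(coefs),
                 se = stats::setNames(sm[-1L, "Std. Error"], colnames(X)),
                 p = ps,
                 n_trials = nrow(t),
                 n_participants = length(unique(t$participant_id))),
            class = "behavior_model_result")
}

#' Linear model of log reaction times
#'
#' Least-squares regression of log-transformed response times on one or two
#' standardized similarity-difference predictors. Reported coefficients are
#' fully standardized (predictors and log-RT z-scored); `log_coefficients`
#' give the change in log-RT per predictor SD, with their standard errors
#' and t-test p-values.
#'
#' @inheritParams choice_model
#' @return Object of class `"behavior_model_result"`.
#' @export
rt_model <- function(t, predictors) {
  stopifnot(inherits(t, "choice_trial_table"))
  if (any(t$rt_ms <= 0)) stop("non-positive RT reached rt_model", call. = FALSE)
  X <- .standardize_predictors(predictors, nrow(t))
  y <- log(t$rt_ms)
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)$coefficients
  raw <- sm[-1L, "Estimate"]
  names(raw) <- colnames(X)
  ps <- stats::setNames(sm[-1L, "Pr(>|t|)"], colnames(X))
  structure(list(model = if (ncol(X) == 2L) "both" else colnames(X)[1L],
                 type = "rt",
                 coefficients = raw / stats::sd(y),
                 log_coefficients = raw,
                 se = stats::setNames(sm[-1L, "Std. Error"], colnames(X)),
                 p = ps,
                 n_trials = nrow(t),
                 n_participants = length(unique(t$participant_id))),
            class = "behavior_model_result")
}

#' @export
print.behavior_model_result <- function(x, ...) {
  cat(sprintf("<behavior_model_result> %s model (%s), %d trials, %d participants\n",
              x$type, x$model, x$n_trials, x$n_participants))
  tab <- data.frame(coefficient = x$coefficients, p = x$p)
  if (!is.null(x$exponentiated)) tab$odds <- x$exponentiated
  print(tab)
  invisible(x)
}

#' Participant-bootstrap CI for the difference of two predictor coefficients
#'
#' Refits the two-predictor choice or reaction-time model on resamples of
#' participants drawn with replacement, records the difference of the two
#' standardized coefficients (first minus second), and returns the 2.5th to
#' 97.5th percentile interval. This replaces mixed-effects contrasts:
#' clustering by participant in the resampling captures the participant-
#' level dependence that random effects would model.
#'
#' @param t A filtered [choice_trial_table()].
#' @param pred1,pred2 Per-trial predictor vectors (see [trial_predictor()]).
#' @param type `"choice"` for the logistic model, `"rt"` for the log-RT
#'   model.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed; the interval is fully determined by it.
#' @return Numeric length-2 interval `c(lower, upper)` with attributes
#'   `n_failed` and `estimate` (the full-sample coefficient difference).
#' @export
coefficient_difference_ci <- function(t, pred1, pred2,
                                      type = c("choice", "rt"),
                                      n_boot = 1000L, seed = 1L) {
  type <- match.arg(type)
  stopifnot(inherits(t, "choice_trial_table"))
  n_boot <- .assert_count(n_boot, "n_boot", min = 10L)
  fit_fun <- if (type == "choice") choice_model else rt_model
  full <- fit_fun(t, list(pred1 = pred1, pred2 = pred2)) # errors on collinearity/separation
  est <- unname(full$coefficients[1L] - full$coefficients[2L])

  ids <- unique(t$participant_id)
  by_id <- split(seq_len(nrow(t)), t$participant_id)
  diffs <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample(ids, length(ids), replace = TRUE)
      rows <- unlist(by_id[as.character(take)], use.names = FALSE)
      tb <- t[rows, , drop = FALSE]
      # resampled participants get fresh ids so clusters stay distinct
      tb$participant_id <- rep(seq_along(take),
                               times = lengths(by_id[as.character(take)]))
      class(tb) <- c("choice_trial_table", "data.frame")
      fit <- tryCatch(fit_fun(tb, list(pred1 = pred1[rows],
                                       pred2 = pred2[rows])),
                      error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      unname(fit$coefficients[1L] - fit$coefficients[2L])
    }, numeric(1))
  })
  n_failed <- sum(is.na(diffs))
  if (n_failed > 0.1 * n_boot) {
    stop(sprintf("%d of %d bootstrap refits failed", n_failed, n_boot),
         call. = FALSE)
  }
  ci <- unname(stats::quantile(diffs, c(0.025, 0.975), na.rm = TRUE))
  attr(ci, "n_failed") <- n_failed
  attr(ci, "estimate") <- est
  ci
}

#' Unfitted choice accuracy of a similarity model
#'
#' The fraction of trials on which the chosen option has strictly higher
#' similarity to the reference under the model -- a fit-free measure of how
#' well a similarity account predicts choices (0.5 is chance). Trials on
#' which the two options are exactly tied are excluded from both numerator
#' and denominator, with the count reported.
#'
#' @param t A filtered [choice_trial_table()].
#' @param sim A [condensed_similarity()] covering all targets.
#' @return Proportion in `[0, 1]` with attribute `n_ties`.
#' @export
unfitted_choice_accuracy <- function(t, sim) {
  d <- trial_predictor(t, sim)
  tied <- d == 0
  if (all(tied)) stop("all trials tied under the similarity model", call. = FALSE)
  agree <- (t$choice == "A" & d > 0) | (t$choice == "B" & d < 0)
  acc <- mean(agree[!tied])
  attr(acc, "n_ties") <- sum(tied)
  acc
}
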