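#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the generative model that emulates the study
#' design: a pool of imaging participants viewing mental states and target
#' people, online raters judging state frequencies, trait ratings derived
#' from habitual states, biographical word-count documents, and a triadic
#' similarity choice task. Identical configurations (including `seed`)
#' produce bit-identical data.
#'
#' Defaults mirror the study conditions: 60 famous targets, 15 mental
#' states, 29 person-study and 28 state-study imaging participants, 644
#' online raters, 103 behavioral participants completing 50 trials each, and
#' 13 trait scales. The voxel count defaults to 500 standardized social-
#' brain-network voxels (a scaled-down pattern length; pattern correlations
#' are already stable at this dimensionality).
#'
#' @param n_voxels,n_states,n_targets Pattern length, number of mental
#'   states, number of target people.
#' @param n_state_participants,n_person_participants Imaging sample sizes
#'   for the state study and the person study.
#' @param n_raters Online raters providing state-frequency ratings.
#' @param n_behavior_participants,trials_per_participant Triadic choice task
#'   sample size and trials per participant.
#' @param participant_noise_sd SD of i.i.d. measurement noise added to each
#'   imaging participant's patterns (pattern units; true patterns have unit
#'   voxel variance).
#' @param rater_noise_sd SD of per-rater noise on frequency ratings (rating
#'   units; true weights average `1/n_states`).
#' @param trait_noise_sd SD of trait-rating noise -- the knob controlling
#'   how much independent (non-state) information traits carry.
#' @param residual_signal_sd SD of true person-pattern signal not explained
#'   by the summed states.
#' @param choice_slope Logistic slope on the raw similarity difference in
#'   the choice model.
#' @param rt_base_ms Median response time in ms.
#' @param rt_sd_log SD of log response times around their conditional mean.
#' @param rt_sim_slope Change in expected log-RT per SD of absolute
#'   similarity difference (negative: easier discriminations are faster).
#' @param vocab_size,doc_length Bag-of-words vocabulary size and per-target
#'   document length (tokens).
#' @param text_noise_sd SD of noise on the word-probability construction.
#' @param sim_rating_noise_sd Per-rater noise SD on pairwise similarity
#'   judgments.
#' @param sim_rating_distortion_sd SD of the shared (systematic, non-state)
#'   component of pairwise similarity judgments.
#' @param dirichlet_conc Concentration of the symmetric Dirichlet from which
#'   true state-frequency profiles are drawn (1 = uniform on the simplex).
#' @param n_traits Number of trait scales generated.
#' @param seed Integer seed; fans out to named substreams per stage.
#' @return A validated list of class `"generator_config"`.
#' @export
generator_config <- function(n_voxels = 500L, n_states = 15L,
                             n_targets = 60L,
                             n_state_participants = 28L,
                             n_person_participants = 29L,
                             n_raters = 644L,
                             n_behavior_participants = 103L,
                             trials_per_participant = 50L,
                             participant_noise_sd = 1,
                             rater_noise_sd = 0.05,
                             trait_noise_sd = 0.5,
                             residual_signal_sd = 0.5,
                             choice_slope = 2.5,
                             rt_base_ms = 1500,
                             rt_sd_log = 0.35,
                             rt_sim_slope = -0.1,
                             vocab_size = 200L,
                             doc_length = 2000L,
                             text_noise_sd = 0.1,
                             sim_rating_noise_sd = 0.5,
                             sim_rating_distortion_sd = 0.3,
                             dirichlet_conc = 1,
                             n_traits = 13L,
                             seed = 1L) {
  cfg <- list(
    n_voxels = .assert_count(n_voxels, "n_voxels"),
    n_states = .assert_count(n_states, "n_states"),
    n_targets = .assert_count(n_targets, "n_targets"),
    n_state_participants = .assert_count(n_state_participants,
                                         "n_state_participants"),
    n_person_participants = .assert_count(n_person_participants,
                                          "n_person_participants"),
    n_raters = .assert_count(n_raters, "n_raters"),
    n_behavior_participants = .assert_count(n_behavior_participants,
                                            "n_behavior_participants"),
    trials_per_participant = .assert_count(trials_per_participant,
                                           "trials_per_participant"),
    participant_noise_sd = .assert_nonneg_scalar(participant_noise_sd,
                                                 "participant_noise_sd"),
    rater_noise_sd = .assert_nonneg_scalar(rater_noise_sd, "rater_noise_sd"),
    trait_noise_sd = .assert_nonneg_scalar(trait_noise_sd, "trait_noise_sd"),
    residual_signal_sd = .assert_nonneg_scalar(residual_signal_sd,
                                               "residual_signal_sd"),
    choice_slope = .assert_finite_scalar(choice_slope, "choice_slope"),
    rt_base_ms = .assert_nonneg_scalar(rt_base_ms, "rt_base_ms"),
    rt_sd_log = .assert_nonneg_scalar(rt_sd_log, "rt_sd_log"),
    rt_sim_slope = .assert_finite_scalar(rt_sim_slope, "rt_sim_slope"),
    vocab_size = .assert_count(vocab_size, "vocab_size"),
    doc_length = .assert_count(doc_length, "doc_length"),
    text_noise_sd = .assert_nonneg_scalar(text_noise_sd, "text_noise_sd"),
    sim_rating_noise_sd = .assert_nonneg_scalar(sim_rating_noise_sd,
                                                "sim_rating_noise_sd"),
    sim_rating_distortion_sd = .assert_nonneg_scalar(
      sim_rating_distortion_sd, "sim_rating_distortion_sd"),
    dirichlet_conc = .assert_nonneg_scalar(dirichlet_conc, "dirichlet_conc"),
    n_traits = .assert_count(n_traits, "n_traits"),
    seed = .assert_count(seed, "seed", min = 0L))
  if (cfg$dirichlet_conc <= 0) {
    stop("`dirichlet_conc` must be positive", call. = FALSE)
  }
  if (cfg$vocab_size < cfg$n_states) {
    stop("`vocab_size` must be at least `n_states`", call. = FALSE)
  }
  class(cfg) <- "generator_config"
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> %d voxels, %d states, %d targets; %d/%d imaging, %d raters, %d behavioral participants (seed %d)\n",
    x$n_voxels, x$n_states, x$n_targets, x$n_state_participants,
    x$n_person_participants, x$n_raters, x$n_behavior_participants, x$seed))
  invisible(x)
}

.state_names <- function(n) sprintf("state%02d", seq_len(n))
.target_names <- function(n) sprintf("target%02d", seq_len(n))
.trait_names <- function(n) {
  base <- c("agency", "experience", "warmth", "competence", "trustworthiness",
            "dominance", "openness", "conscientiousness", "extraversion",
            "agreeableness", "neuroticism", "intelligence", "attractiveness")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("trait%02d", seq_len(n - length(base))))
}

# Balance a positive matrix so rows sum to 1 and all column sums are equal
# (Sinkhorn scaling). A matrix with equal column sums is a fixed point of
# the dual normalization (columns then rows), so reconstruction weights
# derived from noise-free ratings reproduce the generating weights exactly.
.balance_weights <- function(w, tol = 1e-13, max_iter = 1000L) {
  target_col <- nrow(w) / ncol(w)
  for (i in seq_len(max_iter)) {
    w <- w / rowSums(w)
    cs <- colSums(w)
    if (max(abs(cs - target_col)) < tol) break
    w <- sweep(w, 2L, cs / target_col, "/")
  }
  w / rowSums(w)
}

#' Generate ground-truth neural data
#'
#' Draws the generative skeleton of the study: true mental-state patterns
#' (independent standard-normal voxel values, column-standardized so each
#' true pattern has exactly mean 0 and unit sample SD), true state-frequency
#' weight rows (symmetric Dirichlet draws, balanced so that the dual
#' normalization used in the analysis leaves them unchanged), true person
#' patterns as weighted sums of state patterns plus optional residual
#' signal, and per-participant observations of both with additive i.i.d.
#' noise.
#'
#' @param config A [generator_config()].
#' @return List with components `truth` (class `"synthetic_truth"`:
#'   `true_state_patterns`, `true_weights`, `true_person_patterns`,
#'   `true_trait_loadings`, `true_state_similarity`, and
#'   `true_person_similarity`, the noise-free neural similarity),
#'   `state_patterns` (list of per-participant [pattern_matrix()]), and
#'   `person_patterns` (likewise).
#' @export
generate_neural <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  v <- config$n_voxels
  s <- config$n_states
  t_ <- config$n_targets
  vox <- sprintf("v%04d", seq_len(v))
  states <- .state_names(s)
  targets <- .target_names(t_)

  .with_seed(.substream(config$seed, "neural"), {
    S <- matrix(stats::rnorm(v * s), v, s)
    S <- scale(S) # exact mean 0 / sd 1 per state pattern
    attr(S, "scaled:center") <- attr(S, "scaled:scale") <- NULL
    dimnames(S) <- list(vox, states)

    W <- matrix(stats::rgamma(t_ * s, shape = config$dirichlet_conc), t_, s)
    W <- .balance_weights(W)
    dimnames(W) <- list(targets, states)

    P <- S %*% t(W)
    if (config$residual_signal_sd > 0) {
      P <- P + matrix(stats::rnorm(v * t_, sd = config$residual_signal_sd),
                      v, t_)
    }
    dimnames(P) <- list(vox, targets)

    noisy <- function(m, pid) {
      obs <- m
      if (config$participant_noise_sd > 0) {
        obs <- obs + matrix(stats::rnorm(length(m),
                                         sd = config$participant_noise_sd),
                            nrow(m), ncol(m))
      }
      pattern_matrix(obs, condition_labels = colnames(m),
                     voxel_ids = rownames(m), participant_id = pid)
    }
    state_sets <- lapply(seq_len(config$n_state_participants),
                         function(p) noisy(S, sprintf("state_p%02d", p)))
    person_sets <- lapply(seq_len(config$n_person_participants),
                          function(p) noisy(P, sprintf("person_p%02d", p)))

    truth <- structure(list(
      true_state_patterns = pattern_matrix(S),
      true_weights = weight_matrix(W, normalized = TRUE),
      true_person_patterns = pattern_matrix(P),
      true_trait_loadings = matrix(stats::rnorm(s * config$n_traits), s,
                                   config$n_traits,
                                   dimnames = list(states,
                                                   .trait_names(config$n_traits))),
      true_state_similarity = state_similarity(weight_matrix(W)),
      true_person_similarity = neural_similarity(pattern_matrix(P))),
      class = "synthetic_truth")
    list(truth = truth, state_patterns = state_sets,
         person_patterns = person_sets)
  })
}

#' Generate averaged state-frequency ratings
#'
#' Each online rater reports the true frequency profile of every target plus
#' independent normal noise, clipped at zero (the rating scale has no
#' negative frequencies); ratings are averaged across raters.
#'
#' @param truth A `synthetic_truth` from [generate_neural()].
#' @param config The same [generator_config()].
#' @return A raw (non-normalized) [weight_matrix()] of averaged ratings.
#' @export
generate_ratings <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(config, "generator_config"))
  W <- unclass(truth$true_weights)
  .with_seed(.substream(config$seed, "ratings"), {
    acc <- matrix(0, nrow(W), ncol(W))
    for (r in seq_len(config$n_raters)) {
      obs <- W
      if (config$rater_noise_sd > 0) {
        obs <- obs + matrix(stats::rnorm(length(W), sd = config$rater_noise_sd),
                            nrow(W), ncol(W))
      }
      acc <- acc + pmax(obs, 0)
    }
    weight_matrix(acc / config$n_raters, rownames(W), colnames(W),
                  normalized = FALSE)
  })
}

#' Generate trait ratings from habitual state frequencies
#'
#' Trait values are noisy linear functions of each target's log state
#' frequencies: `traits = log(pmax(weights, 1e-6)) %*% loadings + noise`.
#' With `trait_noise_sd = 0`, traits carry no information beyond the state
#' frequencies -- the configuration under which the summed-state account
#' should fully mediate trait effects downstream.
#'
#' @inheritParams generate_ratings
#' @return Numeric targets-by-`n_traits` matrix with trait column names.
#' @export
generate_traits <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(config, "generator_config"))
  W <- unclass(truth$true_weights)
  L <- truth$true_trait_loadings
  .with_seed(.substream(config$seed, "traits"), {
    tr <- log(pmax(W, 1e-6)) %*% L
    if (config$trait_noise_sd > 0) {
      tr <- tr + matrix(stats::rnorm(length(tr), sd = config$trait_noise_sd),
                        nrow(tr), ncol(tr))
    }
    tr
  })
}

#' Generate triadic similarity choices and response times
#'
#' Each behavioral participant completes trials with three distinct randomly
#' sampled targets (one reference, two options). The probability of choosing
#' option A is `plogis(choice_slope * (sim(A, ref) - sim(B, ref)))`; response
#' times are lognormal with median `rt_base_ms`, log-SD `rt_sd_log`, and an
#' expected log-RT that changes by `rt_sim_slope` per SD of absolute
#' similarity difference (easy discriminations are faster).
#'
#' @param state_sim A [condensed_similarity()] defining the similarity
#'   structure driving choices (usually `truth$true_state_similarity`).
#' @param config A [generator_config()] (needs at least 3 targets).
#' @return A [choice_trial_table()].
#' @export
generate_behavior <- function(state_sim, config) {
  stopifnot(inherits(state_sim, "condensed_similarity"),
            inherits(config, "generator_config"))
  labs <- attr(state_sim, "target_labels")
  if (length(labs) < 3L) stop("need at least 3 targets", call. = FALSE)
  m <- similarity_matrix(state_sim, diag_value = NA_real_)
  n_p <- config$n_behavior_participants
  n_tr <- config$trials_per_participant
  total <- n_p * n_tr
  .with_seed(.substream(config$seed, "behavior"), {
    triads <- t(replicate(total, sample(labs, 3L)))
    ref <- triads[, 1L]; oa <- triads[, 2L]; ob <- triads[, 3L]
    d <- m[cbind(oa, ref)] - m[cbind(ob, ref)]
    p_a <- stats::plogis(config$choice_slope * d)
    choice <- ifelse(stats::runif(total) < p_a, "A", "B")
    ad <- abs(d)
    z_ad <- if (stats::sd(ad) > 0) (ad - mean(ad)) / stats::sd(ad) else ad * 0
    log_rt <- log(config$rt_base_ms) + config$rt_sim_slope * z_ad +
      stats::rnorm(total, sd = config$rt_sd_log)
    choice_trial_table(data.frame(
      participant_id = rep(sprintf("behav_p%03d", seq_len(n_p)), each = n_tr),
      reference = ref, option_a = oa, option_b = ob,
      choice = choice, rt_ms = exp(log_rt),
      stringsAsFactors = FALSE))
  })
}

#' Generate bag-of-words token counts per target
#'
#' Builds a word-probability vector for each target as a noisy linear map of
#' its true state-frequency profile (a common states-by-vocabulary topic
#' matrix, plus noise, floored and renormalized), then draws multinomial
#' token counts of length `doc_length`. Document distances therefore track
#' true state distances.
#'
#' @inheritParams generate_ratings
#' @return Non-negative targets-by-vocabulary count matrix (row sums equal
#'   `doc_length`).
#' @export
generate_text <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(config, "generator_config"))
  W <- unclass(truth$true_weights)
  v <- config$vocab_size
  .with_seed(.substream(config$seed, "text"), {
    B <- matrix(stats::rexp(ncol(W) * v), ncol(W), v)
    P <- W %*% B
    if (config$text_noise_sd > 0) {
      P <- P + matrix(stats::rnorm(length(P), sd = config$text_noise_sd),
                      nrow(P), ncol(P))
    }
    P <- pmax(P, 1e-8)
    P <- P / rowSums(P)
    counts <- t(vapply(seq_len(nrow(P)), function(i) {
      as.numeric(stats::rmultinom(1L, config$doc_length, P[i, ]))
    }, numeric(v)))
    dimnames(counts) <- list(rownames(W), sprintf("word%04d", seq_len(v)))
    counts
  })
}

#' Generate averaged pairwise similarity judgments
#'
#' Emulates explicit similarity ratings of target pairs: the population
#' judgment is the true state similarity plus a shared systematic distortion
#' (variance not carried by states), each rater adds independent noise, and
#' ratings are averaged across raters.
#'
#' @inheritParams generate_ratings
#' @return A [condensed_similarity()] of kind `"rating"`.
#' @export
generate_similarity_ratings <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(config, "generator_config"))
  s <- as.numeric(truth$true_state_similarity)
  labs <- attr(truth$true_state_similarity, "target_labels")
  .with_seed(.substream(config$seed, "sim_ratings"), {
    pop <- s + stats::rnorm(length(s), sd = config$sim_rating_distortion_sd)
    noise_mean <- stats::rnorm(length(s),
                               sd = config$sim_rating_noise_sd /
                                 sqrt(config$n_raters))
    condensed_similarity(pop + noise_mean, labs, "rating")
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs every generator stage under one configuration and returns all
#' pipeline inputs together with the ground truth.
#'
#' @param config A [generator_config()].
#' @return List of class `"synthetic_dataset"` with elements `config`,
#'   `truth`, `state_patterns`, `person_patterns`, `ratings`, `traits`,
#'   `text_counts`, `trials`, and `rating_similarity`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  neural <- generate_neural(config)
  structure(list(config = config,
                 truth = neural$truth,
                 state_patterns = neural$state_patterns,
                 person_patterns = neural$person_patterns,
                 ratings = generate_ratings(neural$truth, config),
                 traits = generate_traits(neural$truth, config),
                 text_counts = generate_text(neural$truth, config),
                 trials = generate_behavior(neural$truth$true_state_similarity,
                                            config),
                 rating_similarity = generate_similarity_ratings(neural$truth,
                                                                 config)),
            class = "synthetic_dataset")
}
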