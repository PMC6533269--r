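#' Item-level correlation between two similarity vectors
#'
#' Pearson correlation across target pairs, treating the elements of the
#' condensed similarity vectors as independent units of analysis, with the
#' two-sided parametric p-value.
#'
#' @param dv,pred Aligned [condensed_similarity()] vectors (same targets,
#'   same order).
#' @return List with `r`, `p`, and `n` (number of pairs).
#' @export
item_correlation <- function(dv, pred) {
  stopifnot(inherits(dv, "condensed_similarity"),
            inherits(pred, "condensed_similarity"))
  .check_aligned(dv, pred)
  n <- length(dv)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  ct <- stats::cor.test(as.numeric(dv), as.numeric(pred), method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Semi-partial correlation of a predictor controlling for a competitor
#'
#' Estimates the unique explanatory power of predictor `x` for `dv` when
#' controlling for a competing predictor: `x` is residualized on `control`
#' by least squares (with intercept), and the semi-partial coefficient is
#' the Pearson correlation between `dv` and those residuals. Only the
#' predictor is residualized -- the dependent variable is left intact -- so
#' the coefficient quantifies the variance in `dv` uniquely attributable to
#' `x`. The p-value is the two-sided t test on the coefficient with
#' `n - 3` degrees of freedom (one control variable).
#'
#' @param dv,x,control Aligned [condensed_similarity()] vectors.
#' @return List with `sr`, `p`, and `n`.
#' @export
semi_partial <- function(dv, x, control) {
  stopifnot(inherits(dv, "condensed_similarity"),
            inherits(x, "condensed_similarity"),
            inherits(control, "condensed_similarity"))
  .check_aligned(dv, x, control)
  n <- length(dv)
  if (n < 5L) stop("need at least 5 pairs", call. = FALSE)
  res <- stats::lm.fit(cbind(1, as.numeric(control)), as.numeric(x))$residuals
  if (stats::var(res) < 1e-12) {
    stop("predictor is collinear with the control (no residual variance)",
         call. = FALSE)
  }
  sr <- stats::cor(as.numeric(dv), res)
  df <- n - 3L
  tval <- sr * sqrt(df / (1 - sr^2))
  list(sr = sr, p = 2 * stats::pt(-abs(tval), df), n = n)
}

#' Group-level representational similarity analysis
#'
#' Correlates a model's predicted similarity vector with each participant's
#' measured (e.g., neural) similarity vector, Fisher-transforms the
#' per-participant coefficients, and enters them into a two-sided one-sample
#' t-test against zero. Cohen's d is computed on the Fisher z scale.
#'
#' @param per_participant_dv List of aligned [condensed_similarity()]
#'   vectors, one per participant.
#' @param pred A [condensed_similarity()] prediction.
#' @return Object of class `"group_rsa_result"`: `per_participant_r`,
#'   `mean_z`, `mean_r` (back-transformed), `t`, `p`, `cohens_d`, `n`.
#' @export
group_level_rsa <- function(per_participant_dv, pred) {
  stopifnot(is.list(per_participant_dv), length(per_participant_dv) >= 2L,
            inherits(pred, "condensed_similarity"))
  rs <- vapply(seq_along(per_participant_dv), function(i) {
    dv <- per_participant_dv[[i]]
    stopifnot(inherits(dv, "condensed_similarity"))
    .check_aligned(dv, pred)
    stats::cor(as.numeric(dv), as.numeric(pred))
  }, numeric(1))
  if (any(abs(rs) >= 1)) {
    stop(sprintf("participant %d has |r| = 1; Fisher z is infinite",
                 which(abs(rs) >= 1)[1L]), call. = FALSE)
  }
  z <- atanh(rs)
  if (stats::sd(z) == 0) {
    stop("zero variance of Fisher z across participants", call. = FALSE)
  }
  tt <- stats::t.test(z, mu = 0, alternative = "two.sided")
  structure(list(per_participant_r = rs, mean_z = mean(z),
                 mean_r = tanh(mean(z)),
                 t = unname(tt$statistic), p = tt$p.value,
                 cohens_d = mean(z) / stats::sd(z),
                 n = length(rs)),
            class = "group_rsa_result")
}

#' @export
print.group_rsa_result <- function(x, ...) {
  cat(sprintf("<group_rsa_result> n = %d, mean r = %.3f (z = %.3f), t = %.3f, p = %.3g, d = %.3f\n",
              x$n, x$mean_r, x$mean_z, x$t, x$p, x$cohens_d))
  invisible(x)
}

#' Test the difference of two dependent correlations (Steiger Z)
#'
#' Parametric paired correlation difference test for two predictors
#' correlated with the same dependent variable, using Steiger's (1980)
#' Z-bar-2-star statistic: Fisher z transforms of the two correlations are
#' compared with a covariance term evaluated at the back-transformed mean of
#' the two z values.
#'
#' @param dv,x1,x2 Aligned [condensed_similarity()] vectors; `x1` and `x2`
#'   are the competing predictors sharing `dv`.
#' @return List with `z_stat` (positive when `x1` correlates more strongly
#'   with `dv` than `x2` does), two-sided `p`, the three sample correlations
#'   `r1`, `r2`, `r12`, and `n`.
#' @export
paired_correlation_difference <- function(dv, x1, x2) {
  stopifnot(inherits(dv, "condensed_similarity"),
            inherits(x1, "condensed_similarity"),
            inherits(x2, "condensed_similarity"))
  .check_aligned(dv, x1, x2)
  n <- length(dv)
  if (n < 10L) stop("need at least 10 pairs", call. = FALSE)
  r1 <- stats::cor(as.numeric(dv), as.numeric(x1))
  r2 <- stats::cor(as.numeric(dv), as.numeric(x2))
  r12 <- stats::cor(as.numeric(x1), as.numeric(x2))
  if (any(abs(c(r1, r2)) >= 1)) {
    stop("degenerate input: a correlation with the DV has magnitude 1",
         call. = FALSE)
  }
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  rm_ <- tanh((z1 + z2) / 2) # back-transformed mean correlation
  psi <- r12 * (1 - 2 * rm_^2) - 0.5 * rm_^2 * (1 - 2 * rm_^2 - r12^2)
  cbar <- psi / (1 - rm_^2)^2
  z_stat <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cbar))
  # identical predictors: zero difference over a vanishing variance is 0
  if (!is.finite(z_stat)) z_stat <- if (z1 == z2) 0 else sign(z1 - z2) * Inf
  list(z_stat = z_stat, p = 2 * stats::pnorm(-abs(z_stat)),
       r1 = r1, r2 = r2, r12 = r12, n = n)
}

#' Split-half reliability of a similarity measure
#'
#' Estimates how reliably a group of participants measures the same
#' similarity structure: participants are repeatedly split into random
#' halves, the half-averaged similarity vectors are correlated, the
#' correlation is stepped up with the Spearman-Brown formula
#' `2r / (1 + r)`, and the result is averaged over splits. Used as the
#' noise ceiling for disattenuation.
#'
#' @param per_participant_dv List (length >= 4) of aligned
#'   [condensed_similarity()] vectors.
#' @param n_splits Number of random half-splits (default 20).
#' @param seed Integer seed for the split assignment.
#' @param floor Small positive value substituted (with a warning) when the
#'   average split correlation is not positive.
#' @return Reliability in `(0, 1]`.
#' @export
similarity_reliability <- function(per_participant_dv, n_splits = 20L,
                                   seed = 1L, floor = 1e-3) {
  stopifnot(is.list(per_participant_dv))
  n_p <- length(per_participant_dv)
  if (n_p < 4L) stop("need at least 4 participants", call. = FALSE)
  n_splits <- .assert_count(n_splits, "n_splits", min = 1L)
  do.call(.check_aligned, per_participant_dv)
  mat <- vapply(per_participant_dv, as.numeric,
                numeric(length(per_participant_dv[[1L]])))
  n_half <- n_p %/% 2L
  sb <- .with_seed(seed, vapply(seq_len(n_splits), function(s) {
    idx <- sample.int(n_p)
    m1 <- rowMeans(mat[, idx[seq_len(n_half)], drop = FALSE])
    m2 <- rowMeans(mat[, idx[(n_half + 1L):n_p], drop = FALSE])
    r <- stats::cor(m1, m2)
    2 * r / (1 + r)
  }, numeric(1)))
  rel <- mean(sb)
  if (!is.finite(rel) || rel <= 0) {
    warning("non-positive split-half reliability; flooring at ", floor)
    rel <- floor
  }
  min(rel, 1)
}

#' Disattenuate an item-level correlation by measure reliability
#'
#' Estimates the share of the *reliable* variance in a dependent similarity
#' measure that a predictor explains, by dividing the squared item-level
#' correlation by the measure's split-half reliability.
#'
#' @param item_r Item-level correlation between predictor and measure.
#' @param reliability Reliability of the measure, in `(0, 1]` (see
#'   [similarity_reliability()]).
#' @return Proportion of reliable variance explained (multiply by 100 for
#'   percent). Values above 1 (a sampling artifact) are returned with a
#'   warning.
#' @export
disattenuate <- function(item_r, reliability) {
  .assert_finite_scalar(item_r, "item_r")
  if (length(reliability) != 1L || !is.finite(reliability) ||
      reliability <= 0 || reliability > 1) {
    stop("`reliability` must lie in (0, 1]", call. = FALSE)
  }
  share <- item_r^2 / reliability
  if (share > 1) {
    warning("disattenuated share exceeds 1 (sampling artifact)")
  }
  share
}

#' Bayesian Information Criterion of a similarity regression
#'
#' Ordinary least squares of the dependent similarity vector on one or more
#' predictor vectors (with intercept), scored by the Gaussian BIC
#' `n * log(RSS / n) + k * log(n)` with `k` the number of predictors plus
#' the intercept. Additive constants are dropped consistently, so
#' differences between models fitted to the same `dv` are valid.
#'
#' @param dv A [condensed_similarity()] dependent vector.
#' @param predictors A single `condensed_similarity` or a list of them.
#' @return The BIC (a single finite number).
#' @export
model_bic <- function(dv, predictors) {
  stopifnot(inherits(dv, "condensed_similarity"))
  if (inherits(predictors, "condensed_similarity")) predictors <- list(predictors)
  stopifnot(is.list(predictors), length(predictors) >= 1L)
  do.call(.check_aligned, c(list(dv), predictors))
  n <- length(dv)
  k <- length(predictors) + 1L # predictors + intercept
  if (n <= k) stop("too few pairs for the number of predictors", call. = FALSE)
  X <- cbind(1, do.call(cbind, lapply(predictors, as.numeric)))
  fit <- stats::lm.fit(X, as.numeric(dv))
  if (fit$rank < ncol(X)) stop("rank-deficient design (collinear predictors)",
                               call. = FALSE)
  rss <- sum(fit$residuals^2)
  if (rss < 1e-12) {
    stop("exact fit (RSS ~ 0); BIC is degenerate", call. = FALSE)
  }
  n * log(rss / n) + k * log(n)
}
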