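test_that("item_correlation matches the textbook formula oracle", {
  x <- cs(c(0.2, -0.1, 0.5, 0.3, -0.4, 0.1))
  y <- cs(c(0.1, 0.0, 0.45, 0.2, -0.2, 0.15), kind = "state")
  res <- item_correlation(x, y)
  expect_equal(res$r, oracle_pearson(as.numeric(x), as.numeric(y)),
               tolerance = 1e-12)
  expect_equal(item_correlation(x, x)$r, 1.0, tolerance = 1e-12)
  neg <- cs(-as.numeric(x))
  expect_equal(item_correlation(x, neg)$r, -1.0, tolerance = 1e-12)
  # misaligned labels refuse to correlate
  z <- condensed_similarity(as.numeric(y), paste0("q", 1:4), "state")
  expect_error(item_correlation(x, z), "aligned")
})

test_that("semi_partial equals an explicit two-step residualization oracle", {
  set.seed(7)
  dvv <- rnorm(28); xv <- rnorm(28); cv <- 0.6 * xv + rnorm(28)
  dv <- cs(dvv); x <- cs(xv, "state"); ctl <- cs(cv, "trait")
  res <- semi_partial(dv, x, ctl)
  # oracle: residualize x on control by closed-form simple regression
  b <- sum((xv - mean(xv)) * (cv - mean(cv))) / sum((cv - mean(cv))^2)
  resid_x <- xv - (mean(xv) - b * mean(cv)) - b * cv
  expect_equal(res$sr, oracle_pearson(dvv, resid_x), tolerance = 1e-10)
  # orthogonal control: sr collapses to the zero-order correlation
  cv_orth <- residuals(lm(rnorm(28) ~ xv))
  sr_orth <- semi_partial(dv, x, cs(cv_orth, "trait"))
  expect_equal(sr_orth$sr, cor(dvv, xv), tolerance = 1e-10)
  # x identical to control is degenerate
  expect_error(semi_partial(dv, x, cs(xv, "trait")), "collinear")
})

test_that("semi-partial magnitude never exceeds the zero-order correlation
           when predictor and control are positively correlated", {
  set.seed(17)
  for (i in 1:20) {
    base <- rnorm(36)
    xv <- base + rnorm(36)
    cv <- base + rnorm(36)
    if (cor(xv, cv) <= 0) next
    dvv <- 0.5 * base + rnorm(36)
    sr <- semi_partial(cs(dvv), cs(xv, "state"), cs(cv, "trait"))$sr
    r <- item_correlation(cs(dvv), cs(xv, "state"))$r
    expect_lte(abs(sr), abs(r) + 1e-10)
  }
})

test_that("group_level_rsa matches the closed-form Fisher/t oracle", {
  # participants engineered to have exact correlations with the predictor
  pred_v <- c(1, 2, 3, 4, 5, 6)
  make_dv_with_r <- function(r, seed) {
    set.seed(seed)
    noise <- residuals(lm(rnorm(6) ~ pred_v))
    noise <- noise / sd(noise)
    pv <- scale(pred_v)[, 1]
    cs(r * pv + sqrt(1 - r^2) * noise)
  }
  rs <- c(0.1, 0.2, 0.3)
  dvs <- lapply(seq_along(rs), function(i) make_dv_with_r(rs[i], i))
  res <- group_level_rsa(dvs, cs(pred_v, "state"))
  expect_equal(res$per_participant_r, rs, tolerance = 1e-10)
  z <- atanh(rs)
  t_oracle <- mean(z) / (sd(z) / sqrt(3))
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 2), tolerance = 1e-10)
  expect_equal(res$cohens_d, mean(z) / sd(z), tolerance = 1e-10)
  # symmetric r around 0 -> t = 0, p = 1
  sym <- group_level_rsa(list(make_dv_with_r(-0.2, 5), make_dv_with_r(0.2, 6)),
                         cs(pred_v, "state"))
  expect_equal(sym$mean_z, 0, tolerance = 1e-10)
  expect_equal(sym$p, 1, tolerance = 1e-8)
  # order of participants cannot matter
  perm <- group_level_rsa(dvs[c(3, 1, 2)], cs(pred_v, "state"))
  expect_equal(perm$p, res$p, tolerance = 1e-12)
  # identical r for everyone has zero variance
  expect_error(group_level_rsa(list(make_dv_with_r(0.2, 9),
                                    make_dv_with_r(0.2, 9)),
                               cs(pred_v, "state")), "variance")
})

test_that("paired_correlation_difference behaves like Steiger's Z", {
  set.seed(23)
  n <- 45
  dvv <- rnorm(n); x1v <- 0.5 * dvv + rnorm(n); x2v <- 0.3 * dvv + rnorm(n)
  dv <- cs(dvv); x1 <- cs(x1v, "state"); x2 <- cs(x2v, "trait")
  res <- paired_correlation_difference(dv, x1, x2)
  # identical predictors -> z = 0, p = 1
  same <- paired_correlation_difference(dv, x1, cs(x1v, "trait"))
  expect_equal(same$z_stat, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  # swapping predictors flips the sign, p unchanged
  swap <- paired_correlation_difference(dv, x2, x1)
  expect_equal(swap$z_stat, -res$z_stat, tolerance = 1e-12)
  expect_equal(swap$p, res$p, tolerance = 1e-12)
  # oracle recomputation of the published formula
  r1 <- oracle_pearson(dvv, x1v); r2 <- oracle_pearson(dvv, x2v)
  r12 <- oracle_pearson(x1v, x2v)
  z1 <- atanh(r1); z2 <- atanh(r2); rm_ <- tanh((z1 + z2) / 2)
  psi <- r12 * (1 - 2 * rm_^2) - 0.5 * rm_^2 * (1 - 2 * rm_^2 - r12^2)
  z_or <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * psi / (1 - rm_^2)^2))
  expect_equal(res$z_stat, z_or, tolerance = 1e-10)
})

test_that("similarity_reliability tracks participant noise", {
  set.seed(41)
  signal <- rnorm(45)
  make_group <- function(noise_sd) {
    lapply(1:16, function(p) cs(signal + rnorm(45, sd = noise_sd)))
  }
  # identical participants are perfectly reliable
  ident <- replicate(6, cs(signal), simplify = FALSE)
  expect_equal(similarity_reliability(ident, seed = 1), 1.0, tolerance = 1e-10)
  rels <- sapply(c(0.5, 1.5, 4), function(s)
    similarity_reliability(make_group(s), seed = 2))
  expect_true(all(diff(rels) < 0))
  # pure independent noise: near-zero reliability (floored positive)
  noise_only <- lapply(1:30, function(p) cs(rnorm(45)))
  rel0 <- suppressWarnings(similarity_reliability(noise_only, seed = 3))
  expect_lt(rel0, 0.1)
  expect_gt(rel0, 0)
})

test_that("disattenuate computes r^2 / reliability with guard rails", {
  expect_equal(disattenuate(0.5, 0.5), 0.5)
  expect_equal(disattenuate(0.3, 1), 0.09)
  expect_error(disattenuate(0.5, 0), "reliability")
  expect_warning(disattenuate(0.9, 0.5), "exceeds 1")
})

test_that("model_bic agrees with an independent least-squares oracle", {
  set.seed(53)
  n <- 10
  dvv <- rnorm(n); x1v <- rnorm(n); x2v <- rnorm(n)
  dv <- cs(dvv); x1 <- cs(x1v, "state"); x2 <- cs(x2v, "trait")
  bic1 <- model_bic(dv, x1)
  # oracle: normal equations solved by hand, same BIC formula
  X <- cbind(1, x1v)
  beta <- solve(t(X) %*% X, t(X) %*% dvv)
  rss <- sum((dvv - X %*% beta)^2)
  expect_equal(bic1, n * log(rss / n) + 2 * log(n), tolerance = 1e-8)
  # differences agree with stats::BIC on lm fits (constants cancel)
  bic2 <- model_bic(dv, list(x1, x2))
  lm1 <- lm(dvv ~ x1v); lm2 <- lm(dvv ~ x1v + x2v)
  expect_equal(bic1 - bic2, BIC(lm1) - BIC(lm2), tolerance = 1e-8)
  # degenerate situations
  expect_error(model_bic(dv, list(x1, cs(x1v, "trait"))), "rank")
  exact <- cs(2 * x1v + 1)
  expect_error(model_bic(exact, x1), "exact fit")
})

test_that("adding a pure-noise predictor raises BIC on noise-only data", {
  set.seed(61)
  worse <- 0
  for (i in 1:20) {
    dvv <- rnorm(36)
    x1v <- rnorm(36); x2v <- rnorm(36)
    b1 <- model_bic(cs(dvv), cs(x1v, "state"))
    b2 <- model_bic(cs(dvv), list(cs(x1v, "state"), cs(x2v, "trait")))
    worse <- worse + (b2 > b1)
  }
  expect_gte(worse, 15) # the ln(n) penalty dominates chance fit improvements
})
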