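make_trials <- function(n_participants = 6, n_trials = 40, seed = 1,
                        targets = paste0("t", 1:8), rt_range = c(600, 2500)) {
  set.seed(seed)
  total <- n_participants * n_trials
  tri <- t(replicate(total, sample(targets, 3)))
  choice_trial_table(data.frame(
    participant_id = rep(paste0("p", seq_len(n_participants)), each = n_trials),
    reference = tri[, 1], option_a = tri[, 2], option_b = tri[, 3],
    choice = sample(c("A", "B"), total, replace = TRUE),
    rt_ms = runif(total, rt_range[1], rt_range[2]),
    stringsAsFactors = FALSE))
}

test_that("filter_trials applies the participant rule before the trial rule", {
  # one participant with 19/20 fast trials (95% > 90%): fully removed,
  # including their single slow trial
  t <- make_trials(n_participants = 3, n_trials = 20, seed = 2)
  t$rt_ms[1:19] <- 300            # p1 fast on 19 of 20 trials
  t$rt_ms[20] <- 1200             # p1's one slow trial
  t$rt_ms[21] <- 400              # p2 has a single fast trial
  t$rt_ms[22] <- 500              # exactly at the floor: retained
  out <- filter_trials(t)
  expect_false("p1" %in% out$participant_id)
  expect_equal(attr(out, "n_participants_removed"), 1)
  expect_equal(sum(out$participant_id == "p2"), 19) # lost only the 400 ms trial
  expect_true(500 %in% out$rt_ms[out$participant_id == "p2"])
  expect_equal(attr(out, "n_trials_removed"), 21)
  expect_true(all(out$rt_ms >= 500))
})

test_that("trial_predictor computes similarity differences with antisymmetry", {
  simv <- cs(seq(-0.5, 0.5, length.out = 28), kind = "state") # 8 targets
  t <- make_trials(seed = 3)
  d <- trial_predictor(t, simv)
  m <- similarity_matrix(simv)
  expect_equal(d[1], m[t$option_a[1], t$reference[1]] -
                 m[t$option_b[1], t$reference[1]])
  # swapping the options negates the predictor
  t_sw <- t
  t_sw$option_a <- t$option_b
  t_sw$option_b <- t$option_a
  expect_equal(trial_predictor(t_sw, simv), -d)
  # hand case via a constructed table
  tt <- choice_trial_table(data.frame(
    participant_id = "p", reference = "t1", option_a = "t2", option_b = "t3",
    choice = "A", rt_ms = 1000))
  m2 <- matrix(0, 3, 3, dimnames = list(paste0("t", 1:3), paste0("t", 1:3)))
  m2["t2", "t1"] <- m2["t1", "t2"] <- 0.8
  m2["t3", "t1"] <- m2["t1", "t3"] <- 0.3
  expect_equal(trial_predictor(tt, condense_matrix(m2, "state")), 0.5)
  # unknown target labels are an alignment error
  expect_error(trial_predictor(t, cs(rnorm(6), labels = paste0("x", 1:4))),
               "missing")
})

simulate_choices <- function(t, d, slope, seed) {
  set.seed(seed)
  z <- (d - mean(d)) / sd(d)
  t$choice <- ifelse(runif(nrow(t)) < plogis(slope * z), "A", "B")
  t
}

test_that("choice_model recovers a known slope and rejects degenerate designs", {
  simv <- cs(rnorm(28, sd = 0.4), kind = "state")
  t <- make_trials(n_participants = 25, n_trials = 200, seed = 5)
  d <- trial_predictor(t, simv)
  t <- simulate_choices(t, d, slope = 1.5, seed = 6)
  fit <- choice_model(t, list(states = d))
  expect_lt(abs(fit$coefficients[["states"]] - 1.5), 2 * fit$se[["states"]])
  expect_equal(fit$exponentiated[["states"]],
               exp(fit$coefficients[["states"]]))
  expect_lt(fit$p[["states"]], 1e-6)
  # null slope: coefficient near zero
  t0 <- simulate_choices(t, d, slope = 0, seed = 7)
  fit0 <- choice_model(t0, list(states = d))
  expect_lt(abs(fit0$coefficients[["states"]]), 0.06)
  # duplicated predictor is collinear
  expect_error(choice_model(t, list(a = d, b = d)), "collinear")
  # deterministic choices separate
  t_sep <- t
  t_sep$choice <- ifelse(d > 0, "A", "B")
  expect_error(choice_model(t_sep, list(states = d)), "separation")
})

test_that("rt_model recovers a log-linear slope and is scale invariant", {
  simv <- cs(rnorm(28, sd = 0.4), kind = "state")
  t <- make_trials(n_participants = 25, n_trials = 200, seed = 8)
  d <- trial_predictor(t, simv)
  z <- (d - mean(d)) / sd(d)
  set.seed(9)
  t$rt_ms <- exp(log(1500) - 0.1 * z + rnorm(nrow(t), sd = 0.3))
  fit <- rt_model(t, list(states = d))
  expect_lt(abs(fit$log_coefficients[["states"]] + 0.1), 2 * fit$se[["states"]])
  # unit change of RT leaves standardized coefficients unchanged
  t_ms <- t
  t_ms$rt_ms <- t$rt_ms * 1000
  fit_ms <- rt_model(t_ms, list(states = d))
  expect_equal(fit$coefficients, fit_ms$coefficients, tolerance = 1e-10)
  # null predictor: near-zero standardized coefficient
  set.seed(10)
  t$rt_ms <- exp(log(1500) + rnorm(nrow(t), sd = 0.3))
  fit0 <- rt_model(t, list(states = d))
  expect_lt(abs(fit0$coefficients[["states"]]), 0.05)
})

test_that("consistently relabeling A/B flips nothing that matters", {
  simv <- cs(rnorm(28, sd = 0.4), kind = "state")
  t <- make_trials(n_participants = 10, n_trials = 80, seed = 11)
  d <- trial_predictor(t, simv)
  t <- simulate_choices(t, d, slope = 1, seed = 12)
  t_fl <- t
  t_fl$option_a <- t$option_b
  t_fl$option_b <- t$option_a
  t_fl$choice <- ifelse(t$choice == "A", "B", "A")
  d_fl <- trial_predictor(t_fl, simv)
  f1 <- choice_model(t, list(states = d))
  f2 <- choice_model(t_fl, list(states = d_fl))
  expect_equal(abs(f1$coefficients), abs(f2$coefficients), tolerance = 1e-8)
  expect_equal(unfitted_choice_accuracy(t, simv),
               unfitted_choice_accuracy(t_fl, simv), tolerance = 1e-12)
})

test_that("coefficient_difference_ci is seeded, clustered, and detects a true gap", {
  simv <- cs(rnorm(28, sd = 0.4), kind = "state")
  t <- make_trials(n_participants = 30, n_trials = 100, seed = 13)
  d1 <- trial_predictor(t, simv)
  set.seed(14)
  d2 <- rnorm(nrow(t)) * sd(d1) # pure-noise competitor
  t <- simulate_choices(t, d1, slope = 1, seed = 15)
  ci <- coefficient_difference_ci(t, d1, d2, type = "choice", n_boot = 120,
                                  seed = 3)
  expect_gt(ci[1], 0) # interval excludes zero: states beat the noise predictor
  ci2 <- coefficient_difference_ci(t, d1, d2, type = "choice", n_boot = 120,
                                   seed = 3)
  expect_identical(as.numeric(ci), as.numeric(ci2)) # same seed, same interval
  expect_error(coefficient_difference_ci(t, d1, d1, type = "choice",
                                         n_boot = 50, seed = 1), "collinear")
})

test_that("unfitted_choice_accuracy counts strict agreements and excludes ties", {
  m <- matrix(0, 4, 4, dimnames = list(paste0("t", 1:4), paste0("t", 1:4)))
  m["t2", "t1"] <- m["t1", "t2"] <- 0.9
  m["t3", "t1"] <- m["t1", "t3"] <- 0.1
  m["t4", "t1"] <- m["t1", "t4"] <- 0.1 # t3 and t4 tie against each other
  simv <- condense_matrix(m, "state")
  tt <- choice_trial_table(data.frame(
    participant_id = "p",
    reference = "t1",
    option_a = c("t2", "t2", "t2", "t3", "t3"),
    option_b = c("t3", "t3", "t3", "t2", "t4"),
    choice = c("A", "A", "B", "B", "A"),
    rt_ms = 1000))
  acc <- unfitted_choice_accuracy(tt, simv)
  # 4 informative trials: 3 agree (A,A with t2 higher; B choosing t2) 1 not
  expect_equal(as.numeric(acc), 0.75)
  expect_equal(attr(acc, "n_ties"), 1)
  # all-tied table is undefined
  tt2 <- tt[5, ]
  class(tt2) <- c("choice_trial_table", "data.frame")
  expect_error(unfitted_choice_accuracy(tt2, simv), "tied")
})
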