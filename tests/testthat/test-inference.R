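# Minimal hand-built trial frames for the exclusion rules.
trial_frame <- function(id, condition, opted_out, chose_left, d_left, d_right) {
  n <- length(opted_out)
  data.frame(
    participant_id = id, condition = condition, ballot_index = seq_len(n),
    d_left = d_left, d_right = d_right,
    overall = (d_left + d_right) / 2,
    relative_signed = d_left - d_right,
    relative_unsigned = abs(d_left - d_right),
    opted_out = opted_out, chose_left = chose_left,
    rt_log10 = ifelse(opted_out, NA, 0.5),
    deadline_censored = FALSE
  )
}

test_that("exclusion rules drop never-opt-out and goal-inconsistent participants", {
  n <- 100
  d_hi <- rep(8, n); d_lo <- rep(2, n)
  # never opts out, always consistent -> excluded for rule (1)
  never <- trial_frame("never", "selection", rep(FALSE, n), rep(TRUE, n), d_hi, d_lo)
  # rejection participant choosing the best candidate on 60% of voted ballots
  rej_bad <- trial_frame("rej_bad", "rejection", c(TRUE, rep(FALSE, n - 1)),
                         c(NA, rep(TRUE, 59), rep(FALSE, 40)), d_hi, d_lo)
  # one opt-out, all votes consistent -> retained
  good <- trial_frame("good", "selection", c(TRUE, rep(FALSE, n - 1)),
                      c(NA, rep(TRUE, n - 1)), d_hi, d_lo)
  res <- apply_exclusions(rbind(never, rej_bad, good))
  expect_setequal(res$log$participant_id, c("never", "rej_bad"))
  expect_equal(res$log$reason[res$log$participant_id == "never"], "no_optout")
  expect_equal(res$log$reason[res$log$participant_id == "rej_bad"],
               "goal_inconsistent")
  expect_setequal(unique(res$trials$participant_id), "good")
  # idempotence: a second pass removes nobody
  res2 <- apply_exclusions(res$trials)
  expect_equal(nrow(res2$log), 0)
  expect_equal(nrow(res2$trials), nrow(res$trials))
})

test_that("the 50% inconsistency boundary is inclusive", {
  n <- 10
  half <- trial_frame("half", "selection", c(TRUE, rep(FALSE, n - 1)),
                      c(NA, rep(FALSE, 5), rep(TRUE, 4)),
                      rep(8, n), rep(2, n)) # 5 of 9 voted = 55% inconsistent
  expect_equal(apply_exclusions(half)$log$reason, "goal_inconsistent")
  under <- trial_frame("under", "selection", c(TRUE, TRUE, rep(FALSE, n - 2)),
                       c(NA, NA, rep(FALSE, 3), rep(TRUE, 5)),
                       rep(8, n), rep(2, n)) # 3 of 8 voted = 37.5%
  expect_equal(nrow(apply_exclusions(under)$log), 0)
})

test_that("within-participant standardization has exact moments and inverts", {
  set.seed(11)
  tr <- rbind(
    trial_frame("a", "selection", rep(c(TRUE, FALSE), 10), rep(NA, 20),
                runif(20, 0, 10), runif(20, 0, 10)),
    trial_frame("b", "selection", rep(c(TRUE, FALSE), 10), rep(NA, 20),
                runif(20, 0, 10), runif(20, 0, 10))
  )
  std <- standardize_within_participant(tr)
  for (id in c("a", "b")) {
    d <- std[std$participant_id == id, ]
    for (col in c("overall_std", "relative_signed_std",
                  "relative_unsigned_std", "trial_order_std")) {
      expect_equal(mean(d[[col]]), 0, tolerance = 1e-12)
      expect_equal(sd(d[[col]]), 1, tolerance = 1e-12)
    }
    # affine inverse returns the raw predictor
    expect_equal(d$overall_std * sd(d$overall) + mean(d$overall), d$overall,
                 tolerance = 1e-12)
  }
  # constant predictor is a degenerate input
  flat <- trial_frame("flat", "selection", rep(c(TRUE, FALSE), 5), rep(NA, 10),
                      rep(5, 10), rep(5, 10))
  expect_error(standardize_within_participant(flat), "zero variance")
})

test_that("logistic fit recovers the exact log odds ratio of a 2x2 table", {
  # 40/10 events at x = 1 vs 20/30 at x = 0: OR = (40*30)/(10*20) = 6
  x <- rep(c(1, 0), c(50, 50))
  y <- c(rep(1, 40), rep(0, 10), rep(1, 20), rep(0, 30))
  fit <- fit_logistic(y, cbind(x = x))
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients["x"]), log(6), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(20 / 30),
               tolerance = 1e-8)
})

test_that("logistic fit agrees with a brute-force likelihood grid search", {
  set.seed(13)
  x <- rnorm(400)
  y <- rbinom(400, 1, plogis(0.5 + 1.2 * x))
  fit <- fit_logistic(y, cbind(x = x))
  nll <- function(b0, b1) -sum(y * (b0 + b1 * x) - log(1 + exp(b0 + b1 * x)))
  # iteratively refined grid search, an independent optimizer
  ctr <- c(0, 0); width <- 4
  for (pass in 1:8) {
    b0s <- seq(ctr[1] - width, ctr[1] + width, length.out = 21)
    b1s <- seq(ctr[2] - width, ctr[2] + width, length.out = 21)
    vals <- outer(b0s, b1s, Vectorize(nll))
    ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    ctr <- c(b0s[ix[1]], b1s[ix[2]])
    width <- width / 5
  }
  expect_equal(unname(fit$coefficients), ctr, tolerance = 1e-4)
})

test_that("null slopes are recovered as null and separation is flagged", {
  set.seed(17)
  x <- matrix(rnorm(2e4), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  y <- rbinom(1e4, 1, 0.4)
  fit <- fit_logistic(y, x)
  expect_true(all(abs(fit$z_values[c("a", "b")]) < 3))
  # perfectly separated data
  xs <- c(-(1:20), 1:20)
  ys <- c(rep(0, 20), rep(1, 20))
  sep <- fit_logistic(ys, cbind(x = xs))
  expect_false(sep$converged)
  # rank-deficient design
  expect_error(fit_logistic(y, cbind(a = x[, 1], b = x[, 1])), "rank deficient")
  expect_error(fit_logistic(rep(1, 10), cbind(x = rnorm(10))), "both classes")
})

test_that("condition relabeling flips interaction coefficients exactly", {
  set.seed(19)
  n <- 60
  mk <- function(id, cond) {
    tr <- trial_frame(id, cond, rbinom(n, 1, 0.4) == 1, rep(NA, n),
                      runif(n, 0, 10), runif(n, 0, 10))
    tr$chose_left[!tr$opted_out] <- rbinom(sum(!tr$opted_out), 1, 0.5) == 1
    tr
  }
  tr <- standardize_within_participant(
    rbind(mk("s1", "selection"), mk("s2", "selection"),
          mk("r1", "rejection"), mk("r2", "rejection"))
  )
  fit <- fit_condition_interaction(tr, "optout")
  flipped <- tr
  flipped$condition <- ifelse(tr$condition == "selection", "rejection", "selection")
  fit_f <- fit_condition_interaction(flipped, "optout")
  for (cf in c("condition", "overall_std:condition",
               "relative_unsigned_std:condition")) {
    expect_equal(unname(fit$coefficients[cf]), -unname(fit_f$coefficients[cf]),
                 tolerance = 1e-8)
  }
  for (cf in c("(Intercept)", "overall_std", "relative_unsigned_std")) {
    expect_equal(unname(fit$coefficients[cf]), unname(fit_f$coefficients[cf]),
                 tolerance = 1e-8)
  }
  expect_error(fit_condition_interaction(tr[tr$condition == "selection", ]),
               "both conditions")
})

test_that("quartile summary bins evenly and handles the all-opt-out edge", {
  set.seed(23)
  tr <- rbind(
    trial_frame("a", "selection", rep(TRUE, 100), rep(NA, 100),
                runif(100, 0, 10), runif(100, 0, 10)),
    trial_frame("b", "selection", rep(TRUE, 100), rep(NA, 100),
                runif(100, 0, 10), runif(100, 0, 10))
  )
  qs <- quartile_optout_summary(tr)
  expect_equal(qs$rate, rep(1, 4))
  expect_equal(qs$ci_hi - qs$ci_lo, rep(0, 4))
  expect_equal(qs$n_trials, rep(50, 4)) # 25 per participant per quartile
  expect_equal(qs$quartile, 1:4)
})

test_that("quartile rates order by desirability under the selection agent", {
  set.seed(29)
  # direct construction: opt-out probability falls with overall desirability
  mk <- function(id) {
    d_left <- runif(100, 0, 10); d_right <- runif(100, 0, 10)
    ov <- (d_left + d_right) / 2
    po <- plogis(-0.4 - 2.7 * as.numeric(scale(ov)))
    trial_frame(id, "selection", rbinom(100, 1, po) == 1, rep(NA, 100),
                d_left, d_right)
  }
  tr <- rbind(mk("a"), mk("b"), mk("c"), mk("d"), mk("e"), mk("f"))
  qs <- quartile_optout_summary(tr)
  expect_true(all(diff(qs$rate) < 0))
  # pooled binning is also available and bins evenly overall
  qp <- quartile_optout_summary(tr, pooled = TRUE)
  expect_equal(qp$n_trials, rep(150, 4))
})

test_that("recovery harness reports sensible structure on a small run", {
  rec <- recovery_experiment(agent_params("selection"), n_agents = 5,
                             n_ballots = 20, n_reps = 3, seed = 99)
  expect_setequal(unique(rec$report$model), c("optout", "choice"))
  expect_true(all(is.finite(rec$report$bias)))
  expect_true(all(rec$report$coverage >= 0 & rec$report$coverage <= 1))
  expect_equal(nrow(rec$report), 8) # 4 coefficients x 2 models
  expect_true(all(rec$estimates$rep %in% 1:3))
})
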