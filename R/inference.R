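#' Apply the participant-level exclusion rules
#'
#' Drops (1) participants who voted on every ballot without opting out
#' once, and (2) participants who, on half or more of the ballots where
#' they voted, chose the candidate inconsistent with their assigned goal —
#' under selection, choosing the strictly less desirable candidate; under
#' rejection, rejecting the strictly more desirable one. Deadline-censored
#' ballots carry no choice and do not enter the consistency denominator.
#'
#' The rules are idempotent: re-applying them to the retained data removes
#' no one further.
#'
#' @param trials Trial data frame (see [simulate_dataset()]).
#' @return A list with `trials` (retained rows) and `log` (data frame of
#'   `participant_id`, `condition`, `reason` for each exclusion; reasons
#'   are `"no_optout"` and `"goal_inconsistent"`).
#' @export
apply_exclusions <- function(trials) {
  if (!nrow(trials)) stop("empty trial data")
  by_p <- split(trials, trials$participant_id)
  verdict <- lapply(by_p, function(d) {
    if (sum(d$opted_out) == 0) return("no_optout")
    voted <- d[!d$opted_out & !d$deadline_censored, , drop = FALSE]
    if (nrow(voted)) {
      chose_higher <- ifelse(voted$chose_left,
                             voted$d_left > voted$d_right,
                             voted$d_right > voted$d_left)
      chose_lower <- ifelse(voted$chose_left,
                            voted$d_left < voted$d_right,
                            voted$d_right < voted$d_left)
      inconsistent <- if (d$condition[1] == "selection") chose_lower else chose_higher
      if (mean(inconsistent) >= 0.5) return("goal_inconsistent")
    }
    NA_character_
  })
  reasons <- unlist(verdict)
  excluded <- names(reasons)[!is.na(reasons)]
  log <- data.frame(
    participant_id = excluded,
    condition = vapply(by_p[excluded], function(d) d$condition[1], ""),
    reason = reasons[excluded],
    row.names = NULL
  )
  list(
    trials = trials[!trials$participant_id %in% excluded, , drop = FALSE],
    log = log
  )
}

#' Standardize ballot descriptors within participant
#'
#' Centers and scales overall desirability, signed and unsigned relative
#' desirability, and trial order to mean 0 and sample SD 1 separately for
#' each participant, writing/overwriting the `*_std` columns. Errors if any
#' predictor is constant within a participant.
#'
#' @param trials Trial data frame with raw descriptor columns.
#' @return The trial data frame with columns `overall_std`,
#'   `relative_signed_std`, `relative_unsigned_std`, `trial_order_std`.
#' @export
standardize_within_participant <- function(trials) {
  pieces <- lapply(split(trials, trials$participant_id), function(d) {
    d$overall_std <- std_vec(d$overall, "overall")
    d$relative_signed_std <- std_vec(d$relative_signed, "relative_signed")
    d$relative_unsigned_std <- std_vec(d$relative_unsigned, "relative_unsigned")
    d$trial_order_std <- std_vec(d$ballot_index, "trial_order")
    d
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$participant_id, out$ballot_index), , drop = FALSE]
}

# Wrap a fitted glm/lm into the common fit-result shape.
as_fit_result <- function(fit, converged, n_obs) {
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  structure(
    list(
      coefficients = est,
      standard_errors = se,
      z_values = z,
      ci95 = cbind(lo = est - 1.96 * se, hi = est + 1.96 * se),
      converged = converged,
      n_obs = n_obs
    ),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  tab <- data.frame(
    estimate = x$coefficients,
    se = x$standard_errors,
    z = x$z_values,
    ci_lo = x$ci95[, "lo"],
    ci_hi = x$ci95[, "hi"]
  )
  cat(sprintf("<fit_result: n = %d, converged = %s>\n", x$n_obs, x$converged))
  print(round(tab, 4))
  invisible(x)
}

#' Maximum-likelihood logistic regression
#'
#' Fits a fixed-effects logistic model by iteratively reweighted least
#' squares (via [stats::glm()]) and reports Wald standard errors, z values
#' and 95% confidence intervals. Perfect or quasi-perfect separation is
#' flagged by `converged = FALSE`; a rank-deficient design is an error.
#'
#' @param response Logical or 0/1 vector.
#' @param x Numeric matrix or data frame of predictors (an intercept is
#'   added automatically).
#' @return A `fit_result` with elements `coefficients`,
#'   `standard_errors`, `z_values`, `ci95`, `converged`, `n_obs`.
#' @export
fit_logistic <- function(response, x) {
  x <- as.matrix(x)
  y <- as.numeric(response)
  keep <- complete.cases(x) & !is.na(y)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2) stop("response must contain both classes")
  X <- cbind(`(Intercept)` = 1, x)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  sep_warning <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warning <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  names(fit$coefficients) <- colnames(X)
  converged <- fit$converged && !sep_warning &&
    all(abs(coef(fit)) < 50) # runaway estimates indicate separation
  as_fit_result(fit, converged, length(y))
}

# Assemble the standard predictor matrix for a model type.
model_predictors <- function(trials, model = c("optout", "choice", "rt")) {
  model <- match.arg(model)
  switch(model,
    optout = cbind(
      overall_std = trials$overall_std,
      relative_unsigned_std = trials$relative_unsigned_std,
      trial_order_std = trials$trial_order_std
    ),
    choice = cbind(
      relative_signed_std = trials$relative_signed_std,
      overall_std = trials$overall_std,
      trial_order_std = trials$trial_order_std
    ),
    rt = cbind(
      relative_unsigned_std = trials$relative_unsigned_std,
      overall_std = trials$overall_std
    )
  )
}

#' Fit the standard single-condition models
#'
#' Convenience fitters for the three trial-level analyses, using the same
#' predictor sets as the generating agent:
#'
#' * `fit_optout()`: logistic regression of opting out (censored trials
#'   count as not abstaining) on standardized overall desirability,
#'   unsigned relative desirability and trial order.
#' * `fit_choice()`: logistic regression of choosing the left candidate on
#'   standardized signed relative desirability, overall desirability and
#'   trial order, over voted, uncensored trials.
#' * `fit_rt()`: ordinary least squares on log10 decision time with the RT
#'   predictor set, over voted, uncensored trials.
#'
#' @param trials Standardized trial data frame (see
#'   [standardize_within_participant()]).
#' @return A `fit_result`.
#' @export
fit_optout <- function(trials) {
  fit_logistic(trials$opted_out, model_predictors(trials, "optout"))
}

#' @rdname fit_optout
#' @export
fit_choice <- function(trials) {
  voted <- trials[!trials$opted_out & !trials$deadline_censored, , drop = FALSE]
  fit_logistic(voted$chose_left, model_predictors(voted, "choice"))
}

#' @rdname fit_optout
#' @export
fit_rt <- function(trials) {
  voted <- trials[!trials$opted_out & !trials$deadline_censored, , drop = FALSE]
  X <- model_predictors(voted, "rt")
  fit <- lm(voted$rt_log10 ~ X)
  names(fit$coefficients) <- c("(Intercept)", colnames(X))
  as_fit_result(fit, TRUE, nrow(voted))
}

#' Fit the cross-condition interaction model
#'
#' Combines both goal-frame conditions, codes condition as selection = -1,
#' rejection = +1, and fits the opt-out (or choice) model with condition
#' main effect and condition-by-desirability interactions. On this coding
#' a condition-specific slope equals main effect plus/minus the
#' interaction, so the interaction coefficient is half the
#' rejection-minus-selection slope difference.
#'
#' @param trials Standardized trial data frame containing both conditions.
#' @param model `"optout"` or `"choice"`.
#' @return A `fit_result` with coefficients including
#'   `condition`, `overall_std:condition` and the relative-desirability
#'   interaction.
#' @export
fit_condition_interaction <- function(trials, model = c("optout", "choice")) {
  model <- match.arg(model)
  if (length(unique(trials$condition)) < 2) {
    stop("both conditions must be present")
  }
  cond <- ifelse(trials$condition == "selection", -1, 1)
  if (model == "optout") {
    X <- cbind(
      overall_std = trials$overall_std,
      relative_unsigned_std = trials$relative_unsigned_std,
      trial_order_std = trials$trial_order_std,
      condition = cond,
      `overall_std:condition` = trials$overall_std * cond,
      `relative_unsigned_std:condition` = trials$relative_unsigned_std * cond
    )
    fit_logistic(trials$opted_out, X)
  } else {
    voted <- trials[!trials$opted_out & !trials$deadline_censored, , drop = FALSE]
    cond <- cond[!trials$opted_out & !trials$deadline_censored]
    X <- cbind(
      relative_signed_std = voted$relative_signed_std,
      overall_std = voted$overall_std,
      trial_order_std = voted$trial_order_std,
      condition = cond,
      `relative_signed_std:condition` = voted$relative_signed_std * cond,
      `overall_std:condition` = voted$overall_std * cond
    )
    fit_logistic(voted$chose_left, X)
  }
}

#' Opt-out rate by overall-desirability quartile
#'
#' Bins each participant's ballots into quartiles of raw overall
#' desirability (rank-based, so 100 ballots give 25 per quartile), computes
#' the per-participant opt-out rate in each quartile, and summarizes across
#' participants with a normal-approximation 95% CI on the participant-mean
#' distribution. Quartile 1 holds the least desirable candidate pairs.
#'
#' @param trials Trial data frame.
#' @param pooled If `TRUE`, quartile boundaries are computed on the pooled
#'   distribution across participants instead of within participant.
#' @return Data frame with `quartile`, `rate`, `ci_lo`, `ci_hi`,
#'   `n_trials`, `n_participants`.
#' @export
quartile_optout_summary <- function(trials, pooled = FALSE) {
  if (length(unique(trials$overall)) < 4) {
    stop("need at least 4 distinct overall-desirability values")
  }
  if (pooled) {
    r <- rank(trials$overall, ties.method = "first")
    trials$.quartile <- ceiling(4 * r / length(r))
  } else {
    trials <- do.call(rbind, lapply(split(trials, trials$participant_id),
      function(d) {
        r <- rank(d$overall, ties.method = "first")
        d$.quartile <- ceiling(4 * r / nrow(d))
        d
      }))
  }
  out <- lapply(1:4, function(q) {
    dq <- trials[trials$.quartile == q, , drop = FALSE]
    pm <- tapply(dq$opted_out, dq$participant_id, mean)
    if (length(pm) < 2) stop("too few participants per quartile")
    se <- sd(pm) / sqrt(length(pm))
    data.frame(
      quartile = q,
      rate = mean(pm),
      ci_lo = mean(pm) - 1.96 * se,
      ci_hi = mean(pm) + 1.96 * se,
      n_trials = nrow(dq),
      n_participants = length(pm)
    )
  })
  do.call(rbind, out)
}

# Map generating agent parameters onto the coefficient names of a fitted
# model, for recovery comparisons.
truth_for_model <- function(params, model) {
  if (model == "optout") {
    b <- params$optout_coefs
    c(`(Intercept)` = unname(b["intercept"]),
      overall_std = unname(b["b_overall"]),
      relative_unsigned_std = unname(b["b_relative_unsigned"]),
      trial_order_std = unname(b["b_trial_order"]))
  } else {
    b <- params$choice_coefs
    c(`(Intercept)` = unname(b["intercept"]),
      relative_signed_std = unname(b["b_relative_signed"]),
      overall_std = unname(b["b_overall"]),
      trial_order_std = unname(b["b_trial_order"]))
  }
}

#' Parameter-recovery experiment
#'
#' Simulates data from known generating coefficients and verifies that the
#' fixed-effects fitting pipeline (simulate, exclude, standardize, fit)
#' returns them. Participant profiles and ballot sets are generated once
#' from the base seed and held fixed across replicates — recovery is
#' assessed conditional on the design, as in a repeated study with the same
#' trial lists — while the behavioral randomness is redrawn every
#' replicate.
#'
#' @param params Generating [agent_params()].
#' @param n_agents Number of simulated participants.
#' @param n_ballots Ballots per participant (must be even; default 100).
#' @param n_reps Number of replicates.
#' @param seed Integer base seed.
#' @param models Character vector among `"optout"`, `"choice"`.
#' @param design Trial design passed to [simulate_dataset()].
#' @param noise_sd Candidate stance noise for the design generator.
#' @return A list with `report` (data frame: `model`, `coefficient`,
#'   `truth`, `mean_estimate`, `bias`, `rmse`, `coverage`) and `estimates`
#'   (long data frame of per-replicate estimates and CI bounds).
#' @export
recovery_experiment <- function(params, n_agents, n_ballots = 100,
                                n_reps = 50, seed = 1,
                                models = c("optout", "choice"),
                                design = "two_stage", noise_sd = 0.3) {
  stopifnot(n_reps >= 1, n_ballots %% 2 == 0)
  models <- match.arg(models, several.ok = TRUE)
  n_iter <- n_ballots / 2
  profiles <- with_seed(child_seed(seed, 1),
                        random_profiles(n_agents, params$goal))
  ballot_sets <- lapply(seq_along(profiles), function(i) {
    tab <- build_candidate_table(profiles[[i]], noise_sd = noise_sd,
                                 seed = child_seed(seed, 100 + i))
    generate_ballot_set(profiles[[i]], tab, seed = child_seed(seed, 500 + i),
                        n_iterations = n_iter)
  })
  params_by_condition <- setNames(list(params), params$goal)

  rows <- list()
  for (rep in seq_len(n_reps)) {
    trials <- simulate_dataset(profiles, ballot_sets, params_by_condition,
                               design = design,
                               seed = child_seed(seed, 1000 + rep))
    kept <- apply_exclusions(trials)$trials
    if (!nrow(kept)) next
    kept <- standardize_within_participant(kept)
    for (model in models) {
      fit <- switch(model, optout = fit_optout(kept), choice = fit_choice(kept))
      rows[[length(rows) + 1]] <- data.frame(
        rep = rep, model = model,
        coefficient = names(fit$coefficients),
        estimate = unname(fit$coefficients),
        ci_lo = unname(fit$ci95[, "lo"]),
        ci_hi = unname(fit$ci95[, "hi"]),
        converged = fit$converged
      )
    }
  }
  estimates <- do.call(rbind, rows)
  report <- do.call(rbind, lapply(models, function(model) {
    truth <- truth_for_model(params, model)
    est <- estimates[estimates$model == model, , drop = FALSE]
    do.call(rbind, lapply(names(truth), function(cf) {
      e <- est[est$coefficient == cf, , drop = FALSE]
      data.frame(
        model = model, coefficient = cf, truth = truth[[cf]],
        mean_estimate = mean(e$estimate),
        bias = mean(e$estimate) - truth[[cf]],
        rmse = sqrt(mean((e$estimate - truth[[cf]])^2)),
        coverage = mean(e$ci_lo <= truth[[cf]] & truth[[cf]] <= e$ci_hi)
      )
    }))
  }))
  rownames(report) <- NULL
  list(report = report, estimates = estimates)
}

#' Export a fit result or recovery report
#'
#' @param fit A `fit_result`.
#' @param report The `report` element of [recovery_experiment()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  tab <- data.frame(
    coefficient = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    se = unname(fit$standard_errors),
    z = unname(fit$z_values),
    ci_lo = unname(fit$ci95[, "lo"]),
    ci_hi = unname(fit$ci95[, "hi"]),
    converged = fit$converged,
    n_obs = fit$n_obs
  )
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fit_result
#' @export
write_recovery_report <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}
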