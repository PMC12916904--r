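#' Default voting-agent parameters for a goal frame
#'
#' Bundles the logistic and decision-time coefficients that govern a
#' simulated voter under a given goal frame. All choice-model predictors
#' are standardized within participant, so coefficients are on the log-odds
#' (or log10-seconds) scale per standard deviation of the predictor.
#'
#' Defaults are the package's documented generating values, anchored to the
#' fixed-effect estimates of the two lab studies:
#'
#' * Selection opt-out: overall desirability -2.72 (strong alienation
#'   effect: the worse the pair, the more opting out), unsigned relative
#'   desirability -0.92 (indifference effect), intercept `qlogis(0.403)`
#'   matching the 40.3% overall opt-out rate under selection.
#' * Rejection opt-out: overall desirability +0.71 (a modest reversal:
#'   slightly more opting out between two *good* candidates), unsigned
#'   relative desirability -0.92, intercept `qlogis(0.333)` matching the
#'   33.3% rejection opt-out rate.
#' * Choice (left candidate chosen): signed relative desirability (left
#'   minus right) +2.75 under selection and -1.67 under rejection (where
#'   "choosing" a candidate means rejecting them, hence the sign flip).
#' * Decision time (log10 s): slope -0.04 on unsigned relative desirability
#'   and -0.04 on overall desirability under selection; -0.02 and +0.02
#'   under rejection (goal-congruency reversal: rejecting gets slower as
#'   candidates get better).
#'
#' Trial-order coefficients default to 0 (the task analyses treat trial
#' order as a control).
#'
#' @param goal `"selection"` or `"rejection"`.
#' @param optout_coefs,choice_coefs,rt_coefs Named numeric vectors
#'   overriding the defaults (see Details for names).
#' @param rt_noise_sd Gaussian noise SD on the log10-seconds scale
#'   (>= 0).
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(goal = c("selection", "rejection"),
                         optout_coefs = NULL, choice_coefs = NULL,
                         rt_coefs = NULL, rt_noise_sd = 0.15) {
  goal <- match.arg(goal)
  defaults <- if (goal == "selection") {
    list(
      optout = c(intercept = qlogis(0.403), b_overall = -2.72,
                 b_relative_unsigned = -0.92, b_trial_order = 0),
      choice = c(intercept = 0, b_relative_signed = 2.75,
                 b_overall = 0, b_trial_order = 0),
      rt = c(intercept = 0.45, b_relative_unsigned = -0.04, b_overall = -0.04)
    )
  } else {
    list(
      optout = c(intercept = qlogis(0.333), b_overall = 0.71,
                 b_relative_unsigned = -0.92, b_trial_order = 0),
      choice = c(intercept = 0, b_relative_signed = -1.67,
                 b_overall = 0, b_trial_order = 0),
      rt = c(intercept = 0.45, b_relative_unsigned = -0.02, b_overall = 0.02)
    )
  }
  merge_coefs <- function(def, user) {
    if (is.null(user)) return(def)
    if (is.null(names(user)) || !all(names(user) %in% names(def))) {
      stop("coefficient overrides must be named subsets of: ",
           paste(names(def), collapse = ", "))
    }
    def[names(user)] <- user
    def
  }
  if (rt_noise_sd < 0) stop("`rt_noise_sd` must be non-negative")
  structure(
    list(
      goal = goal,
      optout_coefs = merge_coefs(defaults$optout, optout_coefs),
      choice_coefs = merge_coefs(defaults$choice, choice_coefs),
      rt_coefs = merge_coefs(defaults$rt, rt_coefs),
      rt_noise_sd = rt_noise_sd
    ),
    class = "agent_params"
  )
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf("<agent_params goal = %s>\n", x$goal))
  cat("  opt-out:", paste(sprintf("%s = %.3g", names(x$optout_coefs),
                                  x$optout_coefs), collapse = ", "), "\n")
  cat("  choice: ", paste(sprintf("%s = %.3g", names(x$choice_coefs),
                                  x$choice_coefs), collapse = ", "), "\n")
  cat("  rt:     ", paste(sprintf("%s = %.3g", names(x$rt_coefs),
                                  x$rt_coefs), collapse = ", "),
      sprintf("(noise sd %.3g)", x$rt_noise_sd), "\n")
  invisible(x)
}

# Predictor columns expected by the probability functions. `predictors`
# may be a data frame or a named list of equal-length vectors.
pred_col <- function(predictors, name) {
  x <- predictors[[name]]
  if (is.null(x)) stop(sprintf("predictor `%s` is missing", name))
  if (any(!is.finite(x))) stop(sprintf("predictor `%s` must be finite", name))
  x
}

#' Opt-out probability of a voting agent
#'
#' Inverse-logit of the opt-out linear predictor: intercept plus
#' coefficients on standardized overall desirability, standardized unsigned
#' relative desirability, and standardized trial order.
#'
#' @param params An [agent_params()].
#' @param predictors Data frame or list with numeric elements
#'   `overall_std`, `relative_unsigned_std`, `trial_order_std`.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
p_opt_out <- function(params, predictors) {
  b <- params$optout_coefs
  eta <- b[["intercept"]] +
    b[["b_overall"]] * pred_col(predictors, "overall_std") +
    b[["b_relative_unsigned"]] * pred_col(predictors, "relative_unsigned_std") +
    b[["b_trial_order"]] * pred_col(predictors, "trial_order_std")
  inv_logit(eta)
}

#' Probability that the agent chooses the left candidate
#'
#' Inverse-logit of the choice linear predictor on the *signed* relative
#' desirability (left minus right). Under the rejection goal, "choosing"
#' the left candidate means voting against them, which is why the default
#' rejection coefficient is negative.
#'
#' @inheritParams p_opt_out
#' @param predictors Data frame or list with numeric elements
#'   `relative_signed_std`, `overall_std`, `trial_order_std`.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
p_choose_left <- function(params, predictors) {
  b <- params$choice_coefs
  eta <- b[["intercept"]] +
    b[["b_relative_signed"]] * pred_col(predictors, "relative_signed_std") +
    b[["b_overall"]] * pred_col(predictors, "overall_std") +
    b[["b_trial_order"]] * pred_col(predictors, "trial_order_std")
  inv_logit(eta)
}

# Standardize a vector to mean 0, sample sd 1; errors on zero variance.
std_vec <- function(x, what) {
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12) {
    stop(sprintf("cannot standardize `%s`: zero variance", what))
  }
  (x - mean(x)) / s
}

# Per-participant standardized predictors for one ballot-set data frame.
ballot_predictors <- function(ballots) {
  data.frame(
    overall_std = std_vec(ballots$overall, "overall"),
    relative_signed_std = std_vec(ballots$relative_signed, "relative_signed"),
    relative_unsigned_std = std_vec(ballots$relative_unsigned, "relative_unsigned"),
    trial_order_std = std_vec(ballots$ballot_index, "trial_order")
  )
}

#' Simulate trial-level voting data
#'
#' Plays each participant's ballot set through a goal-framed voting agent.
#' Predictors are standardized within participant (mirroring the analysis
#' pipeline) before entering the agent's linear predictors. Two task
#' designs are supported and are distributionally identical:
#'
#' * `"two_stage"`: a Bernoulli opt-out draw, then (if voting) a Bernoulli
#'   side draw — the sequential design of the binary-choice task.
#' * `"trinary"`: one categorical draw over \{no-vote, left, right\} with
#'   masses \eqn{\{p_{out},\ (1-p_{out})p_{left},\ (1-p_{out})(1-p_{left})\}}
#'   — the compulsory single-choice design.
#'
#' Voted trials receive a log10 decision time from the agent's linear RT
#' model plus Gaussian noise. Each trial is independently censored with
#' probability `deadline_prob`, emulating the rare implicit per-trial
#' deadline; censored trials count as not opting out but carry no choice
#' or decision time.
#'
#' @param profiles List of [participant_profile()] objects.
#' @param ballot_sets List of `ballot_set` objects, same order as
#'   `profiles`.
#' @param params_by_condition Named list with elements `selection` and/or
#'   `rejection`, each an [agent_params()] (or a list of per-participant
#'   [agent_params()] as produced by [heterogeneity()]).
#' @param design `"two_stage"` or `"trinary"`.
#' @param seed Optional integer seed.
#' @param deadline_prob Per-trial censoring probability.
#' @return A data frame with one row per trial: `participant_id`,
#'   `condition`, `ballot_index`, raw descriptors (`overall`,
#'   `relative_signed`, `relative_unsigned`, `d_left`, `d_right`),
#'   standardized predictors (`*_std`), `opted_out`, `chose_left`,
#'   `rt_log10`, `deadline_censored`.
#' @export
simulate_dataset <- function(profiles, ballot_sets, params_by_condition,
                             design = c("two_stage", "trinary"),
                             seed = NULL, deadline_prob = 0.001) {
  design <- match.arg(design)
  if (length(profiles) != length(ballot_sets)) {
    stop("`profiles` and `ballot_sets` must have the same length")
  }
  ids_p <- vapply(profiles, `[[`, "", "participant_id")
  ids_b <- vapply(ballot_sets, `[[`, "", "participant_id")
  if (!identical(ids_p, ids_b)) {
    stop("`ballot_sets` must match `profiles` participant for participant")
  }
  conditions <- vapply(profiles, `[[`, "", "condition")
  within_cond <- stats::ave(seq_along(profiles), conditions, FUN = seq_along)
  with_seed(seed, {
    out <- lapply(seq_along(profiles), function(idx) {
      p <- profiles[[idx]]
      ballots <- ballot_sets[[idx]]$ballots
      par <- params_by_condition[[p$condition]]
      if (is.null(par)) {
        stop(sprintf("no agent parameters supplied for condition `%s`",
                     p$condition))
      }
      if (!inherits(par, "agent_params")) par <- par[[within_cond[idx]]]
      n <- nrow(ballots)
      preds <- ballot_predictors(ballots)
      po <- p_opt_out(par, preds)
      pl <- p_choose_left(par, preds)
      if (design == "two_stage") {
        opted_out <- rbinom(n, 1, po) == 1
        chose_left <- ifelse(opted_out, NA, rbinom(n, 1, pl) == 1)
      } else {
        u <- runif(n)
        opted_out <- u < po
        chose_left <- ifelse(opted_out, NA, u < po + (1 - po) * pl)
      }
      censored <- runif(n) < deadline_prob
      opted_out[censored] <- FALSE
      chose_left[censored] <- NA
      voted <- !opted_out & !censored
      b <- par$rt_coefs
      rt <- b[["intercept"]] +
        b[["b_relative_unsigned"]] * preds$relative_unsigned_std +
        b[["b_overall"]] * preds$overall_std +
        rnorm(n, 0, par$rt_noise_sd)
      rt[!voted] <- NA
      data.frame(
        participant_id = p$participant_id,
        condition = p$condition,
        ballot_index = ballots$ballot_index,
        d_left = ballots$d_left, d_right = ballots$d_right,
        overall = ballots$overall,
        relative_signed = ballots$relative_signed,
        relative_unsigned = ballots$relative_unsigned,
        preds,
        opted_out = opted_out,
        chose_left = chose_left,
        rt_log10 = rt,
        deadline_censored = censored
      )
    })
    do.call(rbind, out)
  })
}

#' Draw heterogeneous per-agent parameters around population values
#'
#' Supports mixed-model-style between-agent variation: each agent's
#' coefficients are drawn independently Gaussian around the population
#' [agent_params()], with standard deviations given per coefficient block.
#' Zero SDs reproduce the homogeneous population exactly.
#'
#' @param params Population-level [agent_params()].
#' @param sd_vector Named list with optional numeric elements `optout`,
#'   `choice`, `rt` giving per-coefficient SDs (recycled if scalar); all
#'   must be non-negative. Missing blocks default to 0.
#' @param n_agents Number of agents.
#' @param seed Optional integer seed.
#' @return A list of `n_agents` [agent_params()] objects.
#' @export
heterogeneity <- function(params, sd_vector = list(), n_agents, seed = NULL) {
  blocks <- c("optout", "choice", "rt")
  sds <- lapply(blocks, function(bl) {
    base <- params[[paste0(bl, "_coefs")]]
    s <- sd_vector[[bl]]
    if (is.null(s)) s <- 0
    s <- rep_len(as.numeric(s), length(base))
    if (any(s < 0)) stop("heterogeneity SDs must be non-negative")
    s
  })
  names(sds) <- blocks
  with_seed(seed, {
    lapply(seq_len(n_agents), function(a) {
      draw <- params
      for (bl in blocks) {
        slot <- paste0(bl, "_coefs")
        draw[[slot]] <- draw[[slot]] +
          rnorm(length(draw[[slot]]), 0, sds[[bl]])
      }
      draw
    })
  })
}

#' Read and write trial records as CSV
#'
#' @param trials A trial data frame as returned by [simulate_dataset()].
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns the trial data frame.
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  tr$opted_out <- as.logical(tr$opted_out)
  tr$chose_left <- as.logical(tr$chose_left)
  tr$deadline_censored <- as.logical(tr$deadline_censored)
  tr
}
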