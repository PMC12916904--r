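#' Standardization moments for the voting-agent grid
#'
#' The voting agent evaluates candidate pairs whose desirabilities are
#' given directly (e.g. on the 9 x 9 grid), so its predictors must be
#' standardized with fixed centers and scales rather than within a
#' participant. The reference moments are obtained from the design
#' generator's own population: profiles and balanced ballot sets are
#' generated, each participant's mean and SD of overall, signed-relative
#' and unsigned-relative desirability are computed, and these are averaged
#' across participants. Trial-order moments come from the 1..`n_ballots`
#' presentation index.
#'
#' @param n_participants Number of reference participants to generate.
#' @param seed Integer seed for the reference population.
#' @param noise_sd Candidate stance noise for the design generator.
#' @param n_ballots Ballots per participant (even; default 100).
#' @return A list of class `design_moments` with named numeric vectors
#'   `center` and `scale` over `overall`, `relative_signed`,
#'   `relative_unsigned`, `trial_order`.
#' @export
reference_moments <- function(n_participants = 20, seed = 20240328,
                              noise_sd = 0.3, n_ballots = 100) {
  stopifnot(n_participants >= 1, n_ballots %% 2 == 0)
  profiles <- with_seed(child_seed(seed, 1),
                        random_profiles(n_participants, "selection"))
  per <- lapply(seq_along(profiles), function(i) {
    tab <- build_candidate_table(profiles[[i]], noise_sd = noise_sd,
                                 seed = child_seed(seed, 100 + i))
    b <- generate_ballot_set(profiles[[i]], tab,
                             seed = child_seed(seed, 500 + i),
                             n_iterations = n_ballots / 2)$ballots
    c(m_overall = mean(b$overall), s_overall = sd(b$overall),
      m_rs = mean(b$relative_signed), s_rs = sd(b$relative_signed),
      m_ru = mean(b$relative_unsigned), s_ru = sd(b$relative_unsigned))
  })
  m <- colMeans(do.call(rbind, per))
  structure(
    list(
      center = c(overall = unname(m["m_overall"]),
                 relative_signed = unname(m["m_rs"]),
                 relative_unsigned = unname(m["m_ru"]),
                 trial_order = mean(seq_len(n_ballots))),
      scale = c(overall = unname(m["s_overall"]),
                relative_signed = unname(m["s_rs"]),
                relative_unsigned = unname(m["s_ru"]),
                trial_order = sd(seq_len(n_ballots)))
    ),
    class = "design_moments"
  )
}

# Standardized predictors for explicit (d_blue, d_red) desirabilities.
# Blue plays the role of the "left" candidate; trial order is fixed at 1
# (the agent has a single ballot to vote on).
grid_predictors <- function(d_blue, d_red, moments) {
  ctr <- moments$center; scl <- moments$scale
  if (any(scl <= 0)) stop("standardization scales must be strictly positive")
  overall <- (d_blue + d_red) / 2
  rs <- d_blue - d_red
  data.frame(
    overall_std = (overall - ctr[["overall"]]) / scl[["overall"]],
    relative_signed_std = (rs - ctr[["relative_signed"]]) / scl[["relative_signed"]],
    relative_unsigned_std = (abs(rs) - ctr[["relative_unsigned"]]) / scl[["relative_unsigned"]],
    trial_order_std = (1 - ctr[["trial_order"]]) / scl[["trial_order"]]
  )
}

# Model-implied turnout and blue-vote probabilities at explicit
# desirabilities. Under rejection, voting blue means rejecting red.
agent_probabilities <- function(params, d_blue, d_red, moments) {
  preds <- grid_predictors(d_blue, d_red, moments)
  p_out <- p_opt_out(params, preds)
  p_left <- p_choose_left(params, preds) # "left" = blue
  p_blue <- if (params$goal == "selection") p_left else 1 - p_left
  data.frame(p_not_opt_out = 1 - p_out, p_vote_blue = p_blue)
}

#' Probability surface of a voting agent
#'
#' Evaluates a goal-framed voting agent on the 9 x 9 grid of candidate
#' desirabilities (blue and red candidate each from 1 to 9 out of 10),
#' returning for each of the 81 candidate pairs the probability of not
#' opting out and the probability of voting for the blue candidate given a
#' vote is cast. Predictors are standardized with fixed reference moments
#' ([reference_moments()]) and trial order is set to 1.
#'
#' @param params An [agent_params()].
#' @param moments A `design_moments` object (defaults to the package's
#'   reference population via [reference_moments()]).
#' @param desirabilities Grid values for each candidate (default `1:9`).
#' @return An object of class `probability_surface`: a list with `goal`,
#'   `grid` (a long data frame with `d_blue`, `d_red`, `p_not_opt_out`,
#'   `p_vote_blue`), `params` and `moments`.
#' @export
probability_surface <- function(params, moments = reference_moments(),
                                desirabilities = 1:9) {
  g <- expand.grid(d_blue = desirabilities, d_red = desirabilities)
  probs <- agent_probabilities(params, g$d_blue, g$d_red, moments)
  structure(
    list(goal = params$goal, grid = cbind(g, probs),
         params = params, moments = moments),
    class = "probability_surface"
  )
}

#' @export
print.probability_surface <- function(x, ...) {
  cat(sprintf("<probability_surface goal = %s: %d cells>\n",
              x$goal, nrow(x$grid)))
  invisible(x)
}

#' Construct voter groups
#'
#' @param d_blue,d_red Desirability of the blue and red candidate for this
#'   group of voters.
#' @param count Non-negative number of voters.
#' @return A one-row data frame; rbind groups to build an electorate.
#' @export
voter_group <- function(d_blue, d_red, count) {
  if (count < 0) stop("`count` must be non-negative")
  data.frame(d_blue = d_blue, d_red = d_red, count = count)
}

#' Deterministic expected-vote election
#'
#' Computes the expectation of an election outcome over voter groups, with
#' no sampling. For each group, blue votes accrue as count times the
#' probability of not opting out times the probability of voting blue
#' (under rejection framing, the probability of rejecting the red
#' candidate); red votes symmetrically; abstentions are count times the
#' opt-out probability. Group desirabilities off the 9 x 9 grid are handled
#' by direct model evaluation — the logistic agent is defined everywhere,
#' the grid is a reporting surface.
#'
#' @param surface A [probability_surface()].
#' @param groups Data frame of voter groups (see [voter_group()]).
#' @param full_turnout If `TRUE`, the opt-out pathway is disabled and every
#'   voter casts a ballot.
#' @return A list of class `election_result` with `votes_blue`,
#'   `votes_red`, `abstentions`, `margin_blue` (blue minus red), `winner`
#'   (`"blue"`, `"red"` or `"tie"`) and `total`.
#' @export
expected_votes <- function(surface, groups, full_turnout = FALSE) {
  pr <- agent_probabilities(surface$params, groups$d_blue, groups$d_red,
                            surface$moments)
  p_in <- if (full_turnout) rep(1, nrow(groups)) else pr$p_not_opt_out
  votes_blue <- sum(groups$count * p_in * pr$p_vote_blue)
  votes_red <- sum(groups$count * p_in * (1 - pr$p_vote_blue))
  abst <- sum(groups$count * (1 - p_in))
  margin <- votes_blue - votes_red
  structure(
    list(
      votes_blue = votes_blue, votes_red = votes_red, abstentions = abst,
      margin_blue = margin,
      winner = if (abs(margin) < 1e-9) "tie" else if (margin > 0) "blue" else "red",
      total = sum(groups$count)
    ),
    class = "election_result"
  )
}

#' @export
print.election_result <- function(x, ...) {
  cat(sprintf(
    "<election_result: blue %.1f, red %.1f, abstain %.1f -> %s by %.1f>\n",
    x$votes_blue, x$votes_red, x$abstentions, x$winner, abs(x$margin_blue)
  ))
  invisible(x)
}

#' Run the standard election scenarios
#'
#' Simulates elections of 10,000 voters split between two archetypes that
#' prefer opposing candidates by the same 3-point margin but differ in how
#' much they like the candidates overall: Blue Voters rate the blue
#' candidate 4 and the red candidate 1 (liking both less), Red Voters rate
#' them 3 and 6 (liking both more). Four population mixes are crossed with
#' both goal frames, each with a free-turnout and a full-turnout variant.
#'
#' @param params_by_goal Named list with `selection` and `rejection`
#'   [agent_params()] (defaults to the package defaults).
#' @param moments A `design_moments` object shared by both surfaces.
#' @param mixes Two-column matrix or data frame of (blue, red) voter
#'   counts; defaults to (500, 9500), (3500, 6500), (6500, 3500),
#'   (9500, 500).
#' @param blue_voter,red_voter Length-2 vectors `(d_blue, d_red)` for the
#'   two archetypes.
#' @return Data frame with one row per goal x mix x turnout-variant:
#'   `goal`, `n_blue_voters`, `n_red_voters`, `turnout`, `votes_blue`,
#'   `votes_red`, `abstentions`, `margin_blue`, `winner`,
#'   `majority_archetype`.
#' @export
run_scenarios <- function(params_by_goal = list(selection = agent_params("selection"),
                                                rejection = agent_params("rejection")),
                          moments = reference_moments(),
                          mixes = cbind(blue = c(500, 3500, 6500, 9500),
                                        red = c(9500, 6500, 3500, 500)),
                          blue_voter = c(4, 1), red_voter = c(3, 6)) {
  mixes <- as.matrix(mixes)
  rows <- list()
  for (goal in names(params_by_goal)) {
    surface <- probability_surface(params_by_goal[[goal]], moments)
    for (m in seq_len(nrow(mixes))) {
      groups <- rbind(
        voter_group(blue_voter[1], blue_voter[2], mixes[m, 1]),
        voter_group(red_voter[1], red_voter[2], mixes[m, 2])
      )
      for (full in c(FALSE, TRUE)) {
        res <- expected_votes(surface, groups, full_turnout = full)
        rows[[length(rows) + 1]] <- data.frame(
          goal = goal,
          n_blue_voters = mixes[m, 1], n_red_voters = mixes[m, 2],
          turnout = if (full) "full" else "free",
          votes_blue = res$votes_blue, votes_red = res$votes_red,
          abstentions = res$abstentions, margin_blue = res$margin_blue,
          winner = res$winner,
          majority_archetype = if (mixes[m, 1] > mixes[m, 2]) "blue" else "red"
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a probability surface or scenario table as CSV
#'
#' @param surface A [probability_surface()].
#' @param scenarios A [run_scenarios()] table.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  out <- cbind(goal = surface$goal, surface$grid)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surface
#' @export
write_scenarios <- function(scenarios, path) {
  write.csv(scenarios, path, row.names = FALSE)
  invisible(path)
}
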