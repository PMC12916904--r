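#' Rescale an importance rating from the slider scale to a weight
#'
#' Importance ratings are collected on a -3 ("not important at all") to +3
#' ("very important") slider and enter the desirability score as non-negative
#' weights on a 0-6 scale via the affine map `x + 3`.
#'
#' @param importance_raw Numeric vector of raw importance ratings in
#'   `[-3, 3]`.
#' @return Numeric vector of weights in `[0, 6]`.
#' @examples
#' rescale_importance(c(-3, 0, 3))
#' @export
rescale_importance <- function(importance_raw) {
  if (!is.numeric(importance_raw) || anyNA(importance_raw)) {
    stop("`importance_raw` must be numeric without missing values")
  }
  if (any(importance_raw < -3 | importance_raw > 3)) {
    stop("`importance_raw` must lie within [-3, 3]")
  }
  importance_raw + 3
}

#' Construct a participant profile
#'
#' A participant is described by their stance on each of 13 political issues
#' and how important each issue is to them, both on continuous -3 to +3
#' slider scales, plus the goal frame (condition) they were assigned to.
#' Issues are opaque integer ids; no issue content is modeled.
#'
#' @param participant_id Character scalar.
#' @param stance Numeric vector of 13 stances in `[-3, 3]`.
#' @param importance_raw Numeric vector of 13 importance ratings in
#'   `[-3, 3]`.
#' @param condition `"selection"` or `"rejection"`.
#' @param issue_id Integer vector of 13 distinct issue ids (default `1:13`).
#' @return An object of class `participant_profile`: a list with elements
#'   `participant_id`, `condition` and `issues` (a data frame with columns
#'   `issue_id`, `stance`, `importance_raw`).
#' @export
participant_profile <- function(participant_id, stance, importance_raw,
                                condition = c("selection", "rejection"),
                                issue_id = 1:13) {
  condition <- match.arg(condition)
  if (length(stance) != 13L || length(importance_raw) != 13L ||
      length(issue_id) != 13L) {
    stop("a profile requires exactly 13 issues")
  }
  if (anyDuplicated(issue_id)) stop("issue ids must be distinct")
  if (any(stance < -3 | stance > 3)) stop("stances must lie within [-3, 3]")
  rescale_importance(importance_raw) # bounds check
  structure(
    list(
      participant_id = as.character(participant_id),
      condition = condition,
      issues = data.frame(
        issue_id = as.integer(issue_id),
        stance = as.numeric(stance),
        importance_raw = as.numeric(importance_raw)
      )
    ),
    class = "participant_profile"
  )
}

#' @export
print.participant_profile <- function(x, ...) {
  cat(sprintf(
    "<participant_profile %s, condition = %s, %d issues>\n",
    x$participant_id, x$condition, nrow(x$issues)
  ))
  invisible(x)
}

#' Generate synthetic participant profiles
#'
#' Draws stance and importance ratings for `n` participants on 13 issues.
#' Stances are uniform on the full slider range; importance ratings are
#' drawn from a Gaussian centered above the scale midpoint (most issues on a
#' self-relevant political questionnaire are rated at least somewhat
#' important) and clipped to the slider bounds. Sliders are treated as
#' continuous, so importance ties are measure-zero and issue ranking is
#' almost surely unambiguous.
#'
#' @param n Number of profiles.
#' @param condition Condition assigned to every generated profile.
#' @param id_prefix Prefix for participant ids.
#' @param importance_mean,importance_sd Location and spread of the raw
#'   importance distribution before clipping to `[-3, 3]`.
#' @return A list of [participant_profile()] objects.
#' @export
random_profiles <- function(n, condition = c("selection", "rejection"),
                            id_prefix = "p",
                            importance_mean = 1, importance_sd = 1.5) {
  condition <- match.arg(condition)
  lapply(seq_len(n), function(i) {
    participant_profile(
      participant_id = sprintf("%s%03d", id_prefix, i),
      stance = runif(13, -3, 3),
      importance_raw = pmin(3, pmax(-3, rnorm(13, importance_mean, importance_sd))),
      condition = condition
    )
  })
}

#' Construct a candidate
#'
#' A hypothetical candidate takes a position on exactly two distinct issues.
#' Positions are real-valued stances in `[-3, 3]`; `level_a`/`level_b`
#' record the nominal level (left/neutral/right) the stance was generated
#' from, when applicable.
#'
#' @param candidate_id Character scalar.
#' @param issue_a,issue_b Distinct integer issue ids.
#' @param stance_a,stance_b Stances in `[-3, 3]`.
#' @param level_a,level_b Optional nominal levels, one of `"left"`,
#'   `"neutral"`, `"right"`, or `NA`.
#' @return A one-row data frame of class `c("candidate", "data.frame")`.
#' @export
candidate <- function(candidate_id, issue_a, issue_b, stance_a, stance_b,
                      level_a = NA_character_, level_b = NA_character_) {
  if (issue_a == issue_b) stop("a candidate's two issues must be distinct")
  if (any(c(stance_a, stance_b) < -3 | c(stance_a, stance_b) > 3)) {
    stop("candidate stances must lie within [-3, 3]")
  }
  out <- data.frame(
    candidate_id = as.character(candidate_id),
    issue_a = as.integer(issue_a), issue_b = as.integer(issue_b),
    stance_a = as.numeric(stance_a), stance_b = as.numeric(stance_b),
    level_a = level_a, level_b = level_b
  )
  class(out) <- c("candidate", "data.frame")
  out
}

# Look up a participant's stance and importance weight for given issue ids.
# Errors if any issue is absent from the profile.
profile_lookup <- function(participant, issue_ids) {
  idx <- match(issue_ids, participant$issues$issue_id)
  if (anyNA(idx)) {
    stop(sprintf(
      "issue(s) %s not present in profile %s",
      paste(issue_ids[is.na(idx)], collapse = ", "),
      participant$participant_id
    ))
  }
  list(
    stance = participant$issues$stance[idx],
    weight = rescale_importance(participant$issues$importance_raw[idx])
  )
}

#' Candidate desirability score
#'
#' Scores how desirable a candidate is to a participant as an
#' importance-weighted sum of issue alignments over the candidate's two
#' issues:
#'
#' \deqn{D = \frac{10}{12} \sum_{k=1}^{2} w_k
#'   \left[1 - \frac{|s^{cand}_k - s^{part}_k|}{6}\right]}
#'
#' where \eqn{w_k \in [0, 6]} is the rescaled importance the participant
#' assigns to issue \eqn{k} and the bracketed alignment term runs from 0
#' (diametrically opposed stances) to 1 (identical stances). The 10/12
#' factor scales the score to the `[0, 10]` range: 10 is attained when both
#' issues are maximally important and perfectly aligned, 0 when both weights
#' vanish or alignments are zero.
#'
#' `candidates` may be a single [candidate()] or any data frame with columns
#' `issue_a`, `issue_b`, `stance_a`, `stance_b` (e.g. the `candidates` table
#' of a [build_candidate_table()] result); the return is vectorized over its
#' rows.
#'
#' @param participant A [participant_profile()].
#' @param candidates A candidate or data frame of candidates.
#' @return Numeric vector of desirability scores in `[0, 10]`.
#' @examples
#' p <- participant_profile("p1", rep(0, 13), rep(3, 13))
#' candidate_desirability(p, candidate("c1", 1, 2, 0, 0)) # == 10
#' @export
candidate_desirability <- function(participant, candidates) {
  a <- profile_lookup(participant, candidates$issue_a)
  b <- profile_lookup(participant, candidates$issue_b)
  align_a <- 1 - abs(candidates$stance_a - a$stance) / 6
  align_b <- 1 - abs(candidates$stance_b - b$stance) / 6
  (10 / 12) * (a$weight * align_a + b$weight * align_b)
}

#' Desirability descriptors for a ballot
#'
#' Computes the two candidates' desirability scores and the ballot-level
#' descriptors used throughout the analyses: *overall* desirability (the
#' mean of the two scores, indexing how good the option set is in absolute
#' terms) and *relative* desirability (their difference, indexing preference
#' strength; signed as left minus right for side-choice models, unsigned
#' for opt-out models).
#'
#' @param participant A [participant_profile()].
#' @param left,right Candidates scoreable for this participant.
#' @return A list of class `desirability_pair` with elements `d_left`,
#'   `d_right`, `overall`, `relative_signed`, `relative_unsigned`.
#' @export
ballot_descriptors <- function(participant, left, right) {
  d_left <- candidate_desirability(participant, left)
  d_right <- candidate_desirability(participant, right)
  structure(
    list(
      d_left = d_left, d_right = d_right,
      overall = (d_left + d_right) / 2,
      relative_signed = d_left - d_right,
      relative_unsigned = abs(d_left - d_right)
    ),
    class = "desirability_pair"
  )
}

#' Read and write participant profiles as CSV
#'
#' Profiles are interchanged as long-format CSV with one row per issue and
#' columns `participant_id`, `issue_id`, `stance`, `importance_raw`,
#' `condition`.
#'
#' @param profiles A list of [participant_profile()] objects.
#' @param path File path.
#' @return `write_profiles()` returns `path` invisibly; `read_profiles()`
#'   returns a list of profiles.
#' @export
write_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(
      participant_id = p$participant_id,
      p$issues,
      condition = p$condition
    )
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  rows <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "issue_id", "stance", "importance_raw", "condition")
  if (!all(needed %in% names(rows))) {
    stop("profile CSV must have columns: ", paste(needed, collapse = ", "))
  }
  lapply(split(rows, rows$participant_id), function(d) {
    participant_profile(
      participant_id = d$participant_id[1],
      stance = d$stance,
      importance_raw = d$importance_raw,
      condition = d$condition[1],
      issue_id = d$issue_id
    )
  })
}
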