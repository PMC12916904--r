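#' Rank a participant's issues by importance
#'
#' Orders the 13 issues by descending raw importance. The 8 most important
#' issues feed the main task, the 9th-12th feed the practice session, and
#' the least important issue is dropped. Ties are broken by ascending
#' `issue_id`, making the ranking deterministic.
#'
#' @param participant A [participant_profile()].
#' @return A list with integer vectors `main` (8 ids, most important
#'   first), `practice` (4 ids) and `dropped` (1 id).
#' @export
rank_issues <- function(participant) {
  iss <- participant$issues
  ord <- order(-iss$importance_raw, iss$issue_id)
  ranked <- iss$issue_id[ord]
  list(
    main = ranked[1:8],
    practice = ranked[9:12],
    dropped = ranked[13]
  )
}

#' Build the per-participant table of 252 hypothetical candidates
#'
#' Every unordered pair of the participant's top-8 issues (8 * 7 / 2 = 28
#' pairs) is crossed with all 3 x 3 combinations of nominal stance levels
#' (left, neutral, right), giving 252 candidates. Nominal levels map to base
#' stances -3 / 0 / +3, perturbed by zero-mean Gaussian noise and clipped
#' back to the `[-3, 3]` slider range so every candidate remains admissible.
#' Each candidate's desirability for this participant is computed once and
#' stored.
#'
#' @param participant A [participant_profile()].
#' @param noise_sd Standard deviation of the stance noise (>= 0). With
#'   `noise_sd = 0` stances are exactly -3, 0, +3.
#' @param seed Optional integer seed for the stance noise.
#' @param issues Optional set of issue ids to build the table from
#'   (default: the participant's top-8 issues). Used for the practice
#'   ballots built from issues ranked 9-12.
#' @return An object of class `candidate_table`: a list with
#'   `participant_id`, `issues` (the ranked issue ids used), `candidates`
#'   (a 252-row data frame with columns `candidate_id`, `issue_a`,
#'   `issue_b`, `level_a`, `level_b`, `stance_a`, `stance_b`,
#'   `desirability`) and `noise_sd`.
#' @export
build_candidate_table <- function(participant, noise_sd = 0.3, seed = NULL,
                                  issues = NULL) {
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (is.null(issues)) issues <- rank_issues(participant)$main
  if (length(issues) < 2) stop("need at least two issues to pair")
  base <- c(left = -3, neutral = 0, right = 3)
  pair_mat <- combn(issues, 2L)
  n_pairs <- ncol(pair_mat)
  lev <- names(base)
  grid <- expand.grid(level_a = lev, level_b = lev,
                      stringsAsFactors = FALSE) # 9 combos per pair
  n <- n_pairs * nrow(grid)
  cand <- data.frame(
    candidate_id = sprintf("c%03d", seq_len(n)),
    issue_a = rep(pair_mat[1, ], each = nrow(grid)),
    issue_b = rep(pair_mat[2, ], each = nrow(grid)),
    level_a = rep(grid$level_a, n_pairs),
    level_b = rep(grid$level_b, n_pairs),
    stringsAsFactors = FALSE
  )
  with_seed(seed, {
    cand$stance_a <- clip(base[cand$level_a] + rnorm(n, 0, noise_sd), -3, 3)
    cand$stance_b <- clip(base[cand$level_b] + rnorm(n, 0, noise_sd), -3, 3)
  })
  rownames(cand) <- NULL
  cand$desirability <- candidate_desirability(participant, cand)
  structure(
    list(participant_id = participant$participant_id, issues = issues,
         candidates = cand, noise_sd = noise_sd),
    class = "candidate_table"
  )
}

#' @export
print.candidate_table <- function(x, ...) {
  cat(sprintf(
    "<candidate_table for %s: %d candidates on %d issues (%d pairs)>\n",
    x$participant_id, nrow(x$candidates), length(x$issues),
    choose(length(x$issues), 2)
  ))
  invisible(x)
}

# Enumerate all admissible candidate pairs of a table: unordered pairs of
# distinct candidates whose four issues are all distinct. Returns a list
# with index vectors i < j (lexicographic order by candidate id), the
# pair-level descriptors (overall, unsigned relative desirability) and an
# integer bitmask of the issues each pair uses (bit k set <=> issues[k+1]
# used). Cached on the table by generate_ballot_set().
candidate_pairs <- function(table) {
  cand <- table$candidates
  n <- nrow(cand)
  cmb <- combn(n, 2L)
  i <- cmb[1, ]; j <- cmb[2, ]
  distinct <- cand$issue_a[i] != cand$issue_a[j] &
    cand$issue_a[i] != cand$issue_b[j] &
    cand$issue_b[i] != cand$issue_a[j] &
    cand$issue_b[i] != cand$issue_b[j]
  i <- i[distinct]; j <- j[distinct]
  bit <- function(issue) bitwShiftL(1L, match(issue, table$issues) - 1L)
  usage <- bitwOr(
    bitwOr(bit(cand$issue_a[i]), bit(cand$issue_b[i])),
    bitwOr(bit(cand$issue_a[j]), bit(cand$issue_b[j]))
  )
  d <- cand$desirability
  list(
    i = i, j = j,
    overall = (d[i] + d[j]) / 2,
    relative = abs(d[i] - d[j]),
    usage = usage
  )
}

# Convex hull of the feasible (overall, unsigned relative) cloud, as a
# closed polygon matrix for point-in-polygon tests.
feasible_hull <- function(pairs) {
  pts <- cbind(pairs$overall, pairs$relative)
  h <- grDevices::chull(pts)
  pts[c(h, h[1]), , drop = FALSE]
}

#' Sample desirability targets from the feasible design space
#'
#' Draws target points for the (overall, unsigned relative) desirability of
#' a candidate pair, uniformly over the region of descriptor space
#' realizable from the participant's candidate table (the convex hull of
#' the descriptors of all admissible pairs). Sampling is by rejection from
#' the bounding box. If the feasible region degenerates to a single point
#' (e.g. a table of identical candidates), that point is returned.
#'
#' @param table A [build_candidate_table()] result.
#' @param n Number of target points.
#' @param seed Optional integer seed.
#' @return An `n` x 2 matrix with columns `overall`, `relative`.
#' @export
sample_desirability_targets <- function(table, n = 1, seed = NULL) {
  pairs <- candidate_pairs(table)
  sample_targets_impl(pairs, feasible_hull(pairs), n, seed)
}

sample_targets_impl <- function(pairs, hull, n, seed = NULL) {
  rx <- range(pairs$overall)
  ry <- range(pairs$relative)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("overall", "relative")))
  if (diff(rx) < 1e-12 && diff(ry) < 1e-12) {
    out[, 1] <- rx[1]; out[, 2] <- ry[1]
    return(out)
  }
  with_seed(seed, {
    got <- 0L
    while (got < n) {
      m <- max(2L * (n - got), 32L)
      x <- runif(m, rx[1], rx[2])
      y <- runif(m, ry[1], ry[2])
      ok <- mgcv::in.out(hull, cbind(x, y))
      keep <- which(ok)
      if (length(keep)) {
        take <- head(keep, n - got)
        out[(got + 1):(got + length(take)), 1] <- x[take]
        out[(got + 1):(got + length(take)), 2] <- y[take]
        got <- got + length(take)
      }
    }
  })
  out
}

#' Find the candidate pair closest to a desirability target
#'
#' Scans all admissible candidate pairs (four distinct issues within the
#' pair, none drawn from `forbidden_issues`) and returns the pair whose
#' (overall, unsigned relative) desirability descriptors minimize the
#' Euclidean distance to the target point. Exact ties are broken in favor
#' of the lexicographically smallest pair of candidate ids.
#'
#' @param targets Numeric length-2 vector `(overall, relative)` (or a 1-row
#'   matrix as returned by [sample_desirability_targets()]).
#' @param table A [build_candidate_table()] result.
#' @param forbidden_issues Integer vector of issue ids the pair must avoid.
#' @param pairs Optional precomputed pair enumeration (internal use).
#' @return A list with `first` and `second` (one-row candidate data
#'   frames, id-ordered), `distance`, and the pair's `overall` and
#'   `relative` descriptors.
#' @export
match_candidate_pair <- function(targets, table,
                                 forbidden_issues = integer(0),
                                 pairs = NULL) {
  if (is.null(pairs)) pairs <- candidate_pairs(table)
  targets <- as.numeric(targets)
  admissible <- seq_along(pairs$i)
  if (length(forbidden_issues)) {
    pos <- match(forbidden_issues, table$issues)
    pos <- pos[!is.na(pos)]
    if (length(pos)) {
      mask <- Reduce(bitwOr, bitwShiftL(1L, pos - 1L), 0L)
      admissible <- which(bitwAnd(pairs$usage, mask) == 0L)
    }
  }
  if (!length(admissible)) {
    stop("no admissible candidate pair under the given issue constraints")
  }
  d2 <- (pairs$overall[admissible] - targets[1])^2 +
    (pairs$relative[admissible] - targets[2])^2
  # pairs are enumerated in lexicographic (i, j) order, so the first
  # minimizer is the lexicographic tie-break winner
  best <- admissible[which.min(d2)]
  i <- pairs$i[best]; j <- pairs$j[best]
  list(
    first = table$candidates[i, , drop = FALSE],
    second = table$candidates[j, , drop = FALSE],
    distance = sqrt(min(d2)),
    overall = pairs$overall[best],
    relative = pairs$relative[best]
  )
}

#' Generate a balanced, counterbalanced ballot set
#'
#' Assembles the trial list for one participant. Each of `n_iterations`
#' iterations produces two ballots: the first candidate pair is matched to
#' a random desirability target over all admissible pairs; the second is
#' matched to a fresh target under the constraint that its four issues are
#' disjoint from the first pair's, so each iteration uses all 8 top issues
#' exactly once and every issue occurs exactly `n_iterations` times across
#' the set. Side assignment is counterbalanced so the more desirable
#' candidate appears on the left in exactly half of the ballots, candidate
#' colors are counterbalanced, and presentation order is shuffled.
#'
#' @param participant A [participant_profile()].
#' @param table A [build_candidate_table()] for that participant.
#' @param seed Optional integer seed; fixing it makes the ballot set fully
#'   reproducible.
#' @param n_iterations Number of design iterations (default 50, giving 100
#'   ballots).
#' @param max_retries Resampling budget per ballot slot before giving up
#'   with a generation error.
#' @return An object of class `ballot_set`: a list with `participant_id`,
#'   `ballots` (a `2 * n_iterations`-row data frame), `n_iterations` and
#'   `noise_sd`.
#' @export
generate_ballot_set <- function(participant, table, seed = NULL,
                                n_iterations = 50, max_retries = 100) {
  if (table$participant_id != participant$participant_id) {
    stop("candidate table does not belong to this participant")
  }
  if (length(table$issues) != 8) {
    stop("ballot sets require a table over exactly 8 issues")
  }
  pairs <- candidate_pairs(table)
  hull <- feasible_hull(pairs)
  n_ballots <- 2L * n_iterations

  with_seed(seed, {
    slots <- vector("list", n_ballots)
    k <- 0L
    for (it in seq_len(n_iterations)) {
      forbidden <- integer(0)
      for (slot in 1:2) {
        match_res <- NULL
        for (attempt in seq_len(max_retries)) {
          tgt <- sample_targets_impl(pairs, hull, 1L)
          match_res <- tryCatch(
            match_candidate_pair(tgt[1, ], table, forbidden, pairs),
            error = function(e) NULL
          )
          if (!is.null(match_res)) break
        }
        if (is.null(match_res)) {
          stop(sprintf(
            "ballot generation failed: no admissible pair after %d target resamples (iteration %d, slot %d)",
            max_retries, it, slot
          ))
        }
        k <- k + 1L
        slots[[k]] <- match_res
        forbidden <- c(
          forbidden,
          match_res$first$issue_a, match_res$first$issue_b,
          match_res$second$issue_a, match_res$second$issue_b
        )
      }
    }

    # counterbalance which side carries the more desirable candidate
    higher_left <- sample(rep(c(TRUE, FALSE), each = n_iterations))
    color_left <- sample(rep(c("yellow", "green"), each = n_iterations))
    rows <- lapply(seq_len(n_ballots), function(b) {
      m <- slots[[b]]
      da <- m$first$desirability
      db <- m$second$desirability
      first_higher <- if (da == db) TRUE else da > db
      if (higher_left[b] == first_higher) {
        left <- m$first; right <- m$second
      } else {
        left <- m$second; right <- m$first
      }
      data.frame(
        left_candidate_id = left$candidate_id,
        right_candidate_id = right$candidate_id,
        left_issue_a = left$issue_a, left_issue_b = left$issue_b,
        left_stance_a = left$stance_a, left_stance_b = left$stance_b,
        right_issue_a = right$issue_a, right_issue_b = right$issue_b,
        right_stance_a = right$stance_a, right_stance_b = right$stance_b,
        d_left = left$desirability, d_right = right$desirability,
        color_left = color_left[b]
      )
    })
    ballots <- do.call(rbind, rows)
    ballots$overall <- (ballots$d_left + ballots$d_right) / 2
    ballots$relative_signed <- ballots$d_left - ballots$d_right
    ballots$relative_unsigned <- abs(ballots$relative_signed)
    ballots <- ballots[sample(n_ballots), , drop = FALSE]
    ballots <- cbind(ballot_index = seq_len(n_ballots), ballots)
    rownames(ballots) <- NULL
    structure(
      list(participant_id = participant$participant_id, ballots = ballots,
           n_iterations = n_iterations, noise_sd = table$noise_sd),
      class = "ballot_set"
    )
  })
}

#' @export
print.ballot_set <- function(x, ...) {
  cat(sprintf(
    "<ballot_set for %s: %d ballots (%d iterations)>\n",
    x$participant_id, nrow(x$ballots), x$n_iterations
  ))
  invisible(x)
}

#' Generate practice ballots from mid-ranked issues
#'
#' Practice ballots are built from the issues ranked 9th-12th by
#' importance, using the same target-sampling and pair-matching machinery
#' as the main task but without the cross-iteration issue-balance
#' constraint (each practice ballot only requires its own four issues to
#' be distinct).
#'
#' @param participant A [participant_profile()].
#' @param n_ballots Number of practice ballots (default 8).
#' @param noise_sd Candidate stance noise SD.
#' @param seed Optional integer seed.
#' @return A data frame of practice ballots in the same column layout as
#'   `ballot_set$ballots` (without counterbalancing guarantees).
#' @export
practice_ballots <- function(participant, n_ballots = 8, noise_sd = 0.3,
                             seed = NULL) {
  issues <- rank_issues(participant)$practice
  table <- build_candidate_table(participant, noise_sd = noise_sd,
                                 seed = seed, issues = issues)
  pairs <- candidate_pairs(table)
  hull <- feasible_hull(pairs)
  with_seed(if (is.null(seed)) NULL else seed + 1L, {
    rows <- lapply(seq_len(n_ballots), function(b) {
      tgt <- sample_targets_impl(pairs, hull, 1L)
      m <- match_candidate_pair(tgt[1, ], table, pairs = pairs)
      left <- m$first; right <- m$second
      data.frame(
        ballot_index = b,
        left_candidate_id = left$candidate_id,
        right_candidate_id = right$candidate_id,
        left_issue_a = left$issue_a, left_issue_b = left$issue_b,
        left_stance_a = left$stance_a, left_stance_b = left$stance_b,
        right_issue_a = right$issue_a, right_issue_b = right$issue_b,
        right_stance_a = right$stance_a, right_stance_b = right$stance_b,
        d_left = left$desirability, d_right = right$desirability,
        color_left = if (b %% 2 == 0) "yellow" else "green"
      )
    })
    ballots <- do.call(rbind, rows)
    ballots$overall <- (ballots$d_left + ballots$d_right) / 2
    ballots$relative_signed <- ballots$d_left - ballots$d_right
    ballots$relative_unsigned <- abs(ballots$relative_signed)
    ballots
  })
}

#' Tally issue occurrences across a ballot set
#'
#' Counts, for each issue, the number of ballots on which either candidate
#' takes a position on it. By construction of [generate_ballot_set()] the
#' tally is flat at `n_iterations` for every top-8 issue.
#'
#' @param ballot_set A [generate_ballot_set()] result.
#' @return Named integer vector of per-issue ballot counts.
#' @export
issue_occurrences <- function(ballot_set) {
  b <- ballot_set$ballots
  issues <- c(b$left_issue_a, b$left_issue_b, b$right_issue_a, b$right_issue_b)
  tab <- table(factor(issues))
  setNames(as.integer(tab), names(tab))
}

#' Read and write ballot sets as CSV
#'
#' Ballot sets are interchanged as CSV with one row per ballot, carrying
#' candidate ids, issues and stances for both sides, the desirability
#' descriptors and the left-side color.
#'
#' @param ballot_sets A list of `ballot_set` objects (or a single one).
#' @param path File path.
#' @return `write_ballots()` returns `path` invisibly; `read_ballots()`
#'   returns a data frame with a `participant_id` column.
#' @export
write_ballots <- function(ballot_sets, path) {
  if (inherits(ballot_sets, "ballot_set")) ballot_sets <- list(ballot_sets)
  rows <- do.call(rbind, lapply(ballot_sets, function(bs) {
    cbind(participant_id = bs$participant_id, bs$ballots)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ballots
#' @export
read_ballots <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
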