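test_that("issue ranking is deterministic with ascending-id tie-break", {
  # strictly decreasing importance: ranking is the identity
  p <- make_profile(importance = seq(3, -3, length.out = 13))
  r <- rank_issues(p)
  expect_equal(r$main, 1:8)
  expect_equal(r$practice, 9:12)
  expect_equal(r$dropped, 13)
  # all equal: ties broken by ascending issue id
  p_tie <- make_profile(importance = rep(1, 13))
  expect_equal(rank_issues(p_tie)$main, 1:8)
  # shuffled profile: recovered order matches a generic sort oracle
  set.seed(3)
  imp <- sample(seq(-3, 3, length.out = 13))
  p_sh <- make_profile(importance = imp)
  oracle <- order(imp, decreasing = TRUE)
  expect_equal(
    c(rank_issues(p_sh)$main, rank_issues(p_sh)$practice,
      rank_issues(p_sh)$dropped),
    oracle
  )
})

test_that("candidate table has 252 candidates over 28 issue pairs", {
  p <- make_profile()
  tab <- build_candidate_table(p, seed = 1)
  expect_equal(nrow(tab$candidates), 252)
  pair_key <- paste(pmin(tab$candidates$issue_a, tab$candidates$issue_b),
                    pmax(tab$candidates$issue_a, tab$candidates$issue_b))
  expect_equal(length(unique(pair_key)), 28)
  # every pair carries all 9 level combinations
  combos <- table(pair_key, paste(tab$candidates$level_a, tab$candidates$level_b))
  expect_true(all(combos == 1))
  expect_false(anyDuplicated(tab$candidates$candidate_id) > 0)
})

test_that("zero stance noise gives exact level stances; noise is clipped", {
  p <- make_profile()
  tab0 <- build_candidate_table(p, noise_sd = 0, seed = 1)
  expect_true(all(tab0$candidates$stance_a %in% c(-3, 0, 3)))
  expect_true(all(tab0$candidates$stance_b %in% c(-3, 0, 3)))
  tab <- build_candidate_table(p, noise_sd = 2, seed = 1)
  expect_true(all(abs(tab$candidates$stance_a) <= 3))
  expect_true(all(abs(tab$candidates$stance_b) <= 3))
  expect_error(build_candidate_table(p, noise_sd = -0.1), "non-negative")
})

test_that("candidate tables are reproducible under a seed", {
  p <- make_profile()
  expect_identical(build_candidate_table(p, seed = 9)$candidates,
                   build_candidate_table(p, seed = 9)$candidates)
})

test_that("desirability targets fall inside the feasible region", {
  p <- make_profile(stance = runif(13, -3, 3))
  tab <- build_candidate_table(p, seed = 5)
  pairs <- voteframe:::candidate_pairs(tab)
  pts <- cbind(pairs$overall, pairs$relative)
  h <- grDevices::chull(pts)
  tg <- sample_desirability_targets(tab, n = 500, seed = 11)
  ok <- vapply(seq_len(nrow(tg)), function(i) {
    in_hull(tg[i, 1], tg[i, 2], pts[h, 1], pts[h, 2], tol = 1e-7)
  }, logical(1))
  expect_true(all(ok))
  # coarse uniformity check over the bounding box cells that intersect
  # the region: no cell should be wildly over- or under-represented
  gx <- cut(tg[, 1], 4); gy <- cut(tg[, 2], 4)
  counts <- table(gx, gy)
  expect_gt(sum(counts > 0), 6) # spread over many cells, not clumped
})

test_that("a degenerate desirability region collapses to a point", {
  # importance all at the scale minimum: every candidate scores 0
  p <- make_profile(importance = rep(-3, 13))
  tab <- build_candidate_table(p, seed = 2)
  tg <- sample_desirability_targets(tab, n = 10, seed = 1)
  expect_true(all(tg[, "overall"] == 0))
  expect_true(all(tg[, "relative"] == 0))
})

test_that("pair matching is a global minimizer with lexicographic ties", {
  p <- make_profile(stance = cos(1:13), importance = sin(1:13) * 3)
  # reduced 4-issue table keeps exhaustive enumeration cheap
  tab <- build_candidate_table(p, seed = 13, issues = rank_issues(p)$main[1:4])
  cand <- tab$candidates
  set.seed(21)
  for (rep in 1:20) {
    tgt <- c(runif(1, 0, 10), runif(1, 0, 10))
    got <- match_candidate_pair(tgt, tab)
    # exhaustive scan oracle
    best_d <- Inf; best_ids <- NULL
    for (i in seq_len(nrow(cand) - 1)) {
      for (j in (i + 1):nrow(cand)) {
        iss <- c(cand$issue_a[c(i, j)], cand$issue_b[c(i, j)])
        if (anyDuplicated(iss)) next
        ov <- (cand$desirability[i] + cand$desirability[j]) / 2
        rl <- abs(cand$desirability[i] - cand$desirability[j])
        d <- (ov - tgt[1])^2 + (rl - tgt[2])^2
        if (d < best_d) {
          best_d <- d
          best_ids <- c(cand$candidate_id[i], cand$candidate_id[j])
        }
      }
    }
    expect_equal(got$distance^2, best_d, tolerance = 1e-12)
    expect_equal(sort(c(got$first$candidate_id, got$second$candidate_id)),
                 sort(best_ids))
  }
})

test_that("forbidden issues constrain matching and can make it infeasible", {
  p <- make_profile()
  tab <- build_candidate_table(p, seed = 4)
  top8 <- tab$issues
  got <- match_candidate_pair(c(5, 2), tab, forbidden_issues = top8[1:4])
  used <- c(got$first$issue_a, got$first$issue_b,
            got$second$issue_a, got$second$issue_b)
  expect_true(all(used %in% top8[5:8]))
  # fewer than 4 issues left: no admissible pair
  expect_error(
    match_candidate_pair(c(5, 2), tab, forbidden_issues = top8[1:5]),
    "no admissible"
  )
})

test_that("ballot sets satisfy balance, distinctness and counterbalancing", {
  p <- make_profile(stance = runif(13, -3, 3), importance = runif(13, -3, 3))
  tab <- build_candidate_table(p, seed = 31)
  bs <- generate_ballot_set(p, tab, seed = 32)
  b <- bs$ballots
  expect_equal(nrow(b), 100)
  expect_equal(b$ballot_index, 1:100)
  # every top-8 issue appears on exactly 50 ballots
  occ <- issue_occurrences(bs)
  expect_equal(sort(as.integer(names(occ))), sort(tab$issues))
  expect_true(all(occ == 50))
  # the four issues within each ballot are distinct
  for (i in seq_len(nrow(b))) {
    expect_equal(anyDuplicated(c(b$left_issue_a[i], b$left_issue_b[i],
                                 b$right_issue_a[i], b$right_issue_b[i])), 0)
  }
  # counterbalancing audits
  expect_equal(sum(b$d_left > b$d_right), 50)
  expect_equal(unname(table(b$color_left)["yellow"]), 50)
  # descriptors are consistent with the stored desirabilities
  expect_equal(b$overall, (b$d_left + b$d_right) / 2)
  expect_equal(b$relative_unsigned, abs(b$relative_signed))
})

test_that("small ballot sets keep exact per-iteration issue balance", {
  p <- make_profile()
  tab <- build_candidate_table(p, seed = 8)
  bs <- generate_ballot_set(p, tab, seed = 9, n_iterations = 2)
  expect_equal(nrow(bs$ballots), 4)
  occ <- issue_occurrences(bs)
  expect_true(all(occ == 2))
})

test_that("ballot generation is byte-identical under a fixed seed", {
  p <- make_profile(stance = runif(13, -3, 3))
  tab <- build_candidate_table(p, noise_sd = 0.3, seed = 77)
  bs1 <- generate_ballot_set(p, tab, seed = 78)
  bs2 <- generate_ballot_set(p, tab, seed = 78)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_ballots(bs1, f1)
  write_ballots(bs2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # and a different seed changes the set
  bs3 <- generate_ballot_set(p, tab, seed = 79)
  expect_false(identical(bs1$ballots, bs3$ballots))
})

test_that("ballot CSV round-trips through the package readers", {
  p <- make_profile()
  tab <- build_candidate_table(p, seed = 3)
  bs <- generate_ballot_set(p, tab, seed = 4, n_iterations = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ballots(bs, path)
  back <- read_ballots(path)
  expect_equal(nrow(back), 10)
  expect_equal(back$d_left, bs$ballots$d_left)
  expect_equal(back$participant_id, rep(p$participant_id, 10))
})

test_that("practice ballots use the 9th-12th issues only", {
  p <- make_profile(importance = seq(3, -3, length.out = 13))
  pb <- practice_ballots(p, n_ballots = 6, seed = 15)
  expect_equal(nrow(pb), 6)
  used <- unique(c(pb$left_issue_a, pb$left_issue_b,
                   pb$right_issue_a, pb$right_issue_b))
  expect_true(all(used %in% 9:12))
  for (i in seq_len(nrow(pb))) {
    expect_equal(anyDuplicated(c(pb$left_issue_a[i], pb$left_issue_b[i],
                                 pb$right_issue_a[i], pb$right_issue_b[i])), 0)
  }
})
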