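# Deterministic profile with controllable ratings.
make_profile <- function(id = "p1",
                         stance = seq(-3, 3, length.out = 13),
                         importance = seq(3, -3, length.out = 13),
                         condition = "selection") {
  participant_profile(id, stance, importance, condition)
}

# Independent term-by-term desirability oracle: deliberately scalar and
# loop-based, sharing no code with the package implementation.
oracle_desirability <- function(imp_raw_1, imp_raw_2,
                                part_stance_1, part_stance_2,
                                cand_stance_1, cand_stance_2) {
  total <- 0
  for (k in 1:2) {
    w <- c(imp_raw_1, imp_raw_2)[k] + 3
    ps <- c(part_stance_1, part_stance_2)[k]
    cs <- c(cand_stance_1, cand_stance_2)[k]
    total <- total + w * (1 - abs(cs - ps) / 6)
  }
  total * 10 / 12
}

# Point-in-convex-polygon test via cross products (hull vertices in
# chull order, not closed). Independent of mgcv.
in_hull <- function(px, py, hx, hy, tol = 1e-9) {
  n <- length(hx)
  signs <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
  }, numeric(1))
  all(signs <= tol) || all(signs >= -tol)
}

# A hand-built ballot_set-shaped object with arbitrary descriptors, for
# tests of the behavioral simulator that do not need the design engine.
fake_ballot_set <- function(id, n, seed = 1) {
  set.seed(seed)
  d_left <- runif(n, 0, 10)
  d_right <- runif(n, 0, 10)
  ballots <- data.frame(
    ballot_index = seq_len(n),
    d_left = d_left, d_right = d_right,
    overall = (d_left + d_right) / 2,
    relative_signed = d_left - d_right,
    relative_unsigned = abs(d_left - d_right)
  )
  structure(list(participant_id = id, ballots = ballots,
                 n_iterations = n / 2, noise_sd = 0.3),
            class = "ballot_set")
}

# Fixed standardization moments so election tests need no generator run.
fake_moments <- function(rel_center = 0) {
  structure(
    list(
      center = c(overall = 5, relative_signed = rel_center,
                 relative_unsigned = 2.5, trial_order = 50.5),
      scale = c(overall = 1.5, relative_signed = 3,
                relative_unsigned = 1.75, trial_order = 29.0114919758820)
    ),
    class = "design_moments"
  )
}
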