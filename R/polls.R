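#' Reconstruct a count from a printed percentage and group size
#'
#' Published survey results typically print a percentage and a group size
#' rather than raw counts. This inverts that rounding: the count is
#' `percent * n / 100`, rounded half up. If the back-computed percentage of
#' the reconstructed count differs from the input by more than 0.05
#' percentage points, the reconstruction is ambiguous and a warning is
#' emitted.
#'
#' @param percent Percentage in `[0, 100]`.
#' @param n Positive integer group size.
#' @return Integer count.
#' @examples
#' reconstruct_counts(32.9, 484) # 159
#' @export
reconstruct_counts <- function(percent, n) {
  if (any(percent < 0 | percent > 100)) {
    stop("`percent` must lie within [0, 100]")
  }
  if (any(n <= 0)) stop("`n` must be positive")
  count <- floor(percent * n / 100 + 0.5) # round half up
  back <- 100 * count / n
  off <- abs(back - percent) > 0.05
  if (any(off)) {
    warning(sprintf(
      "reconstructed count(s) %s imply %% %s, differing from input by > 0.05",
      paste(count[off], collapse = ", "),
      paste(sprintf("%.3f", back[off]), collapse = ", ")
    ))
  }
  as.integer(count)
}

#' Two-proportion z test with optional continuity correction
#'
#' Pooled-variance z test for the difference of two independent
#' proportions, as used to compare "undecided" rates between framed poll
#' conditions. With `continuity = TRUE` (the default), the absolute
#' difference of proportions is reduced by `0.5 * (1/n1 + 1/n2)` (floored
#' at zero) before dividing by the pooled standard error; the squared
#' statistic then equals the Yates-corrected chi-square of the 2 x 2
#' table.
#'
#' @param x1,x2 Event counts in the two groups.
#' @param n1,n2 Group sizes.
#' @param continuity Apply the continuity correction?
#' @param alternative `"less"` (prop1 < prop2), `"greater"`, or
#'   `"two.sided"`.
#' @return A list of class `two_proportion_test` with `z`, `chi2`,
#'   `df` (= 1), `p`, `estimate` (the two proportions), `alternative` and
#'   `continuity`.
#' @examples
#' two_proportion_z(96, 483, 159, 484, alternative = "less")
#' @export
two_proportion_z <- function(x1, n1, x2, n2, continuity = TRUE,
                             alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("counts must lie within [0, n]")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  pbar <- (x1 + x2) / (n1 + n2)
  if (pbar <= 0 || pbar >= 1) {
    stop("degenerate table: pooled proportion is 0 or 1")
  }
  se <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  d <- p1 - p2
  if (continuity) {
    cc <- 0.5 * (1 / n1 + 1 / n2)
    d <- sign(d) * max(0, abs(d) - cc)
  }
  z <- d / se
  p <- switch(alternative,
    less = pnorm(z),
    greater = pnorm(z, lower.tail = FALSE),
    two.sided = 2 * pnorm(-abs(z))
  )
  structure(
    list(z = z, chi2 = z^2, df = 1L, p = p,
         estimate = c(prop1 = p1, prop2 = p2),
         alternative = alternative, continuity = continuity),
    class = "two_proportion_test"
  )
}

#' @export
print.two_proportion_test <- function(x, ...) {
  cat(sprintf(
    "Two-proportion z test (%s, continuity %s)\n  z = %.3f, chi2 = %.3f, df = 1, p = %.4g\n  props: %.4f vs %.4f\n",
    x$alternative, if (x$continuity) "on" else "off",
    x$z, x$chi2, x$p, x$estimate[1], x$estimate[2]
  ))
  invisible(x)
}

#' Published framed-poll summaries
#'
#' Group sizes and "undecided" percentages for the two preregistered
#' framed-poll surveys run before the 2024 US presidential election
#' (self-identified US Independents; survey 1 fielded 2024-05-28, survey 2
#' fielded 2024-09-06). These printed values are the inputs from
#' which counts are reconstructed for the two-proportion tests.
#'
#' @return Data frame with columns `study`, `condition`, `n`,
#'   `pct_undecided`.
#' @export
study_poll_data <- function() {
  data.frame(
    study = c(3L, 3L, 4L, 4L),
    condition = c("selection", "rejection", "selection", "rejection"),
    n = c(484L, 483L, 489L, 487L),
    pct_undecided = c(32.9, 19.9, 22.9, 14.6)
  )
}

#' Framed-poll comparison from printed summaries
#'
#' Reconstructs undecided counts from printed percentages and group sizes
#' and runs the one-sided two-proportion z test of the preregistered
#' prediction that rejection-framed respondents are less likely to answer
#' "undecided" than selection-framed respondents.
#'
#' @param study 3 or 4 (which survey), indexing [study_poll_data()].
#' @param continuity Apply the continuity correction?
#' @return A `two_proportion_test` (rejection as group 1, so the
#'   preregistered direction is `alternative = "less"`), with the
#'   reconstructed counts attached as `counts`.
#' @export
poll_framing_test <- function(study = 3, continuity = TRUE) {
  d <- study_poll_data()
  d <- d[d$study == study, , drop = FALSE]
  if (!nrow(d)) stop("unknown study: ", study)
  sel <- d[d$condition == "selection", ]
  rej <- d[d$condition == "rejection", ]
  x_sel <- reconstruct_counts(sel$pct_undecided, sel$n)
  x_rej <- reconstruct_counts(rej$pct_undecided, rej$n)
  out <- two_proportion_z(x_rej, rej$n, x_sel, sel$n,
                          continuity = continuity, alternative = "less")
  out$counts <- c(rejection = x_rej, selection = x_sel)
  out
}
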