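#' Paired Wilcoxon signed-rank test on T0 vs T1 values
#'
#' Two-sided signed-rank test on the paired differences, after dropping
#' zero differences (Wilcoxon's original rule). Exact p-values for up to
#' 25 non-zero pairs without ties; with tied ranks the exact null
#' distribution is enumerated over all sign assignments for up to 20
#' pairs; normal approximation with continuity correction (and tie
#' variance correction) otherwise.
#'
#' @param t0,t1 paired numeric vectors of equal length.
#' @param zero_rule "drop" (default) or "pratt" (rank zeros, then drop
#'   their signed ranks).
#' @return list with \code{statistic} (V, sum of positive ranks),
#'   \code{p_value} and \code{n} (pairs used).
#' @export
wilcoxon_paired <- function(t0, t1, zero_rule = "drop") {
  zero_rule <- match.arg(zero_rule, c("drop", "pratt"))
  assert_that(length(t0) == length(t1), "too_few_pairs",
              "paired vectors differ in length")
  d <- t1 - t0
  if (zero_rule == "drop") {
    d <- d[d != 0]
    assert_that(length(d) >= 5, "too_few_pairs",
                "fewer than 5 non-zero paired differences (%d)", length(d))
    r <- rank(abs(d))
  } else {
    assert_that(sum(d != 0) >= 5, "too_few_pairs",
                "fewer than 5 non-zero paired differences")
    r <- rank(abs(d))
    keep <- d != 0
    r <- r[keep]
    d <- d[keep]
  }
  V <- sum(r[d > 0])
  n <- length(d)
  ties <- any(duplicated(r))
  if (n <= 25 && !ties && zero_rule == "drop") {
    p <- stats::psignrank(V, n)
    p_up <- stats::psignrank(V - 1, n, lower.tail = FALSE)
    p_value <- min(1, 2 * min(p, p_up))
  } else if (n <= 20) {
    # exact null distribution of V by enumerating all sign assignments,
    # valid with tied ranks
    dist <- 0
    for (rk in r) dist <- c(dist, dist + rk)
    eps <- 1e-9
    p_value <- min(1, 2 * min(mean(dist <= V + eps),
                              mean(dist >= V - eps)))
  } else {
    mu <- n * (n + 1) / 4
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24
    tie_tab <- table(r)
    sigma2 <- sigma2 - sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p_value <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = V, p_value = p_value, n = n)
}

#' Percentage of clinically improved subjects
#' @param flags logical vector, one per subject (or counts via
#'   \code{improved} and \code{n}).
#' @return percentage in [0, 100].
#' @export
improvement_proportion <- function(flags) {
  assert_that(length(flags) >= 1, "empty_cohort", "empty cohort")
  100 * sum(flags) / length(flags)
}

#' Pearson chi-squared comparison of improvement proportions
#'
#' 2x2 Pearson chi-squared test (1 df) on improved/not-improved counts in
#' two groups, without continuity correction by default.
#'
#' @param improved_a,n_a improved count and group size of group A.
#' @param improved_b,n_b same for group B.
#' @param correct apply Yates continuity correction.
#' @return list with \code{statistic}, \code{p_value}, \code{df}.
#' @export
chi_squared_proportions <- function(improved_a, n_a, improved_b, n_b,
                                    correct = FALSE) {
  assert_that(n_a >= 1 && n_b >= 1 &&
                improved_a <= n_a && improved_b <= n_b, "degenerate_table",
              "invalid 2x2 counts")
  tab <- matrix(c(improved_a, n_a - improved_a,
                  improved_b, n_b - improved_b), nrow = 2, byrow = TRUE)
  assert_that(all(colSums(tab) > 0) && all(rowSums(tab) > 0),
              "degenerate_table", "a margin of the 2x2 table is zero")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}
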