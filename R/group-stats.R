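# Group comparisons used in the behavioral analysis: Mann-Whitney U for the
# (non-normal) behavioral and P-sol data, one-way ANOVA and Student's t for
# approximately normal quantities, plus the 5-interval P-sol summary used to
# describe phase-state distributions. Significance level throughout: 0.05.

.new_comparison <- function(test, statistic, df, p, n_per_group) {
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 n_per_group = n_per_group),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  lab <- switch(x$test, mann_whitney_u = "Mann-Whitney U-test",
                anova = "One-way ANOVA", t_test = "Student's t-test")
  stat <- switch(x$test, mann_whitney_u = sprintf("U = %g", x$statistic),
                 anova = sprintf("F(%g, %g) = %.4g", x$df[1], x$df[2],
                                 x$statistic),
                 t_test = sprintf("t(%g) = %.4g", x$df, x$statistic))
  cat(sprintf("%s: %s, p = %.4g (n = %s)\n", lab, stat, x$p,
              paste(x$n_per_group, collapse = ", ")))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. U is reported as `min(U1, U2)` (the convention
#' of the usual statistical packages). With `n1 + n2 <= 20` and no ties the
#' p-value is exact, from the null distribution of U over all rank
#' assignments; otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b Numeric samples (each non-empty).
#' @param method `"auto"` (default: exact below the crossover, normal
#'   approximation otherwise), `"exact"` (requires tie-free data) or
#'   `"normal"`.
#' @return A `"group_comparison"` with `test = "mann_whitney_u"`,
#'   `statistic` = U, and the two-sided p-value.
#' @export
mann_whitney_u <- function(a, b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (!length(a) || !length(b))
    .lp_stop("both samples must be non-empty", "lp_contract_error")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  has_ties <- anyDuplicated(c(a, b)) > 0
  if (method == "exact" && has_ties)
    .lp_stop("exact Mann-Whitney p is undefined with ties", "lp_contract_error")
  exact <- switch(method, exact = TRUE, normal = FALSE,
                  auto = n1 + n2 <= 20 && !has_ties)
  if (exact) {
    # exact: P(U <= u) doubled; pwilcox is the exact null CDF of U
    p <- min(1, 2 * stats::pwilcox(u, n1, n2))
  } else {
    mu <- n1 * n2 / 2
    tj <- table(c(a, b))
    N <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tj^3 - tj) / (N * (N - 1)))
    if (sigma2 <= 0)
      .lp_stop("degenerate data: all observations tied", "lp_degenerate_error")
    z <- (u - mu + 0.5) / sqrt(sigma2)  # continuity correction; u <= mu
    p <- min(1, 2 * stats::pnorm(z))
  }
  .new_comparison("mann_whitney_u", u, NA_real_, p, c(n1, n2))
}

#' One-way analysis of variance
#'
#' @param groups List of two or more numeric samples, each with at least two
#'   observations.
#' @return A `"group_comparison"` with `test = "anova"`, `statistic` = F,
#'   `df` = (between, within) degrees of freedom.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L)
    .lp_stop("need at least two groups", "lp_contract_error")
  if (any(vapply(groups, length, integer(1)) < 2L))
    .lp_stop("each group needs at least two observations", "lp_contract_error")
  if (all(vapply(groups, function(g) stats::var(g) == 0, logical(1))))
    .lp_stop("degenerate data: zero within-group variance in every group",
             "lp_degenerate_error")
  y <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  tab <- stats::anova(stats::lm(y ~ grp))
  .new_comparison("anova", tab$`F value`[1], c(tab$Df[1], tab$Df[2]),
                  tab$`Pr(>F)`[1], vapply(groups, length, integer(1)))
}

#' Student's t-test for two groups
#'
#' Pooled-variance two-sample t by default, as used for receptor-expression
#' style comparisons; `welch = TRUE` drops the equal-variance assumption.
#'
#' @param a,b Numeric samples, each with at least two observations.
#' @param welch Use the Welch (unequal-variance) variant.
#' @return A `"group_comparison"` with `test = "t_test"`.
#' @export
students_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    .lp_stop("each group needs at least two observations", "lp_contract_error")
  tt <- stats::t.test(a, b, var.equal = !welch)
  .new_comparison("t_test", unname(tt$statistic), unname(tt$parameter),
                  tt$p.value, c(length(a), length(b)))
}

#' Summarize a set of P-sol scores
#'
#' The median (midpoint convention for even n) and the proportions of
#' animals in the five P-sol intervals `[0, 0.2)`, `[0.2, 0.4)`,
#' `[0.4, 0.6)`, `[0.6, 0.8)`, `[0.8, 1]`; the last interval is closed so a
#' score of exactly 0.8 or 1 falls in the top bin.
#'
#' @param scores Numeric P-sol values in `[0, 1]`, or the data frame
#'   returned by [score_psol()] (its `psol` column is used).
#' @return An object of class `"psol_summary"`: list with `median`, `bins`
#'   (named proportions, summing to 1) and `n`.
#' @export
summarize_psol <- function(scores) {
  if (is.data.frame(scores)) scores <- scores$psol
  if (!length(scores))
    .lp_stop("no scores to summarize", "lp_contract_error")
  if (any(scores < 0 | scores > 1))
    .lp_stop("P-sol scores must lie in [0, 1]", "lp_contract_error")
  counts <- c(sum(scores < 0.2), sum(scores >= 0.2 & scores < 0.4),
              sum(scores >= 0.4 & scores < 0.6),
              sum(scores >= 0.6 & scores < 0.8), sum(scores >= 0.8))
  names(counts) <- c("[0,0.2)", "[0.2,0.4)", "[0.4,0.6)", "[0.6,0.8)",
                     "[0.8,1]")
  structure(list(median = stats::median(scores),
                 bins = counts / length(scores), n = length(scores)),
            class = "psol_summary")
}

#' @export
print.psol_summary <- function(x, ...) {
  cat(sprintf("P-sol summary (n = %d): median = %.4g\n", x$n, x$median))
  print(round(x$bins, 3))
  invisible(x)
}

#' Bar plot of a P-sol interval distribution
#'
#' @param x A `"psol_summary"`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.psol_summary <- function(x, ...) {
  bp <- graphics::barplot(x$bins, ylab = "proportion of animals",
                          xlab = "P-sol interval",
                          ylim = c(0, max(x$bins) * 1.15), ...)
  graphics::abline(v = bp[findInterval(x$median, c(0, 0.2, 0.4, 0.6, 0.8, 1.01))],
                   lty = 2)
  invisible(bp)
}
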