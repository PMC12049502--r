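# Group-level inference: sign-flip permutation one-sample t-tests, effect
# sizes, and Bonferroni correction.

#' Sign-flip permutation one-sample t-test
#'
#' The observed one-sample t statistic is compared against a surrogate
#' distribution obtained from random sign-flips of the per-participant
#' values (exact-level for symmetric nulls). The p-value includes the
#' observed statistic in numerator and denominator, so it is never 0:
#' `p = (1 + #extreme) / (1 + n_perm)`.
#'
#' @param values per-participant statistics.
#' @param alternative `"greater"` (one-sided positive), `"less"`, or
#'   `"two.sided"`.
#' @param n_perm number of random sign-flips.
#' @param seed integer seed for the flip stream.
#' @param mu null value subtracted before testing.
#' @return `group_stat`: list with `t`, `p`, `d` (Cohen's d), `ci` (95%
#'   t-interval of the mean), `n`, `n_perm`, `alternative`.
#' @export
signflip_ttest <- function(values, alternative = c("greater", "two.sided", "less"),
                           n_perm = 10000L, seed = NULL, mu = 0) {
  alternative <- match.arg(alternative)
  x <- values - mu
  n <- length(x)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance: t statistic undefined", call. = FALSE)
  t_obs <- mean(x) / (stats::sd(x) / sqrt(n))

  with_local_seed(seed, {
    flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    xs <- x * flips
    m <- colMeans(xs)
    s <- sqrt((colSums(xs^2) - n * m^2) / (n - 1L))
    t_perm <- m / (s / sqrt(n))
    extreme <- switch(alternative,
                      greater = sum(t_perm >= t_obs),
                      less = sum(t_perm <= t_obs),
                      two.sided = sum(abs(t_perm) >= abs(t_obs)))
    p <- (1 + extreme) / (1 + n_perm)
    ci <- mean(x) + stats::qt(c(0.025, 0.975), n - 1L) * stats::sd(x) / sqrt(n)
    structure(list(t = t_obs, p = p, d = mean(x) / stats::sd(x),
                   ci = ci + mu, n = n, n_perm = n_perm,
                   alternative = alternative, p_corrected = NULL),
              class = "group_stat")
  })
}

#' @export
print.group_stat <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, permutation p = %.4g (%s), Cohen's d = %.3f, 95%% CI [%.4g, %.4g]\n",
              x$n - 1L, x$t, x$p, x$alternative, x$d, x$ci[1L], x$ci[2L]))
  invisible(x)
}

#' Bonferroni correction
#'
#' @param p p-value(s).
#' @param factor number of comparisons (>= 1).
#' @return corrected p-value(s), capped at 1.
#' @export
bonferroni <- function(p, factor) {
  stopifnot(factor >= 1)
  pmin(1, p * factor)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return correlation coefficient.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length vectors of at least 3 values", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}
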