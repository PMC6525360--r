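# The study's replicate-level statistical comparisons: an unequal-variance
# (Welch) two-sample t-test between treatments and paired t-tests between
# genotypes within a treatment. Tail probabilities come from the exact
# Student t distribution function (stats::pt, i.e. the regularized
# incomplete beta), two-sided throughout.

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom. When both sample variances are zero the test is degenerate:
#' p is 1 if the means are equal and 0 otherwise, with a flag.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return List with `statistic`, `df`, `p.value`, `flags`.
#' @export
welch_t_test <- function(group_a, group_b) {
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  m1 <- mean(group_a); m2 <- mean(group_b)
  v1 <- stats::var(group_a); v2 <- stats::var(group_b)
  flags <- character()
  if (v1 == 0 && v2 == 0) {
    flags <- "degenerate_zero_variance"
    return(list(statistic = if (m1 == m2) 0 else sign(m1 - m2) * Inf,
                df = NA_real_, p.value = if (m1 == m2) 1 else 0,
                flags = flags))
  }
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(statistic = t, df = df, p.value = 2 * pt(-abs(t), df),
       flags = flags)
}

#' Paired t-test
#'
#' One-sample t-test on the pair differences, df = n - 1. All-zero
#' differences give p = 1 by convention, flagged; zero variance with a
#' nonzero mean difference gives p = 0, flagged.
#'
#' @param x,y Numeric vectors of equal length >= 2 (pairs), or `y`
#'   omitted and `x` a two-column matrix/data.frame of pairs.
#' @return List with `statistic`, `df`, `p.value`, `flags`.
#' @export
paired_t_test <- function(x, y = NULL) {
  if (is.null(y)) {
    x <- as.matrix(x)
    stopifnot(ncol(x) == 2L)
    y <- x[, 2L]; x <- x[, 1L]
  }
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  d <- x - y
  md <- mean(d); vd <- stats::var(d)
  if (vd == 0) {
    if (md == 0)
      return(list(statistic = 0, df = n - 1, p.value = 1,
                  flags = "degenerate_all_differences_zero"))
    return(list(statistic = sign(md) * Inf, df = n - 1, p.value = 0,
                flags = "degenerate_zero_variance"))
  }
  t <- md / sqrt(vd / n)
  list(statistic = t, df = n - 1, p.value = 2 * pt(-abs(t), n - 1),
       flags = character())
}
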