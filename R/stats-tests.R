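#' Pooled-variance two-sample t test from group summaries
#'
#' Student's pooled two-sample t computed directly from per-group mean, SD
#' and n — usable on published summary tables as well as raw samples. The
#' statistic's sign follows `group1 - group2` and the degrees of freedom are
#' `n1 + n2 - 2`.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`,
#'   `estimate` (mean difference).
#' @examples
#' student_t_from_summaries(0.655, 0.063, 23, 0.615, 0.068, 45)
#' @export
student_t_from_summaries <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean1 - mean2) / se
  tibble::tibble(method = "student_t", statistic = t, df = df,
                 p_value = 2 * stats::pt(-abs(t), df),
                 estimate = mean1 - mean2)
}

#' @rdname student_t_from_summaries
#' @param x,y Raw samples (summaries are computed internally; identical to
#'   the summary path).
#' @export
student_t <- function(x, y) {
  student_t_from_summaries(mean(x), stats::sd(x), length(x),
                           mean(y), stats::sd(y), length(y))
}

#' Mann-Whitney U test with normal approximation
#'
#' Rank-sum test with midrank tie handling. The U statistic is reported for
#' the first sample; the Z statistic uses the tie-corrected variance and a
#' continuity correction, with sign following the tendency of `x` relative
#' to `y` (swapping the samples flips the sign). If every value is tied
#' across both samples, `Z = 0` and `p = 1`.
#'
#' @param x,y Numeric samples.
#' @return One-row tibble: `method`, `statistic` (Z), `u`, `p_value`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("samples must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v <= 0) {
    return(tibble::tibble(method = "mann_whitney", statistic = 0,
                          u = u, p_value = 1))
  }
  cc <- sign(u - mu) * 0.5
  z <- (u - mu - cc) / sqrt(v)
  tibble::tibble(method = "mann_whitney", statistic = z, u = u,
                 p_value = 2 * stats::pnorm(-abs(z)))
}

#' Pearson chi-square test on a contingency table
#'
#' @param counts Matrix (or table) of non-negative integer counts, at least
#'   2 x 2, rows = categories, columns = groups. A zero row or column
#'   marginal is an error.
#' @param correct Apply Yates continuity correction (2 x 2 only); off by
#'   default, matching the reference analysis.
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal in the contingency table", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  tibble::tibble(method = "chi_square", statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value)
}
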