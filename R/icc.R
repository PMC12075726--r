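#' Intraclass correlation coefficient, two-way absolute agreement
#'
#' Single-measurement ICC under the two-way random-effects, absolute-
#' agreement model (ICC(A,1) in the McGraw-Wong taxonomy), the form used to
#' quantify intra- and interobserver reproducibility of the parameter
#' measurements. Computed from the two-way ANOVA mean squares
#' (rows = cases, columns = raters/sessions):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with the F-based 95% confidence interval using the Satterthwaite
#' approximation for the denominator degrees of freedom.
#'
#' @param measurements Numeric matrix or data frame, one row per case, one
#'   column per rater (or session). At least 5 cases and 2 raters, no
#'   missing cells.
#' @param flavor `"inter"` (different observers) or `"intra"` (repeated
#'   sessions of one observer); a label only — the model is the same.
#' @param conf_level Confidence level for the interval.
#' @return One-row tibble: `icc`, `conf_low`, `conf_high`, `model`,
#'   `flavor`, `n`, `k`.
#' @examples
#' m <- cbind(rater1 = c(9, 6, 8, 7, 10, 6), rater2 = c(2, 1, 4, 1, 5, 2))
#' icc_agreement(m)
#' @export
icc_agreement <- function(measurements, flavor = c("inter", "intra"),
                          conf_level = 0.95) {
  flavor <- match.arg(flavor)
  m <- as.matrix(measurements)
  storage.mode(m) <- "double"
  n <- nrow(m); k <- ncol(m)
  if (n < 5L) stop("need at least 5 cases", call. = FALSE)
  if (k < 2L) stop("need at least 2 raters", call. = FALSE)
  if (anyNA(m)) stop("missing cells are not supported", call. = FALSE)
  if (stats::var(as.vector(m)) == 0) {
    stop("ICC is undefined for a constant measurement matrix", call. = FALSE)
  }

  g <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - g)^2)
  ssc <- n * sum((col_m - g)^2)
  sst <- sum((m - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf_level
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) *
    (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)

  tibble::tibble(icc = icc, conf_low = lower, conf_high = upper,
                 model = "two-way random, absolute agreement, single measurement",
                 flavor = flavor, n = n, k = k)
}
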