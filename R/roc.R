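#' Empirical ROC analysis with Youden-index cutoff
#'
#' Builds the empirical ROC curve of a continuous score against a binary
#' label, reports the trapezoidal AUC (identical to the Mann-Whitney
#' `U/(n1*n2)` statistic), and selects the cutoff maximizing the Youden
#' index `sensitivity + specificity - 1`; exact Youden ties are broken
#' toward the higher specificity.
#'
#' @param scores Numeric score per case.
#' @param labels Class label per case (two classes required).
#' @param positive Label of the positive class (default: metastatic).
#' @param higher_is_positive Direction of the score: `TRUE` if larger values
#'   indicate the positive class. Scores are negated internally otherwise and
#'   the cutoff is reported on the original scale.
#' @return A `dwi_roc` object; see [glance.dwi_roc()] for the one-row
#'   summary (auc, cutoff, sensitivity, specificity, youden).
#' @examples
#' cohort <- sample_cohort(seed = 1)
#' r <- empirical_roc(cohort$beta_ctrw, cohort$group)
#' glance(r)
#' @export
empirical_roc <- function(scores, labels, positive = "metastatic",
                          higher_is_positive = TRUE) {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("labels must contain exactly two classes",
                             call. = FALSE)
  if (!positive %in% lv) stop("positive class not present in labels",
                              call. = FALSE)
  negative <- setdiff(lv, positive)
  s <- if (higher_is_positive) scores else -scores
  r <- pROC::roc(response = labels, predictor = s,
                 levels = c(negative, positive), direction = "<",
                 quiet = TRUE)
  co <- pROC::coords(r, "all", ret = c("threshold", "sensitivity",
                                       "specificity"), transpose = FALSE)
  co$youden <- co$sensitivity + co$specificity - 1
  best <- co[co$youden == max(co$youden), , drop = FALSE]
  best <- best[order(-best$specificity), , drop = FALSE][1, ]
  cutoff <- if (higher_is_positive) best$threshold else -best$threshold
  structure(
    list(auc = as.numeric(pROC::auc(r)), cutoff = cutoff,
         sensitivity = best$sensitivity, specificity = best$specificity,
         youden = best$youden, positive = positive,
         higher_is_positive = higher_is_positive,
         coords = tibble::as_tibble(co), roc = r,
         scores = s, labels = labels),
    class = "dwi_roc"
  )
}

#' @export
print.dwi_roc <- function(x, ...) {
  cat(sprintf(
    "<dwi_roc> AUC %.3f, cutoff %.4g (sens %.3f, spec %.3f, Youden %.3f)\n",
    x$auc, x$cutoff, x$sensitivity, x$specificity, x$youden))
  invisible(x)
}

#' @rdname empirical_roc
#' @param x A `dwi_roc` object.
#' @param ... Unused.
#' @export
glance.dwi_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, cutoff = x$cutoff, youden = x$youden,
                 sensitivity = x$sensitivity, specificity = x$specificity)
}

#' @rdname empirical_roc
#' @export
tidy.dwi_roc <- function(x, ...) x$coords

#' Closed-form AUC of two normal score distributions
#'
#' Under binormal score distributions the AUC is
#' `pnorm(|mean_pos - mean_neg| / sqrt(sd_pos^2 + sd_neg^2))`. Used as a
#' consistency check linking published group summaries to published
#' empirical AUCs.
#'
#' @param mean_pos,sd_pos Positive-class score distribution.
#' @param mean_neg,sd_neg Negative-class score distribution.
#' @return AUC in \[0.5, 1\].
#' @examples
#' binormal_auc(0.688, 0.074, 0.782, 0.084) # ~ 0.80
#' @export
binormal_auc <- function(mean_pos, sd_pos, mean_neg, sd_neg) {
  if (sd_pos <= 0 || sd_neg <= 0) stop("SDs must be positive", call. = FALSE)
  stats::pnorm(abs(mean_pos - mean_neg) / sqrt(sd_pos^2 + sd_neg^2))
}

#' DeLong comparison of two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same cases using the
#' DeLong structural-components variance estimate and a two-sided z test.
#' Rank-identical scores (including any monotone transform) have AUC
#' difference 0 with zero variance; that degenerate case returns `p = 1` by
#' convention.
#'
#' @param scores_a,scores_b Paired scores on the same cases.
#' @param labels Class label per case.
#' @param positive Label of the positive class.
#' @return One-row tibble: `auc_a`, `auc_b`, `auc_diff`, `var_a`, `var_b`,
#'   `cov_ab`, `statistic` (z), `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, labels,
                           positive = "metastatic") {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("labels must contain exactly two classes",
                             call. = FALSE)
  negative <- setdiff(lv, positive)
  ra <- pROC::roc(labels, scores_a, levels = c(negative, positive),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(labels, scores_b, levels = c(negative, positive),
                  direction = "<", quiet = TRUE)
  auc_a <- as.numeric(pROC::auc(ra)); auc_b <- as.numeric(pROC::auc(rb))
  var_a <- pROC::var(ra, method = "delong")
  var_b <- pROC::var(rb, method = "delong")
  cov_ab <- pROC::cov(ra, rb, method = "delong")
  var_diff <- var_a + var_b - 2 * cov_ab
  if (abs(auc_a - auc_b) < 1e-12 && var_diff < 1e-14) {
    z <- 0; p <- 1
  } else {
    ht <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    z <- unname(ht$statistic); p <- ht$p.value
  }
  tibble::tibble(auc_a = auc_a, auc_b = auc_b, auc_diff = auc_a - auc_b,
                 var_a = var_a, var_b = var_b, cov_ab = cov_ab,
                 statistic = z, p_value = p)
}
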