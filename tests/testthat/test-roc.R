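test_that("perfectly separated scores give AUC = 1 and Youden = 1", {
  labels <- rep(c("benign", "metastatic"), each = 5)
  scores <- c(1:5, 11:15)
  r <- empirical_roc(scores, labels)
  expect_equal(r$auc, 1)
  expect_equal(r$youden, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_true(r$cutoff > 5 && r$cutoff < 11)
  expect_error(empirical_roc(scores, rep("metastatic", 10)), "two classes")
})

test_that("AUC equals the Mann-Whitney identity on random data", {
  set.seed(61)
  for (i in 1:50) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    pos <- stats::rnorm(n1, 0.5)
    neg <- stats::rnorm(n2)
    if (i %% 3 == 0) {  # force ties
      pos <- round(pos, 1); neg <- round(neg, 1)
    }
    labels <- rep(c("metastatic", "benign"), c(n1, n2))
    r <- empirical_roc(c(pos, neg), labels)
    expect_equal(r$auc, rank_auc(pos, neg), tolerance = 1e-12)
  }
})

test_that("the Youden cutoff maximizes Youden, ties broken to specificity", {
  set.seed(62)
  for (i in 1:20) {
    scores <- sample(1:6, 30, replace = TRUE)  # heavy ties
    labels <- ifelse(stats::runif(30) < stats::plogis(scores - 3.5),
                     "metastatic", "benign")
    if (length(unique(labels)) < 2) next
    r <- empirical_roc(scores, labels)
    expect_equal(r$youden, r$sensitivity + r$specificity - 1, tolerance = 1e-12)
    expect_equal(r$youden, max(r$coords$youden), tolerance = 1e-12)
    at_max <- r$coords[abs(r$coords$youden - r$youden) < 1e-12, ]
    expect_equal(r$specificity, max(at_max$specificity), tolerance = 1e-12)
  }
})

test_that("orientation flips are transparent to the user", {
  set.seed(63)
  # metric lower in the positive class
  pos <- stats::rnorm(30, 0.6, 0.07); neg <- stats::rnorm(20, 0.7, 0.07)
  labels <- rep(c("metastatic", "benign"), c(30, 20))
  r <- empirical_roc(c(pos, neg), labels, higher_is_positive = FALSE)
  expect_gt(r$auc, 0.5)
  # the reported cutoff is on the original scale
  expect_true(r$cutoff > min(pos) && r$cutoff < max(neg))
  sens <- mean(pos < r$cutoff)
  expect_equal(r$sensitivity, sens, tolerance = 1e-12)
})

test_that("binormal AUC matches its limits and a Monte-Carlo oracle", {
  expect_equal(binormal_auc(1, 0.3, 1, 0.4), 0.5)
  # reference D-type summaries put the closed form near the reported AUC
  expect_equal(binormal_auc(0.688, 0.074, 0.782, 0.084), 0.800,
               tolerance = 0.002)
  set.seed(64)
  mc <- mean(stats::rnorm(1e6, 0.688, 0.074) < stats::rnorm(1e6, 0.782, 0.084))
  expect_equal(binormal_auc(0.688, 0.074, 0.782, 0.084), mc,
               tolerance = 0.002)
  expect_error(binormal_auc(1, 0, 0, 1), "positive")
})

test_that("DeLong degenerate cases return p = 1", {
  set.seed(65)
  s <- stats::rnorm(40)
  labels <- rep(c("metastatic", "benign"), 20)
  same <- delong_compare(s, s, labels)
  expect_equal(same$p_value, 1)
  expect_equal(same$auc_diff, 0)
  # a monotone transform has identical ranks
  mono <- delong_compare(s, exp(2 * s) + 3, labels)
  expect_equal(mono$p_value, 1)
  expect_equal(mono$auc_diff, 0)
})

test_that("DeLong single-AUC variance matches the structural-components oracle", {
  set.seed(66)
  for (i in 1:5) {
    pos <- stats::rnorm(8, 0.8); neg <- stats::rnorm(8)
    labels <- rep(c("metastatic", "benign"), each = 8)
    res <- delong_compare(c(pos, neg), stats::rnorm(16), labels)
    expect_equal(res$var_a, delong_var_oracle(pos, neg), tolerance = 1e-10)
    expect_equal(res$auc_a, rank_auc(pos, neg), tolerance = 1e-12)
  }
})
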