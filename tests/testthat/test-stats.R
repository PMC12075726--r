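test_that("pooled t from summaries equals the raw-sample path and base R", {
  set.seed(51)
  x <- stats::rnorm(23, 0.65, 0.06); y <- stats::rnorm(45, 0.61, 0.07)
  a <- student_t(x, y)
  b <- student_t_from_summaries(mean(x), stats::sd(x), 23,
                                mean(y), stats::sd(y), 45)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  ht <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(a$statistic, unname(ht$statistic), tolerance = 1e-12)
  expect_equal(a$p_value, ht$p.value, tolerance = 1e-12)
  expect_equal(a$df, 66)
})

test_that("pooled t degenerates sensibly", {
  same <- student_t_from_summaries(1, 0.2, 10, 1, 0.2, 12)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(student_t_from_summaries(1, 0.2, 1, 1, 0.2, 12), "n >= 2")
  expect_error(student_t_from_summaries(1, 0, 10, 1, 0.2, 12), "positive")
})

test_that("Mann-Whitney handles separation, symmetry and ties", {
  lo <- 1:5; hi <- 6:10
  r1 <- mann_whitney(lo, hi)
  expect_equal(r1$u, 0)
  r2 <- mann_whitney(hi, lo)
  expect_equal(r2$u, 25)  # n1 * n2
  expect_equal(r2$statistic, -r1$statistic, tolerance = 1e-12)
  tied <- mann_whitney(rep(2, 4), rep(2, 6))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)
})

test_that("Mann-Whitney p matches wilcox.test and the exact enumeration", {
  set.seed(52)
  for (i in 1:10) {
    x <- stats::rnorm(12); y <- stats::rnorm(15, 0.5)
    ours <- mann_whitney(x, y)
    wt <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                              exact = FALSE))
    expect_equal(ours$p_value, wt$p.value, tolerance = 1e-10)
    expect_equal(ours$u, unname(wt$statistic), tolerance = 1e-12)
  }
  # small-sample normal approximation vs the exhaustive permutation null,
  # over every achievable U at n1 = n2 = 4: within 0.02 wherever the exact
  # p is in the decision-relevant tail, within 0.035 everywhere (the
  # worst mid-range deviation of the corrected approximation is 0.031)
  vals <- 1:8
  for (idx in list(1:4, c(1, 2, 3, 5), c(1, 2, 4, 6), c(1, 3, 5, 7),
                   c(2, 4, 6, 8), c(3, 5, 7, 8), 5:8)) {
    x <- vals[idx]; y <- vals[-idx]
    d <- abs(mann_whitney(x, y)$p_value - mw_exact_p_oracle(x, y))
    expect_lt(d, 0.035)
    if (mw_exact_p_oracle(x, y) <= 0.25) expect_lt(d, 0.02)
  }
})

test_that("chi-square matches the expected-counts formula", {
  # identical row proportions
  even <- rbind(c(10, 20), c(5, 10))
  expect_equal(chi_square_test(even)$statistic, 0, tolerance = 1e-12)
  # balanced diagonal 2x2
  expect_equal(chi_square_test(rbind(c(10, 0), c(0, 10)))$statistic, 20,
               tolerance = 1e-12)
  # direct formula oracle on a 2x2 of cohort sex counts
  tab <- rbind(c(12, 11), c(31, 14))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  oracle <- sum((tab - e)^2 / e)
  res <- chi_square_test(tab)
  expect_equal(res$statistic, oracle, tolerance = 1e-9)
  expect_equal(res$df, 1)
  expect_error(chi_square_test(rbind(c(0, 0), c(3, 4))), "marginal")
  expect_error(chi_square_test(matrix(2, 1, 2)), "2 x 2")
})

test_that("ICC(A,1) matches an ANOVA-table oracle and its limits", {
  m <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  res <- icc_agreement(m)
  # oracle: mean squares from stats::aov on the long layout
  long <- data.frame(y = as.vector(m),
                     case = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(y ~ case + rater, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 6; k <- 2
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(res$icc, oracle, tolerance = 1e-10)
  expect_true(res$conf_low <= res$icc && res$icc <= res$conf_high)

  # duplicated raters agree perfectly
  dup <- icc_agreement(cbind(m[, 1], m[, 1]))
  expect_equal(dup$icc, 1, tolerance = 1e-12)

  # overwhelming rater noise destroys agreement
  set.seed(53)
  x <- stats::rnorm(1000)
  noisy <- icc_agreement(cbind(x, x + stats::rnorm(1000, sd = 10)))
  expect_lt(noisy$icc, 0.05)

  expect_error(icc_agreement(matrix(1, 6, 2)), "constant")
  expect_error(icc_agreement(m[1:4, ]), "5 cases")
})

test_that("logistic ORs match the 2x2 closed form and the null is calibrated", {
  # single binary predictor: OR = ad/bc
  df <- data.frame(
    group = rep(c("benign", "metastatic"), times = c(30, 40)),
    xbin = c(rep(c(0, 1), times = c(20, 10)), rep(c(0, 1), times = c(15, 25))))
  fit <- fit_logistic(df, "group", "xbin")
  or_closed <- (25 / 15) / (10 / 20)
  expect_equal(tidy(fit)$or, or_closed, tolerance = 1e-6)

  # independence: OR per unit within [0.95, 1.05] at n = 10,000
  set.seed(54)
  df0 <- data.frame(group = sample(c("benign", "metastatic"), 10000, TRUE),
                    x = stats::rnorm(10000))
  fit0 <- fit_logistic(df0, "group", "x")
  expect_gt(tidy(fit0)$or, 0.95)
  expect_lt(tidy(fit0)$or, 1.05)

  # perfect separation is an explicit error
  dfs <- data.frame(group = rep(c("benign", "metastatic"), each = 20),
                    x = c(stats::rnorm(20), stats::rnorm(20) + 100))
  expect_error(fit_logistic(dfs, "group", "x"), "separation")
})

test_that("diffusion parameters report odds ratios per 0.001 units", {
  co <- sample_cohort(seed = 55)
  fit <- fit_logistic(co, "group", "beta_ctrw")
  td <- tidy(fit)
  expect_equal(td$or_scale, 0.001)
  expect_equal(td$or, exp(td$estimate * 0.001), tolerance = 1e-12)
  expect_true(td$or_low < td$or && td$or < td$or_high)
})

test_that("forward stepwise only keeps predictors passing the entry threshold", {
  set.seed(56)
  n <- 400
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n); x3 <- stats::rnorm(n)
  p <- stats::plogis(1.5 * x1)
  df <- data.frame(group = ifelse(stats::runif(n) < p, "metastatic", "benign"),
                   x1 = x1, x2 = x2, x3 = x3)
  fit <- fit_logistic(df, "group", c("x1", "x2", "x3"),
                      selection = "forward_stepwise")
  expect_true("x1" %in% fit$selected)
  expect_true(all(tidy(fit)$p_value < 0.05))
})
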