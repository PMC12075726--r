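b12 <- default_b_values()

test_that("normalize_signal rescales to S(0) = 1 and is idempotent", {
  p <- bvalue_protocol(c(0, 1))
  out <- normalize_signal(c(100, 50), p)
  expect_equal(out$signal, c(1, 0.5))
  out2 <- normalize_signal(out$signal, p)
  expect_equal(out2, out)
  expect_error(normalize_signal(c(0, 50), p), "degenerate")
  expect_error(normalize_signal(c(-3, 50), p), "degenerate")
  expect_error(normalize_signal(c(100, 50, 10), p), "does not match")
})

test_that("stage-1 D equals the independent log-linear oracle", {
  set.seed(21)
  for (i in 1:10) {
    p <- draw_model_params("froc")
    dec <- tibble::tibble(b = b12, signal = signal_froc(b12, p[1], p[2], p[3]))
    fit <- fit_decay(dec, "froc")
    keep <- dec$b <= 1
    oracle <- -unname(stats::coef(stats::lm(log(signal) ~ b,
                                            data = dec[keep, ]))[2])
    expect_equal(fit$stage1_d, oracle, tolerance = 1e-8)
    # stage 2 reproduces the curve and the heterogeneity exponent exactly
    expect_lt(fit$rss, 1e-12)
    expect_equal(unname(fit$params["beta_froc"]), unname(p["beta_froc"]),
                 tolerance = 1e-4)
  }
})

test_that("changing b-values above the D-estimation threshold never moves stage-1 D", {
  dec <- tibble::tibble(b = b12, signal = signal_ctrw(b12, 0.7, 0.65, 0.85))
  f1 <- fit_decay(dec, "ctrw")
  dec2 <- dec
  dec2$signal[dec2$b > 1] <- dec2$signal[dec2$b > 1] * 0.8
  f2 <- fit_decay(dec2, "ctrw")
  expect_identical(f1$stage1_d, f2$stage1_d)
})

test_that("a mono-exponential curve fit with the SEM model hits the nested limit", {
  dec <- tibble::tibble(b = b12, signal = signal_monoexp(b12, 0.655))
  fit <- fit_decay(dec, "sem")
  expect_true(fit$converged)
  expect_gte(fit$params[["alpha_sem"]], 0.999)
  expect_equal(fit$params[["ddc"]], 0.655, tolerance = 1e-4)
})

test_that("the CTRW example curve is recovered and beats a grid-search oracle", {
  truth <- c(d_ctrw = 0.70, alpha_ctrw = 0.65, beta_ctrw = 0.85)
  dec <- tibble::tibble(b = b12,
                        signal = signal_ctrw(b12, 0.70, 0.65, 0.85))
  fit <- fit_decay(dec, "ctrw", fit_config(refit_d = TRUE))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params - truth) / truth), 1e-3)
  # dense grid-search oracle: the LM solution must be at least as good
  grid <- expand.grid(d = seq(0.5, 0.9, by = 0.02),
                      a = seq(0.45, 0.95, by = 0.025),
                      be = seq(0.65, 1, by = 0.025))
  rss <- vapply(seq_len(nrow(grid)), function(i) {
    sum((dec$signal - signal_ctrw(b12, grid$d[i], grid$a[i], grid$be[i]))^2)
  }, numeric(1))
  expect_lte(fit$rss, min(rss) + 1e-12)
})

test_that("noiseless curves round-trip for the identifiable models", {
  set.seed(31)
  cfg <- fit_config(refit_d = TRUE)
  for (m in c("monoexp", "sem", "ctrw")) {
    for (i in 1:15) {
      p <- draw_model_params(m)
      dec <- tibble::tibble(b = b12, signal = signal_model(m, b12, p))
      fit <- fit_decay(dec, m, cfg)
      expect_true(fit$converged)
      expect_lt(max(abs(fit$params - p) / p), 1e-3)
    }
  }
})

test_that("underdetermined input and non-positive signals are rejected", {
  expect_error(
    fit_decay(tibble::tibble(b = c(0, 0.5, 1), signal = c(1, 0.7, 0.5)),
              "ctrw"),
    "more b-values")
  dec <- tibble::tibble(b = b12, signal = signal_monoexp(b12, 0.6))
  dec$signal[5] <- -0.1
  expect_error(fit_decay(dec, "monoexp"), "positive")
})

test_that("tidy, glance and fitted_decay expose the fit", {
  dec <- tibble::tibble(b = b12, signal = signal_sem(b12, 0.72, 0.69))
  fit <- fit_decay(dec, "sem")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("ddc", "alpha_sem"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_b, 12)
  expect_equal(fitted_decay(fit, 0), 1)
})
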