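# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# direct power-series Mittag-Leffler summation (terms assembled in log space
# so small orders do not overflow; still an independent summation path)
ml_series_oracle <- function(z, alpha, terms = 2000L) {
  vapply(z, function(zz) {
    if (zz == 0) return(1)
    k <- 1:terms
    1 + sum((-1)^k * exp(k * log(abs(zz)) - lgamma(1 + alpha * k)))
  }, numeric(1))
}

# Rician corruption of a noiseless signal vector
rician_noise <- function(s, sigma) {
  sqrt((s + sigma * stats::rnorm(length(s)))^2 +
         (sigma * stats::rnorm(length(s)))^2)
}

# trapezoidal AUC via the rank / Mann-Whitney identity, orientation:
# P(pos > neg) + 0.5 P(tie)
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  m <- length(pos)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(neg))
}

# DeLong structural components of one AUC, from the definition
delong_var_oracle <- function(pos, neg) {
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(pos, function(x) mean(psi(x, neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean(psi(pos, y)), numeric(1))
  stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
}

# exhaustive permutation p-value of the Mann-Whitney U (two-sided)
mw_exact_p_oracle <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x); n <- length(all_v)
  r <- rank(all_v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  picks <- utils::combn(n, n1)
  u_all <- apply(picks, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# curve draws from the physiologically informative regime
draw_model_params <- function(model) {
  switch(model,
    monoexp = c(adc = stats::runif(1, 0.3, 1.5)),
    sem = c(ddc = stats::runif(1, 0.3, 1.5),
            alpha_sem = stats::runif(1, 0.4, 0.99)),
    froc = c(d_froc = stats::runif(1, 0.3, 1.5),
             beta_froc = stats::runif(1, 0.4, 0.99),
             mu_froc = stats::runif(1, 1.5, 8)),
    ctrw = c(d_ctrw = stats::runif(1, 0.3, 1.5),
             alpha_ctrw = stats::runif(1, 0.4, 0.99),
             beta_ctrw = stats::runif(1, 0.4, 0.99))
  )
}

# parameter draws from the reference cohort distributions (random group)
draw_cohort_params <- function(model) {
  ref <- reference_parameter_summaries()
  pn <- model_parameters(model)
  r <- ref[match(pn, ref$parameter), ]
  benign <- stats::runif(1) < 0.5
  m <- if (benign) r$benign_mean else r$metastatic_mean
  s <- if (benign) r$benign_sd else r$metastatic_sd
  v <- stats::rnorm(length(pn), m, s)
  lo <- ifelse(pn %in% c("alpha_sem", "beta_froc", "alpha_ctrw", "beta_ctrw"),
               0.05, 0.05)
  hi <- ifelse(pn %in% c("alpha_sem", "beta_froc", "alpha_ctrw", "beta_ctrw"),
               1, ifelse(pn == "mu_froc", 50, 5))
  stats::setNames(pmin(pmax(v, lo), hi), pn)
}
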