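#' Fitting configuration
#'
#' Controls the nonlinear least-squares estimation of the decay models.
#'
#' @param d_estimation_b_max Upper b-value (ms/um^2) of the sub-protocol used
#'   to estimate the D-type coefficient of the FROC and CTRW models by
#'   log-linear regression (stage 1). Default 1.0 (i.e. b <= 1000 s/mm^2).
#' @param adc_b_max Upper b-value for the mono-exponential ADC fit. Default
#'   `Inf` (all b-values); set to `d_estimation_b_max` to exclude the
#'   strongly non-Gaussian tail, which shifts ADC when the decay is
#'   non-mono-exponential.
#' @param refit_d If `TRUE`, the FROC/CTRW stage-2 fit re-estimates D jointly
#'   with the shape parameters (stage 1 then only seeds the optimizer). The
#'   default `FALSE` keeps D fixed at its stage-1 value.
#' @param lower,upper Named parameter bounds. Defaults: D-type coefficients
#'   in \[1e-4, 5\] um^2/ms, heterogeneity exponents in \[0.01, 1\], mu in
#'   \[0.1, 50\] um.
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @param ftol,ptol Convergence tolerances passed to the optimizer.
#' @return A `fit_config` list.
#' @export
fit_config <- function(d_estimation_b_max = 1.0, adc_b_max = Inf,
                       refit_d = FALSE,
                       lower = default_bounds()$lower,
                       upper = default_bounds()$upper,
                       max_iter = 200L, ftol = 1e-12, ptol = 1e-12) {
  stopifnot(d_estimation_b_max > 0, adc_b_max > 0)
  structure(
    list(d_estimation_b_max = d_estimation_b_max, adc_b_max = adc_b_max,
         refit_d = isTRUE(refit_d), lower = lower, upper = upper,
         max_iter = as.integer(max_iter), ftol = ftol, ptol = ptol),
    class = "fit_config"
  )
}

#' @rdname fit_config
#' @export
default_bounds <- function() {
  d_pars <- c("adc", "ddc", "d_froc", "d_ctrw")
  shape <- c("alpha_sem", "beta_froc", "alpha_ctrw", "beta_ctrw")
  lower <- c(stats::setNames(rep(1e-4, 4), d_pars),
             stats::setNames(rep(0.01, 4), shape), mu_froc = 0.1)
  upper <- c(stats::setNames(rep(5, 4), d_pars),
             stats::setNames(rep(1, 4), shape), mu_froc = 50)
  list(lower = lower, upper = upper)
}

#' Normalize a raw decay to S(b)/S(0)
#'
#' @param signal Raw signal intensities, one per protocol b-value.
#' @param protocol A [bvalue_protocol()].
#' @return A tibble with columns `b` and `signal`, `signal[b == 0] == 1`.
#'   Idempotent: normalizing twice equals normalizing once.
#' @export
normalize_signal <- function(signal, protocol = bvalue_protocol()) {
  signal <- as.numeric(signal)
  if (length(signal) != length(protocol$b)) {
    stop("signal length does not match the protocol", call. = FALSE)
  }
  s0 <- signal[1]
  if (!is.finite(s0) || s0 <= 0) {
    stop("degenerate voxel: signal at b = 0 must be positive",
         call. = FALSE)
  }
  tibble::tibble(b = protocol$b, signal = signal / s0)
}

# log-linear estimate of the mono-exponential coefficient over b <= b_max
loglinear_d <- function(decay, b_max = Inf) {
  keep <- decay$b <= b_max & decay$signal > 0
  if (sum(keep) < 2L) stop("too few positive signals for a log-linear fit",
                           call. = FALSE)
  fit <- stats::lm.fit(cbind(1, decay$b[keep]), log(decay$signal[keep]))
  unname(-fit$coefficients[2])
}

# deterministic initializer lattices over the shape parameters (5 starts)
fit_starts <- function(model, d_init, config) {
  clamp <- function(p) pmin(pmax(p, config$lower[names(p)]),
                            config$upper[names(p)])
  starts <- switch(model,
    monoexp = list(c(adc = d_init)),
    sem = lapply(c(0.99, 0.9, 0.7, 0.5, 0.3), function(a) {
      c(ddc = d_init, alpha_sem = a)
    }),
    froc = lapply(list(c(0.9, 3), c(0.99, 2), c(0.7, 4), c(0.5, 8),
                       c(0.3, 15)), function(s) {
      c(d_froc = d_init, beta_froc = s[1], mu_froc = s[2])
    }),
    ctrw = lapply(list(c(0.9, 0.9), c(0.99, 0.99), c(0.7, 0.9), c(0.9, 0.7),
                       c(0.6, 0.8), c(0.9, 0.45), c(0.5, 0.5),
                       c(0.9, 0.6)), function(s) {
      c(d_ctrw = d_init, alpha_ctrw = s[1], beta_ctrw = s[2])
    })
  )
  lapply(starts, clamp)
}

#' Fit one signal decay with a decay model
#'
#' Estimates the parameters of one of the four models from a normalized
#' multi-b-value decay by damped (Levenberg-Marquardt) least squares with
#' box constraints and a deterministic multi-start initializer lattice; the
#' lowest-residual converged start wins.
#'
#' The FROC and CTRW fits follow a two-stage strategy: the D-type
#' coefficient is first estimated by log-linear (mono-exponential)
#' regression over the sub-protocol `b <= d_estimation_b_max`, then the
#' shape parameters are fitted over all b-values with D held fixed (or, with
#' `refit_d = TRUE`, refined jointly). The mono-exponential and SEM fits are
#' single-stage over all b-values.
#'
#' @param decay A data frame with columns `b` (ms/um^2) and `signal`
#'   (normalized; see [normalize_signal()]).
#' @param model One of `"monoexp"`, `"sem"`, `"froc"`, `"ctrw"`.
#' @param config A [fit_config()].
#' @param protocol A [bvalue_protocol()] supplying FROC gradient timing.
#'   Defaults to the decay's own b-values with default timing.
#' @return A `dwi_fit` object: named `params`, `rss`, `converged`,
#'   `n_iter`, `stage1_d` (FROC/CTRW), plus the data and model for
#'   [tidy()]/[glance()]/[autoplot()].
#' @examples
#' b <- default_b_values()
#' decay <- tibble::tibble(b = b, signal = signal_sem(b, 0.72, 0.69))
#' fit <- fit_decay(decay, "sem")
#' tidy(fit)
#' @export
fit_decay <- function(decay, model, config = fit_config(), protocol = NULL) {
  model <- match.arg(model, dwi_models())
  stopifnot(is.data.frame(decay), all(c("b", "signal") %in% names(decay)))
  if (is.null(protocol)) {
    protocol <- bvalue_protocol(decay$b)
  }
  decay <- tibble::tibble(b = as.numeric(decay$b),
                          signal = as.numeric(decay$signal))
  par_names <- model_parameters(model)
  if (nrow(decay) < length(par_names) + 1L) {
    stop("need more b-values than free parameters", call. = FALSE)
  }
  if (any(decay$signal <= 0)) {
    stop("normalized signals must be positive", call. = FALSE)
  }

  two_stage <- model %in% c("froc", "ctrw")
  d_name <- d_parameter(model)
  b_max_d <- if (model == "monoexp") config$adc_b_max else config$d_estimation_b_max
  d_init <- loglinear_d(decay, if (two_stage) b_max_d else min(b_max_d, Inf))
  d_init <- min(max(d_init, config$lower[[d_name]]), config$upper[[d_name]])

  fit_data <- decay
  if (model == "monoexp" && is.finite(config$adc_b_max)) {
    fit_data <- decay[decay$b <= config$adc_b_max, , drop = FALSE]
  }

  free <- if (two_stage && !config$refit_d) setdiff(par_names, d_name) else par_names
  fixed <- if (two_stage && !config$refit_d) stats::setNames(d_init, d_name) else NULL

  resid_fn <- function(p_free) {
    p <- c(p_free, fixed)[par_names]
    names(p) <- par_names
    fit_data$signal - signal_model(model, fit_data$b, p, protocol)
  }

  best <- NULL
  for (start in fit_starts(model, d_init, config)) {
    p0 <- start[free]
    ans <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = resid_fn,
        lower = config$lower[free], upper = config$upper[free],
        control = minpack.lm::nls.lm.control(
          maxiter = config$max_iter, ftol = config$ftol, ptol = config$ptol)
      ),
      error = function(e) NULL
    )
    if (is.null(ans)) next
    rss <- ans$deviance
    if (is.null(best) || rss < best$rss) {
      best <- list(par = ans$par, rss = rss, info = ans$info,
                   n_iter = ans$niter)
    }
  }
  if (is.null(best)) {
    return(new_dwi_fit(model, stats::setNames(rep(NA_real_, length(par_names)),
                                              par_names),
                       rss = NA_real_, converged = FALSE, n_iter = 0L,
                       stage1_d = if (two_stage) d_init else NULL,
                       decay = decay, protocol = protocol, config = config))
  }
  params <- c(unlist(best$par), fixed)[par_names]
  names(params) <- par_names
  # info 1-4: convergence criteria met; 6-7: tolerances tighter than
  # attainable precision (solution found); 5: iteration limit; 0: bad input
  converged <- best$info %in% c(1:4, 6:7) && all(is.finite(params))
  new_dwi_fit(model, params, rss = best$rss, converged = converged,
              n_iter = best$n_iter,
              stage1_d = if (two_stage) d_init else NULL,
              decay = decay, protocol = protocol, config = config)
}

new_dwi_fit <- function(model, params, rss, converged, n_iter, stage1_d,
                        decay, protocol, config) {
  structure(
    list(model = model, params = params, rss = rss, converged = converged,
         n_iter = n_iter, stage1_d = stage1_d, decay = decay,
         protocol = protocol, config = config),
    class = "dwi_fit"
  )
}

#' @export
print.dwi_fit <- function(x, ...) {
  cat("<dwi_fit> model =", x$model,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(round(x$params, 5))
  cat("rss =", signif(x$rss, 5), "in", x$n_iter, "iterations\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.dwi_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @importFrom generics glance
#' @export
glance.dwi_fit <- function(x, ...) {
  tibble::tibble(model = x$model, rss = x$rss, converged = x$converged,
                 n_iter = x$n_iter, n_b = nrow(x$decay))
}

#' Fitted decay curve of a `dwi_fit`
#'
#' @param object A [fit_decay()] result.
#' @param b b-values at which to evaluate; defaults to a fine grid over the
#'   fitted range.
#' @param ... Unused.
#' @return Numeric vector of fitted normalized signals.
#' @export
fitted_decay <- function(object, b = NULL, ...) {
  if (is.null(b)) b <- seq(0, max(object$decay$b), length.out = 101)
  signal_model(object$model, b, object$params, object$protocol)
}
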