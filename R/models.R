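#' Forward signal models for multi-b-value diffusion decay
#'
#' Normalized signal `S(b)/S(0)` under the four decay models fitted by the
#' pipeline. All take b in ms/um^2 and diffusion coefficients in um^2/ms, and
#' return values in (0, 1] with `S(0)/S(0) = 1`:
#'
#' * **mono-exponential** (Gaussian diffusion):
#'   `exp(-b * ADC)`.
#' * **stretched exponential (SEM)**:
#'   `exp(-(b * DDC)^alpha)` with heterogeneity index `alpha` in (0, 1].
#' * **fractional-order calculus (FROC)**:
#'   `exp(-D * mu^(2*(beta-1)) * q^(2*beta) * (Delta - (2*beta-1)/(2*beta+1) * delta))`
#'   with `q = gamma * G_d * delta` back-computed from b via the protocol
#'   timing; `beta` is the intravoxel heterogeneity exponent and `mu` (um) a
#'   spatial scale that keeps the units of `D`.
#' * **continuous-time random walk (CTRW)**:
#'   `E_alpha(-(b * D)^beta)` with the one-parameter Mittag-Leffler function
#'   [mittag_leffler()]; `alpha` and `beta` capture temporal and spatial
#'   diffusion heterogeneity.
#'
#' Each model reduces to the mono-exponential one when its heterogeneity
#' exponents equal 1.
#'
#' @param b b-value(s), ms/um^2, non-negative.
#' @param adc,ddc,d Diffusion coefficient, um^2/ms, positive.
#' @param alpha,beta Heterogeneity exponents in (0, 1].
#' @param mu Spatial diffusion parameter, um, positive (FROC only).
#' @param protocol A [bvalue_protocol()] supplying gradient timing (FROC only).
#' @return Normalized signal, same length as `b`.
#' @examples
#' b <- default_b_values()
#' signal_monoexp(b, adc = 0.655)
#' signal_ctrw(b, d = 0.70, alpha = 0.65, beta = 0.85)
#' @name signal_models
NULL

check_b <- function(b) {
  if (any(!is.finite(b)) || any(b < 0)) {
    stop("b-values must be finite and non-negative", call. = FALSE)
  }
}

check_pos <- function(x, name) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0)) {
    stop(name, " must be a positive scalar", call. = FALSE)
  }
}

check_unit_interval <- function(x, name) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x <= 1)) {
    stop(name, " must lie in (0, 1]", call. = FALSE)
  }
}

#' @rdname signal_models
#' @export
signal_monoexp <- function(b, adc) {
  check_b(b); check_pos(adc, "adc")
  exp(-b * adc)
}

#' @rdname signal_models
#' @export
signal_sem <- function(b, ddc, alpha) {
  check_b(b); check_pos(ddc, "ddc"); check_unit_interval(alpha, "alpha")
  exp(-(b * ddc)^alpha)
}

#' @rdname signal_models
#' @export
signal_froc <- function(b, d, beta, mu, protocol = bvalue_protocol()) {
  check_b(b); check_pos(d, "d"); check_unit_interval(beta, "beta")
  check_pos(mu, "mu")
  if (!inherits(protocol, "bvalue_protocol")) {
    stop("protocol must be a bvalue_protocol", call. = FALSE)
  }
  q <- froc_q(b, protocol)
  t_eff <- protocol$Delta - (2 * beta - 1) / (2 * beta + 1) * protocol$delta
  exp(-d * mu^(2 * (beta - 1)) * q^(2 * beta) * t_eff)
}

#' @rdname signal_models
#' @export
signal_ctrw <- function(b, d, alpha, beta) {
  check_b(b); check_pos(d, "d")
  check_unit_interval(alpha, "alpha"); check_unit_interval(beta, "beta")
  mittag_leffler(-(b * d)^beta, alpha)
}

#' Evaluate a named decay model
#'
#' Dispatch helper mapping a model name and named parameter vector onto the
#' corresponding forward function. Used by the fitting and phantom modules.
#'
#' @param model One of `"monoexp"`, `"sem"`, `"froc"`, `"ctrw"`.
#' @param b b-value(s), ms/um^2.
#' @param params Named numeric vector with the model's parameters (see
#'   [model_parameters()]).
#' @param protocol A [bvalue_protocol()] (needed by `"froc"`).
#' @return Normalized signal, same length as `b`.
#' @export
signal_model <- function(model, b, params, protocol = bvalue_protocol()) {
  switch(match.arg(model, dwi_models()),
    monoexp = signal_monoexp(b, params[["adc"]]),
    sem = signal_sem(b, params[["ddc"]], params[["alpha_sem"]]),
    froc = signal_froc(b, params[["d_froc"]], params[["beta_froc"]],
                       params[["mu_froc"]], protocol),
    ctrw = signal_ctrw(b, params[["d_ctrw"]], params[["alpha_ctrw"]],
                       params[["beta_ctrw"]])
  )
}

#' Model and parameter naming
#'
#' `dwi_models()` lists the four decay models; `model_parameters()` the
#' parameter names of one model; `diffusion_parameter_names()` the nine
#' parameters the full pipeline maps, in report order.
#'
#' @param model One of `"monoexp"`, `"sem"`, `"froc"`, `"ctrw"`.
#' @return Character vectors of names.
#' @export
dwi_models <- function() c("monoexp", "sem", "froc", "ctrw")

#' @rdname dwi_models
#' @export
model_parameters <- function(model) {
  switch(match.arg(model, dwi_models()),
    monoexp = "adc",
    sem = c("ddc", "alpha_sem"),
    froc = c("d_froc", "beta_froc", "mu_froc"),
    ctrw = c("d_ctrw", "alpha_ctrw", "beta_ctrw")
  )
}

#' @rdname dwi_models
#' @export
diffusion_parameter_names <- function() {
  c("adc", "ddc", "alpha_sem", "d_froc", "beta_froc", "mu_froc",
    "d_ctrw", "alpha_ctrw", "beta_ctrw")
}

# which parameter is the D-type coefficient of each model
d_parameter <- function(model) {
  c(monoexp = "adc", sem = "ddc", froc = "d_froc", ctrw = "d_ctrw")[[model]]
}
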