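#' Binary logistic regression with scaled odds ratios
#'
#' Maximum-likelihood logistic regression of a two-class outcome on numeric
#' predictors, reporting Wald odds ratios and 95% CIs. Because the diffusion
#' coefficients live on a scale of ~0.6 um^2/ms, their odds ratios are
#' reported per 0.001 units (`OR = exp(coefficient * scale)`), which is the
#' convention that puts the published ORs near 1; other predictors default to
#' scale 1 and the scale used is always returned.
#'
#' `selection = "forward_stepwise"` starts from the intercept-only model and
#' repeatedly adds the candidate with the smallest Wald p-value while that
#' p-value is below `entry_p`.
#'
#' Complete separation (a predictor that splits the classes perfectly) is
#' detected and raised as an error rather than returning a silently divergent
#' fit.
#'
#' @param data Data frame with the outcome and predictors.
#' @param outcome Name of the outcome column (two classes).
#' @param predictors Character vector of predictor column names.
#' @param positive Outcome level coded 1 (default `"metastatic"`).
#' @param selection `"none"` (all predictors enter) or `"forward_stepwise"`.
#' @param entry_p Entry threshold for stepwise selection.
#' @param or_scale Named numeric vector of per-predictor OR scales;
#'   defaults to 0.001 for the nine diffusion parameters and 1 otherwise.
#' @return A `dwi_logistic` object; [tidy()] gives the OR table, [glance()]
#'   the fit summary, `$fit` the underlying [stats::glm()] object.
#' @examples
#' cohort <- sample_cohort(seed = 1)
#' fit <- fit_logistic(cohort, "group", c("beta_ctrw", "miad_mm"))
#' tidy(fit)
#' @export
fit_logistic <- function(data, outcome, predictors,
                         positive = "metastatic",
                         selection = c("none", "forward_stepwise"),
                         entry_p = 0.05, or_scale = NULL) {
  selection <- match.arg(selection)
  stopifnot(is.data.frame(data), outcome %in% names(data),
            all(predictors %in% names(data)))
  y <- as.integer(as.character(data[[outcome]]) == positive)
  if (length(unique(y)) != 2L) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  scales <- stats::setNames(rep(1, length(predictors)), predictors)
  diff_pars <- intersect(predictors, diffusion_parameter_names())
  scales[diff_pars] <- 0.001
  if (!is.null(or_scale)) scales[names(or_scale)] <- or_scale

  df <- data.frame(.y = y, data[predictors], check.names = FALSE)

  selected <- predictors
  if (selection == "forward_stepwise") {
    selected <- character(0)
    candidates <- predictors
    repeat {
      if (!length(candidates)) break
      # a candidate whose addition separates the classes is ineligible
      p_cand <- vapply(candidates, function(v) {
        tryCatch(wald_p(glm_safe(df, c(selected, v)))[v],
                 error = function(e) Inf)
      }, numeric(1))
      best <- names(which.min(p_cand))
      if (!length(best) || min(p_cand, na.rm = TRUE) >= entry_p) break
      selected <- c(selected, best)
      candidates <- setdiff(candidates, best)
    }
    if (!length(selected)) {
      stop("forward stepwise selected no predictor at entry p < ", entry_p,
           call. = FALSE)
    }
  }

  fit <- glm_safe(df, selected)
  sm <- summary(fit)$coefficients
  terms <- setdiff(rownames(sm), "(Intercept)")
  sc <- scales[terms]
  est <- sm[terms, "Estimate"]; se <- sm[terms, "Std. Error"]
  zc <- stats::qnorm(0.975)
  tab <- tibble::tibble(
    term = terms,
    estimate = unname(est),
    std_error = unname(se),
    or = unname(exp(est * sc)),
    or_low = unname(exp((est - zc * se) * sc)),
    or_high = unname(exp((est + zc * se) * sc)),
    p_value = unname(sm[terms, "Pr(>|z|)"]),
    or_scale = unname(sc)
  )
  structure(list(fit = fit, table = tab, selected = selected,
                 positive = positive, selection = selection,
                 outcome = outcome),
            class = "dwi_logistic")
}

# glm fit with complete-separation detection
glm_safe <- function(df, vars) {
  fml <- stats::reformulate(sprintf("`%s`", vars), response = ".y")
  fit <- suppressWarnings(stats::glm(fml, data = df, family = stats::binomial()))
  p <- stats::fitted(fit)
  if (fit$deviance < 1e-6 || all(abs(p - round(p)) < 1e-8)) {
    stop("complete separation: the predictor(s) perfectly split the classes",
         call. = FALSE)
  }
  fit
}

wald_p <- function(fit) {
  sm <- summary(fit)$coefficients
  stats::setNames(sm[, "Pr(>|z|)"], rownames(sm))
}

#' @export
print.dwi_logistic <- function(x, ...) {
  cat("<dwi_logistic> outcome =", x$outcome, "| selection =", x$selection,
      "| terms:", paste(x$selected, collapse = ", "), "\n")
  print(x$table)
  invisible(x)
}

#' @rdname fit_logistic
#' @param x A `dwi_logistic` object.
#' @param ... Unused.
#' @export
tidy.dwi_logistic <- function(x, ...) x$table

#' @rdname fit_logistic
#' @export
glance.dwi_logistic <- function(x, ...) {
  tibble::tibble(n = length(x$fit$y), deviance = x$fit$deviance,
                 aic = x$fit$aic, n_terms = length(x$selected))
}

#' Predicted probabilities of a fitted logistic model
#'
#' @param object A `dwi_logistic` object.
#' @param newdata Optional data frame; defaults to the training data.
#' @param ... Unused.
#' @return Numeric vector of probabilities of the positive class.
#' @export
predict.dwi_logistic <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(unname(stats::fitted(object$fit)))
  unname(stats::predict(object$fit, newdata = newdata, type = "response"))
}
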