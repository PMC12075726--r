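#' Multi-b-value acquisition protocol
#'
#' Describes the diffusion-weighting protocol of a multi-b-value DWI
#' acquisition: the b-values themselves plus the gradient timing needed by the
#' fractional-order calculus (FROC) signal model. Internally all b-values are
#' carried in ms/um^2 (1 ms/um^2 = 1000 s/mm^2), matching the um^2/ms unit of
#' the diffusion coefficients.
#'
#' The gradient amplitude is never stored: it is back-computed per b-value
#' from `b = (gamma * G_d * delta)^2 * (Delta - delta/3)`, so only the pulse
#' width `delta` and gradient interval `Delta` have to be supplied. Spatial
#' FROC parameters (mu) are only comparable across runs that use the same
#' timing.
#'
#' @param b_values Numeric vector of b-values, strictly increasing, starting
#'   at 0. Default: the 12-point protocol 0-3 ms/um^2 used throughout.
#' @param delta Gradient pulse width, ms.
#' @param Delta Gradient interval, ms. Must exceed `delta / 3`.
#' @param gamma Gyromagnetic ratio, rad * ms^-1 * mT^-1 (proton default).
#' @param units Units of `b_values`: `"ms/um2"` (canonical) or `"s/mm2"`
#'   (converted on construction).
#' @return A `bvalue_protocol` object (list with `b`, `delta`, `Delta`,
#'   `gamma`).
#' @examples
#' p <- bvalue_protocol()
#' p$b
#' @export
bvalue_protocol <- function(b_values = default_b_values(),
                            delta = 15, Delta = 35, gamma = 2.675e5,
                            units = c("ms/um2", "s/mm2")) {
  units <- match.arg(units)
  b <- as.numeric(b_values)
  if (units == "s/mm2") b <- b / 1000
  if (length(b) < 2L) stop("protocol needs at least two b-values", call. = FALSE)
  if (b[1] != 0) stop("first b-value must be 0", call. = FALSE)
  if (any(diff(b) <= 0)) stop("b-values must be strictly increasing", call. = FALSE)
  if (!(delta > 0 && Delta > delta / 3)) {
    stop("gradient timing must satisfy Delta > delta/3 > 0", call. = FALSE)
  }
  structure(
    list(b = b, delta = delta, Delta = Delta, gamma = gamma),
    class = "bvalue_protocol"
  )
}

#' @rdname bvalue_protocol
#' @export
default_b_values <- function() {
  c(0, 10, 20, 50, 100, 200, 400, 800, 1000, 1500, 2000, 3000) / 1000
}

#' @export
print.bvalue_protocol <- function(x, ...) {
  cat("<bvalue_protocol> ", length(x$b), " b-values, ",
      min(x$b), "-", max(x$b), " ms/um2; delta = ", x$delta,
      " ms, Delta = ", x$Delta, " ms\n", sep = "")
  invisible(x)
}

# gamma*G_d*delta in 1/um, back-computed from b (ms/um^2)
froc_q <- function(b, protocol) {
  sqrt(b / (protocol$Delta - protocol$delta / 3))
}

#' Diffusion gradient amplitude implied by a b-value
#'
#' Inverts `b = (gamma * G_d * delta)^2 * (Delta - delta/3)` for the gradient
#' amplitude `G_d` (mT/um under the canonical units).
#'
#' @param b b-value(s), ms/um^2.
#' @param protocol A [bvalue_protocol()].
#' @return Gradient amplitude(s), same length as `b`.
#' @export
gradient_amplitude <- function(b, protocol) {
  froc_q(b, protocol) / (protocol$gamma * protocol$delta)
}
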