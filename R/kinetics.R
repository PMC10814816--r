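# Kinetics, Jacobian and local Taylor expansion of the reaction terms.

# Ratio-dependent functional response uv/(u+v), defined as 0 at the origin.
# The branch avoids 0/0: for u + v below 1e-300 (or any non-positive
# density) the predation term is 0.
ratio_term <- function(u, v) {
  s <- u + v
  out <- numeric(length(s))
  ok <- (u > 0) & (v > 0) & (s >= 1e-300)
  out[ok] <- u[ok] * v[ok] / s[ok]
  out
}

#' Reaction kinetics of the predator-prey model
#'
#' Evaluates the kinetic (reaction) part of the model,
#' \deqn{f(u,v) = a u (1-u)(u-b) - \frac{uv}{u+v}, \qquad
#'       g(u,v) = \frac{c u v}{u+v} - (d+h) v,}
#' with the convention that the ratio-dependent predation term
#' \eqn{uv/(u+v)} equals 0 at the origin, where it is otherwise undefined.
#'
#' @param u,v prey and predator densities (non-negative, vectorised).
#' @param p a [model_params()] object with a concrete `h`.
#' @return A numeric vector `c(du, dv)` (or a 2-column matrix for
#'   vectorised input) with the prey and predator growth rates.
#' @examples
#' p <- model_params(1.8, 0.2, 0.5, 0.3, h = 0.05774)
#' kinetics(0, 0, p)        # origin convention: exactly (0, 0)
#' kinetics(p$b, 0, p)      # prey-only Allee equilibrium
#' @export
kinetics <- function(u, v, p) {
  stopifnot(inherits(p, "model_params"))
  if (is.na(p$h)) stop("kinetics requires a concrete harvesting rate 'h'")
  if (any(u < 0) || any(v < 0)) stop("densities must be non-negative")
  r <- ratio_term(u, v)
  du <- p$a * u * (1 - u) * (u - p$b) - r
  dv <- p$c * r - (p$d + p$h) * v
  if (length(u) == 1L && length(v) == 1L) c(du = du, dv = dv)
  else cbind(du = du, dv = dv)
}

#' Jacobian of the kinetics
#'
#' Analytic Jacobian of the reaction terms at a point with \eqn{u + v > 0}.
#' At an interior equilibrium the entries reduce to the closed forms
#' \deqn{a_{11} = a u^* (1 + b - 2u^*) + \frac{u^* v^*}{(u^*+v^*)^2}, \quad
#'       a_{12} = -\frac{u^{*2}}{(u^*+v^*)^2}, \quad
#'       a_{21} = \frac{c v^{*2}}{(u^*+v^*)^2}, \quad
#'       a_{22} = -\frac{c u^* v^*}{(u^*+v^*)^2},}
#' so that \eqn{a_{12} < 0} and \eqn{a_{21} > 0} there.
#'
#' @param u,v evaluation point; must satisfy `u + v > 0` (the predation term
#'   is not differentiable at the origin).
#' @param p a [model_params()] object with concrete `h`.
#' @return A 2x2 numeric matrix.
#' @export
jacobian_at <- function(u, v, p) {
  stopifnot(inherits(p, "model_params"), length(u) == 1L, length(v) == 1L)
  if (is.na(p$h)) stop("jacobian_at requires a concrete harvesting rate 'h'")
  if (u + v <= 0) stop("Jacobian undefined at the origin (u + v must be positive)")
  s <- u + v
  matrix(c(p$a * (-3 * u^2 + 2 * (1 + p$b) * u - p$b) - v^2 / s^2,
           -u^2 / s^2,
           p$c * v^2 / s^2,
           p$c * u^2 / s^2 - (p$d + p$h)),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("du", "dv"), c("u", "v")))
}

#' Quadratic and cubic Taylor coefficients of the kinetics
#'
#' Expands the kinetics about an interior point \eqn{(u^*, v^*)}:
#' \deqn{f(u^*+u, v^*+v) = \mathrm{linear} + a_1 u^2 + a_2 uv + a_3 v^2 +
#'   a_4 u^3 + a_5 u^2 v + a_6 u v^2 + a_7 v^3 + \dots}
#' and analogously \eqn{b_1,\dots,b_7} for the predator equation.  The
#' fourteen coefficients are evaluated from their closed forms (with
#' \eqn{s = u^* + v^*}):
#' \deqn{a_1 = a(1+b) - 3au^* + v^{*2}/s^3,\; a_2 = -2u^*v^*/s^3,\;
#'       a_3 = u^{*2}/s^3,}
#' \deqn{a_4 = -a - v^{*2}/s^4,\; a_5 = (2u^*v^* - v^{*2})/s^4,\;
#'       a_6 = (2u^*v^* - u^{*2})/s^4,\; a_7 = -u^{*2}/s^4,}
#' \deqn{b_1 = -c v^{*2}/s^3,\; b_2 = 2c u^* v^*/s^3,\; b_3 = -c u^{*2}/s^3,}
#' \deqn{b_4 = c v^{*2}/s^4,\; b_5 = c(v^{*2} - 2u^*v^*)/s^4,\;
#'       b_6 = c(u^{*2} - 2u^*v^*)/s^4,\; b_7 = c u^{*2}/s^4.}
#' For any interior point these satisfy \eqn{a_3 > 0}, \eqn{a_7 < 0},
#' \eqn{b_3 < 0}, \eqn{b_7 > 0}, and \eqn{b_i = -c\, a_{i}}-type sign
#' relations for the predation-derived pairs (e.g. `b2/a2 = -c`).
#'
#' @param p a [model_params()] object.
#' @param u,v expansion point with `u, v > 0`.
#' @return An object of class `"taylor_coeffs"`: a named list
#'   `a1`..`a7`, `b1`..`b7`.
#' @export
taylor_coeffs <- function(p, u, v) {
  stopifnot(inherits(p, "model_params"))
  if (u <= 0 || v <= 0) stop("Taylor expansion point must be interior (u, v > 0)")
  s <- u + v
  structure(list(
    a1 = p$a * (1 + p$b) - 3 * p$a * u + v^2 / s^3,
    a2 = -2 * u * v / s^3,
    a3 = u^2 / s^3,
    a4 = -p$a - v^2 / s^4,
    a5 = (2 * u * v - v^2) / s^4,
    a6 = (2 * u * v - u^2) / s^4,
    a7 = -u^2 / s^4,
    b1 = -p$c * v^2 / s^3,
    b2 = 2 * p$c * u * v / s^3,
    b3 = -p$c * u^2 / s^3,
    b4 = p$c * v^2 / s^4,
    b5 = p$c * (v^2 - 2 * u * v) / s^4,
    b6 = p$c * (u^2 - 2 * u * v) / s^4,
    b7 = p$c * u^2 / s^4), class = "taylor_coeffs")
}
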