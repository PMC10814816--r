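# Hopf bifurcation in the harvesting rate: threshold location and the
# first Lyapunov coefficient.

#' Trace of the Jacobian at the coexistence equilibrium E2*
#'
#' Evaluates \eqn{\mathrm{Tr}\, J|_{E_2^*}(h)}, whose unique positive zero
#' inside the bracket \eqn{((4(c-d) - ac(b-1)^2)/4,\; c-d)} is the Hopf
#' threshold.  The trace is positive below the threshold (E2* unstable) and
#' negative above it (E2* stable).
#'
#' @param h harvesting rate (vectorised).
#' @param p a [model_params()] object (its `h` slot is ignored).
#' @return Numeric vector of traces; `NA` where E2* does not exist.
#' @export
trace_E2star <- function(h, p) {
  vapply(h, function(hi) {
    pi_ <- model_params(p$a, p$b, p$c, p$d, h = hi, D0 = p$D0, l = p$l)
    eq <- interior_equilibria(pi_)
    e <- eq$E2star
    if (is.null(e)) return(NA_real_)
    J <- jacobian_at(e$u, e$v, pi_)
    J[1, 1] + J[2, 2]
  }, numeric(1))
}

#' Locate the Hopf threshold in the harvesting rate
#'
#' Under H1 and H2 the trace at E2* has a unique zero
#' \eqn{h_H \in \left(\frac{4(c-d) - ac(b-1)^2}{4},\; c-d\right)}.
#' The root is found by bracketed Brent iteration ([stats::uniroot()]) with
#' tolerance `1e-12` on `h`; the bracket endpoints are nudged inward by
#' `1e-9` to avoid the boundary degeneracies (the trace limits are known in
#' closed form at both ends but E2* itself degenerates at the lower one).
#'
#' @param p a [model_params()] object; its `h` slot is ignored.
#' @return The Hopf threshold `hH` (numeric scalar).
#' @examples
#' find_hopf_threshold(model_params(1.8, 0.2, 0.5, 0.3))  # 0.0577353
#' @export
find_hopf_threshold <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (!holds_H2(p)) {
    stop("H2 violated or no Hopf point: 4(c-d) - a c (b-1)^2 <= 0")
  }
  lo <- (4 * (p$c - p$d) - p$a * p$c * (1 - p$b)^2) / 4
  hi <- p$c - p$d
  lo <- max(lo, 0) + 1e-9
  hi <- hi - 1e-9
  f <- function(h) trace_E2star(h, p)
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    stop("H2 violated or no Hopf point: trace does not change sign in (",
         format(lo), ", ", format(hi), ")")
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

# transformation constants of the rotation normal form at E2*(h):
# P = [N 1; M 0] with M = -a21/omega, N = (a22 - a11)/(2 omega) brings the
# Jacobian to [kappa -omega; omega kappa].
hopf_transform <- function(J) {
  kappa <- (J[1, 1] + J[2, 2]) / 2
  disc <- -4 * J[1, 2] * J[2, 1] - (J[1, 1] - J[2, 2])^2
  if (disc <= 0) stop("Jacobian at E2* has real eigenvalues; no Hopf structure")
  omega <- sqrt(disc) / 2
  list(kappa = kappa, omega = omega,
       M = -J[2, 1] / omega, N = (J[2, 2] - J[1, 1]) / (2 * omega))
}

#' First Lyapunov coefficient at the Hopf point
#'
#' Evaluates the cubic coefficient \eqn{\alpha(h_H)} of the radial normal
#' form \eqn{\dot\tau = \kappa'(h_H)(h - h_H)\tau + \alpha(h_H)\tau^3}
#' governing the Hopf bifurcation at E2*.  The planar system is brought to
#' rotation form via \eqn{(u,v)^T = P (p,q)^T} and the
#' Guckenheimer-Holmes cubic coefficient
#' \deqn{\alpha = \tfrac{1}{16}(f^1_{ppp} + f^1_{pqq} + g^1_{ppq} + g^1_{qqq})
#'  + \tfrac{1}{16\beta_0}\left[f^1_{pq}(f^1_{pp}+f^1_{qq})
#'  - g^1_{pq}(g^1_{pp}+g^1_{qq}) - f^1_{pp} g^1_{pp}
#'  + f^1_{qq} g^1_{qq}\right]}
#' is assembled from the closed-form partials of the transformed
#' nonlinearities, expressed through the Taylor coefficients of
#' [taylor_coeffs()] and the transformation constants `M0`, `N0`.
#'
#' A positive coefficient means the bifurcation is subcritical (an unstable
#' cycle exists where E2* is stable, bounding its basin); a negative one
#' means supercritical (a stable cycle exists below the threshold).
#'
#' @param p a [model_params()] object whose `h` is at the Hopf point
#'   (trace of `J|E2*` below `trace_tol`).
#' @param tc optionally, a `"taylor_coeffs"` object to use instead of the
#'   closed forms -- intended for cross-checking against finite-difference
#'   derivatives of the kinetics.
#' @param trace_tol tolerance on the trace at `p$h` (default `1e-8`).
#' @return Numeric scalar \eqn{\alpha(h_H)}.
#' @export
lyapunov_coefficient <- function(p, tc = NULL, trace_tol = 1e-8) {
  stopifnot(inherits(p, "model_params"))
  e <- interior_equilibria(p)$E2star
  if (is.null(e)) stop("no coexistence equilibrium E2* at these parameters")
  J <- jacobian_at(e$u, e$v, p)
  if (abs(J[1, 1] + J[2, 2]) > trace_tol) {
    stop("not at the Hopf point: trace of J|E2* = ", format(J[1, 1] + J[2, 2]),
         " exceeds tolerance ", format(trace_tol))
  }
  tr <- hopf_transform(J)
  M0 <- tr$M; N0 <- tr$N; beta0 <- tr$omega
  if (is.null(tc)) tc <- taylor_coeffs(p, e$u, e$v)
  gh_alpha(tc, M0, N0, beta0)
}

# Guckenheimer-Holmes evaluation; partials of
#   f1(p,q) = g(Np + q, Mp)/M,  g1(p,q) = f(Np + q, Mp) - (N/M) g(Np + q, Mp)
# at the origin, written out through the Taylor coefficients.
gh_alpha <- function(tc, M0, N0, beta0) {
  with(tc, {
    fppp <- 6 * (N0^3 / M0 * b4 + N0^2 * b5 + N0 * M0 * b6 + M0^2 * b7)
    fpqq <- 2 * (3 * N0 / M0 * b4 + b5)
    gppq <- 2 * (3 * N0^2 * a4 + 2 * N0 * M0 * a5 + M0^2 * a6 -
                   3 * N0^3 / M0 * b4 - 2 * N0^2 * b5 - N0 * M0 * b6)
    gqqq <- 6 * (a4 - N0 / M0 * b4)
    fpp <- 2 * (N0^2 / M0 * b1 + N0 * b2 + M0 * b3)
    fpq <- 2 * N0 / M0 * b1 + b2
    fqq <- 2 / M0 * b1
    gpp <- 2 * (N0^2 * a1 + N0 * M0 * a2 + M0^2 * a3 -
                  N0^3 / M0 * b1 - N0^2 * b2 - N0 * M0 * b3)
    gpq <- 2 * N0 * a1 + M0 * a2 - 2 * N0^2 / M0 * b1 - N0 * b2
    gqq <- 2 * (a1 - N0 / M0 * b1)
    (fppp + fpqq + gppq + gqqq) / 16 +
      (fpq * (fpp + fqq) - gpq * (gpp + gqq) - fpp * gpp + fqq * gqq) /
      (16 * beta0)
  })
}

#' Full Hopf analysis at the coexistence equilibrium
#'
#' Locates the Hopf threshold, evaluates the frequency, transformation
#' constants, transversality derivative and first Lyapunov coefficient, and
#' renders the verdict on the bifurcating periodic solutions.
#'
#' @param p a [model_params()] object (the `h` slot is ignored).
#' @return An object of class `"hopf_result"` with components `hH`,
#'   `omega0` (frequency \eqn{\beta_0}), `M0`, `N0`, `alpha`
#'   (first Lyapunov coefficient), `kappa_prime` (transversality
#'   derivative, negative), `equilibrium` (E2* at the threshold), and
#'   `verdict`: `"supercritical-stable"` when `alpha < 0`,
#'   `"subcritical-unstable"` when `alpha > 0`.  `|alpha| < 1e-10` raises
#'   an error (degenerate Hopf) rather than guessing.
#' @examples
#' hopf_analysis(model_params(1.82, 0.21, 0.5, 0.3))
#' @export
hopf_analysis <- function(p) {
  hH <- find_hopf_threshold(p)
  pH <- model_params(p$a, p$b, p$c, p$d, h = hH, D0 = p$D0, l = p$l)
  e <- interior_equilibria(pH)$E2star
  J <- jacobian_at(e$u, e$v, pH)
  tr <- hopf_transform(J)
  # transversality: kappa'(hH) = (1/2) d Tr/dh < 0, in closed form
  # d Tr/dh = -(b+1)/(c sqrt(disc)) - [2(1-c)(d+h) + c]/c^2 - 1
  disc <- (p$b - 1)^2 - 4 * (p$c - p$d - hH) / (p$a * p$c)
  dtr <- -(p$b + 1) / (p$c * sqrt(disc)) -
    (2 * (1 - p$c) * (p$d + hH) + p$c) / p$c^2 - 1
  kp <- dtr / 2
  alpha <- lyapunov_coefficient(pH)
  if (abs(alpha) < 1e-10) stop("degenerate Hopf: first Lyapunov coefficient vanishes")
  structure(list(hH = hH, omega0 = tr$omega, M0 = tr$M, N0 = tr$N,
                 alpha = alpha, kappa_prime = kp, equilibrium = e,
                 verdict = if (alpha < 0) "supercritical-stable"
                           else "subcritical-unstable"),
            class = "hopf_result")
}

#' @export
print.hopf_result <- function(x, ...) {
  cat("Hopf bifurcation at the coexistence equilibrium\n")
  cat(sprintf("  hH      = %.7g\n", x$hH))
  cat(sprintf("  E2*(hH) = (%.6g, %.6g)\n", x$equilibrium$u, x$equilibrium$v))
  cat(sprintf("  omega0  = %.7g   (period %.4g)\n", x$omega0, 2 * pi / x$omega0))
  cat(sprintf("  kappa'  = %.6g\n", x$kappa_prime))
  cat(sprintf("  alpha   = %.6g   -> %s\n", x$alpha, x$verdict))
  invisible(x)
}
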