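# Mode-wise linear analysis of the reaction-diffusion system at E2*:
# dispersion quantities, Turing bifurcation curves, critical wavenumbers
# and the Turing-Hopf point.

e2star_jacobian <- function(p) {
  e <- interior_equilibria(p)$E2star
  if (is.null(e)) stop("no coexistence equilibrium E2* at these parameters")
  list(e = e, J = jacobian_at(e$u, e$v, p))
}

#' Dispersion relation of one spatial mode
#'
#' For the cosine mode \eqn{\cos(n x / l)} the linearization of the PDE at
#' E2* has characteristic polynomial
#' \eqn{\lambda^2 - T_n \lambda + J_n} with
#' \deqn{T_n = -(D_0 + 1)\frac{n^2}{l^2} + a_{11} + a_{22}, \qquad
#'       J_n = D_0 \frac{n^4}{l^4} - (a_{11} + D_0 a_{22})\frac{n^2}{l^2}
#'             + a_{11}a_{22} - a_{12}a_{21}.}
#' Mode 0 reproduces the kinetic (ODE) trace and determinant.
#'
#' @param p a [model_params()] object with concrete `h`, `D0` and `l`.
#' @param n mode index (non-negative integer, vectorised).
#' @return For scalar `n`, a list with `n`, `Tn`, `Jn` and the complex
#'   `eigenvalues`; for vector `n`, a data frame of `n`, `Tn`, `Jn` and
#'   eigenvalue real parts.
#' @export
mode_spectrum <- function(p, n) {
  stopifnot(inherits(p, "model_params"))
  if (is.na(p$D0) || is.na(p$l)) stop("mode_spectrum requires 'D0' and 'l'")
  J <- e2star_jacobian(p)$J
  k2 <- n^2 / p$l^2
  Tn <- -(p$D0 + 1) * k2 + J[1, 1] + J[2, 2]
  Jn <- p$D0 * k2^2 - (J[1, 1] + p$D0 * J[2, 2]) * k2 +
    J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  disc <- as.complex(Tn^2 - 4 * Jn)
  l1 <- (Tn + sqrt(disc)) / 2
  l2 <- (Tn - sqrt(disc)) / 2
  if (length(n) == 1L) {
    list(n = n, Tn = Tn, Jn = Jn, eigenvalues = c(l1, l2))
  } else {
    data.frame(n = n, Tn = Tn, Jn = Jn,
               re_lambda1 = Re(l1), re_lambda2 = Re(l2))
  }
}

# Critical diffusion ratio of mode n at harvesting rate h: the unique D0
# solving Jn = 0, i.e. D0 = (a11 n^2/l^2 - det J) / (n^4/l^4 - a22 n^2/l^2).
sn_value <- function(p, n, h) {
  vapply(h, function(hi) {
    pi_ <- model_params(p$a, p$b, p$c, p$d, h = hi, D0 = NA, l = p$l)
    J <- e2star_jacobian(pi_)$J
    k2 <- n^2 / p$l^2
    (J[1, 1] * k2 - (J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1])) /
      (k2^2 - J[2, 2] * k2)
  }, numeric(1))
}

#' Turing bifurcation curve of one mode
#'
#' Returns the curve \eqn{D_0 = S_n(h)} along which mode `n` is neutrally
#' stable (\eqn{J_n = 0}), together with its domain
#' \eqn{(h_H, h(n))}: \eqn{S_n} is strictly decreasing in `h`, positive at
#' \eqn{h_H^+} only for modes at or above the critical wavenumber
#' \eqn{k^*}, and `h(n)` is its positive zero (or `c - d` when no zero
#' exists in the admissible range).  Diffusion-driven (Turing) instability
#' of mode `n` occurs for `D0` *below* the curve: the prey must diffuse
#' sufficiently more slowly than the predator.
#'
#' @param p a [model_params()] object; `h` and `D0` slots are ignored,
#'   `l` must be set.
#' @param n mode index, at least the critical wavenumber `k*`.
#' @return A list with `n`, `S` (vectorised function of `h`), `hH`,
#'   `h_max` (upper domain endpoint `h(n)`), and `D0n_star`
#'   (\eqn{D_0(n)^* = \lim_{h \to h_H^+} S_n(h)}).
#' @export
turing_curve <- function(p, n) {
  stopifnot(inherits(p, "model_params"))
  if (is.na(p$l)) stop("turing_curve requires the domain scale 'l'")
  hH <- find_hopf_threshold(p)
  kw <- critical_wavenumbers(p, hH = hH)
  if (n < kw$k_star) {
    stop("mode below critical wavenumber, curve not positive at hH (k* = ",
         kw$k_star, ")")
  }
  Sfun <- function(h) sn_value(p, n, h)
  hup <- p$c - p$d - 1e-9
  D0n <- sn_value(p, n, hH + 1e-9)
  f_up <- Sfun(hup)
  h_max <- if (is.finite(f_up) && f_up < 0) {
    stats::uniroot(Sfun, c(hH + 1e-9, hup), tol = 1e-12)$root
  } else p$c - p$d
  list(n = n, S = Sfun, hH = hH, h_max = h_max, D0n_star = D0n)
}

#' Critical wavenumbers at the Hopf threshold
#'
#' Computes, at \eqn{h = h_H}:
#' \itemize{
#' \item `k_star`: the smallest integer `n` with
#'   \eqn{n^2/l^2 > (1-c)(c-d-h)(d+h)/c^2}, the smallest mode whose
#'   critical diffusion ratio \eqn{D_0(n)^*} is positive (this reproduces
#'   the floor-plus-one expression; when the bound is an exact integer the
#'   strict inequality gives `k* = bound + 1`);
#' \item `k_m`: \eqn{\lfloor x^* \rfloor} where \eqn{x^*} is the positive
#'   root of the quadratic \eqn{\Phi(x)} governing the sign of
#'   \eqn{dD_0(n)^*/d(n^2)};
#' \item `k0_star`: the mode maximising \eqn{D_0(n)^*}, selected among
#'   `k_star`, `k_m`, `k_m + 1` (and verified by enumeration up to
#'   `n_max`).
#' }
#'
#' @param p a [model_params()] object (the `h`, `D0` slots are ignored).
#' @param hH optionally the precomputed Hopf threshold.
#' @param n_max upper bound of the enumeration guard (default
#'   `max(50, 4 k0*)`); \eqn{D_0(n)^*} decays like \eqn{1/n^2} so the
#'   maximum cannot occur beyond it, which is asserted on the tail.
#' @return A list with `k_star`, `k_m`, `k0_star`, `x_star`, and the
#'   vector `D0n_star` of critical ratios for `n = k_star, ..., n_max`.
#' @export
critical_wavenumbers <- function(p, hH = NULL, n_max = 50) {
  stopifnot(inherits(p, "model_params"))
  if (is.na(p$l)) stop("critical_wavenumbers requires the domain scale 'l'")
  if (is.null(hH)) hH <- find_hopf_threshold(p)
  chd <- p$c - p$d - hH; dph <- p$d + hH
  bound <- p$l^2 * (1 - p$c) * chd * dph / p$c^2    # n^2 must exceed this
  k_star <- floor(sqrt(bound)) + 1
  if (k_star^2 <= bound) k_star <- k_star + 1       # exact-integer boundary
  # Phi(x) = -x^2/l^4 + 2 x (1-c) chd dph / (c^2 l^2) + (1-c) chd^2 dph^2 / c^3
  A <- -1 / p$l^4
  B <- 2 * (1 - p$c) * chd * dph / (p$c^2 * p$l^2)
  C <- (1 - p$c) * chd^2 * dph^2 / p$c^3
  x_star <- (-B - sqrt(B^2 - 4 * A * C)) / (2 * A)  # positive root (A < 0)
  k_m <- floor(sqrt(x_star))
  pH <- model_params(p$a, p$b, p$c, p$d, h = hH, l = p$l)
  n_try <- max(n_max, 4 * max(k_star, k_m + 1))
  ns <- k_star:n_try
  vals <- vapply(ns, function(n) sn_value(pH, n, hH + 1e-12), numeric(1))
  # guard: the tail must be decreasing so the max is inside the range
  ltail <- length(vals)
  stopifnot(vals[ltail] < vals[ltail - 1])
  k0_star <- ns[which.max(vals)]
  cand <- unique(pmax(k_star, c(k_star, k_m, k_m + 1)))
  if (!(k0_star %in% cand)) {
    warning("enumerated maximiser ", k0_star,
            " outside the {k*, km, km+1} candidate set")
  }
  list(k_star = k_star, k_m = k_m, k0_star = k0_star, x_star = x_star,
       D0n_star = stats::setNames(vals, ns))
}

#' The Turing-Hopf codimension-two point
#'
#' Composes [find_hopf_threshold()] with [critical_wavenumbers()]: the
#' Turing-Hopf bifurcation occurs where the Hopf line \eqn{h = h_H} meets
#' the uppermost Turing curve, i.e. at
#' \eqn{(h, D_0) = (h_H, D_0(k_0^*)^*)}.  At that point the mode-0
#' linearization has purely imaginary eigenvalues \eqn{\pm i\omega_0}, the
#' mode-\eqn{k_0^*} linearization has a zero and a negative eigenvalue, and
#' every other mode is strictly stable.
#'
#' @param p a [model_params()] object carrying `a`, `b`, `c`, `d` and `l`
#'   (`h`, `D0` are ignored).
#' @param n_max enumeration bound passed to [critical_wavenumbers()].
#' @return An object of class `"turing_hopf_point"`: a list with `hH`,
#'   `D0_star`, `k_star`, `k_m`, `k0_star`, `omega0`, `equilibrium`
#'   (E2* at `hH`), `D0n_star` (per-mode critical ratios) and `params`
#'   (the input parameters completed with `h = hH`, `D0 = D0_star`).
#' @examples
#' turing_hopf_point(model_params(1.8, 0.2, 0.5, 0.3, l = 2))
#' @export
turing_hopf_point <- function(p, n_max = 50) {
  stopifnot(inherits(p, "model_params"))
  hH <- find_hopf_threshold(p)
  kw <- critical_wavenumbers(p, hH = hH, n_max = n_max)
  D0s <- unname(kw$D0n_star[as.character(kw$k0_star)])
  pstar <- model_params(p$a, p$b, p$c, p$d, h = hH, D0 = D0s, l = p$l)
  ej <- e2star_jacobian(pstar)
  structure(list(hH = hH, D0_star = D0s, k_star = kw$k_star, k_m = kw$k_m,
                 k0_star = kw$k0_star, omega0 = sqrt(det(ej$J)),
                 equilibrium = ej$e, D0n_star = kw$D0n_star,
                 params = pstar),
            class = "turing_hopf_point")
}

#' @export
print.turing_hopf_point <- function(x, ...) {
  cat("Turing-Hopf codimension-two point\n")
  cat(sprintf("  (hH, D0*) = (%.6g, %.6g)\n", x$hH, x$D0_star))
  cat(sprintf("  k* = %d, km = %d, k0* = %d, omega0 = %.6g\n",
              x$k_star, x$k_m, x$k0_star, x$omega0))
  cat(sprintf("  E2* = (%.6g, %.6g)\n", x$equilibrium$u, x$equilibrium$v))
  invisible(x)
}
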