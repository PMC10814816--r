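#' Dimensionless model parameters
#'
#' Bundle the dimensionless parameters of the diffusive ratio-dependent
#' predator-prey model with Allee effect and proportional predator
#' harvesting,
#' \deqn{u_t - D_0 \Delta u = a u (1-u)(u-b) - \frac{uv}{u+v}, \qquad
#'       v_t - \Delta v = \frac{c u v}{u+v} - (d+h) v,}
#' posed on the interval \eqn{(0, l\pi)} with zero-flux (Neumann) boundary
#' conditions.
#'
#' @param a scaled prey growth coefficient (> 0).
#' @param b scaled Allee threshold, the prey density below which per-capita
#'   growth is negative; must satisfy \eqn{0 < b < 1}.
#' @param c conversion rate of predation into predator growth (> 0).
#' @param d scaled predator death rate (> 0).
#' @param h predator harvesting rate (>= 0), the primary bifurcation
#'   parameter.  May be `NA` while it is still to be determined (e.g. before
#'   locating the Hopf threshold).
#' @param D0 ratio of prey to predator diffusion coefficients,
#'   \eqn{D_0 = d_1/d_2} (> 0); `NA` for purely kinetic (ODE) analyses.
#' @param l domain scale: the spatial domain is \eqn{(0, l\pi)}; `NA` for
#'   purely kinetic analyses.
#'
#' @return An object of class `"model_params"`: a named list with components
#'   `a`, `b`, `c`, `d`, `h`, `D0`, `l`.
#'
#' @details Existence of interior equilibria and of the Hopf threshold
#'   depend on the predicate pairs computed by [holds_H1()] and
#'   [holds_H2()]; they are deliberately *not* enforced at construction
#'   time, since boundary and degenerate parameter sets are legitimate
#'   inputs (for instance when scanning across the existence boundary).
#'
#' @seealso [holds_H1()], [holds_H2()], [nondimensionalize()]
#' @examples
#' p <- model_params(a = 1.8, b = 0.2, c = 0.5, d = 0.3, h = 0.05774,
#'                   D0 = 0.17154, l = 2)
#' holds_H1(p)
#' @export
model_params <- function(a, b, c, d, h = NA_real_, D0 = NA_real_,
                         l = NA_real_) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d))
  if (a <= 0) stop("'a' must be positive")
  if (b <= 0 || b >= 1) stop("'b' must lie strictly between 0 and 1")
  if (c <= 0) stop("'c' must be positive")
  if (d <= 0) stop("'d' must be positive")
  if (!is.na(h) && h < 0) stop("'h' must be non-negative")
  if (!is.na(D0) && D0 <= 0) stop("'D0' must be positive")
  if (!is.na(l) && l <= 0) stop("'l' must be positive")
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), h = as.numeric(h), D0 = as.numeric(D0),
                 l = as.numeric(l)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Dimensionless predator-prey model parameters\n")
  cat(sprintf("  a = %g, b = %g, c = %g, d = %g\n", x$a, x$b, x$c, x$d))
  cat(sprintf("  h = %s, D0 = %s, l = %s\n",
              format(x$h), format(x$D0), format(x$l)))
  if (!is.na(x$h)) {
    cat(sprintf("  H1 (two interior equilibria): %s\n", holds_H1(x)))
    cat(sprintf("  H2 (Hopf threshold exists):   %s\n", holds_H2(x)))
  }
  invisible(x)
}

#' Existence predicates for interior equilibria and the Hopf threshold
#'
#' `holds_H1()` tests the condition under which the kinetics admit two
#' interior equilibria: \eqn{d + h < c \le 1} and
#' \eqn{a c (b-1)^2 > 4 (c - d - h)}.  `holds_H2()` tests
#' \eqn{4(c-d) - a c (b-1)^2 > 0}, under which (together with H1) the trace
#' at the larger interior equilibrium has a unique positive zero in `h`
#' (the Hopf threshold).
#'
#' @param p a [model_params()] object; `holds_H1()` requires a non-`NA` `h`.
#' @return Logical scalar.
#' @export
holds_H1 <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (is.na(p$h)) stop("H1 requires a concrete harvesting rate 'h'")
  (p$d + p$h < p$c) && (p$c <= 1) &&
    (p$a * p$c * (p$b - 1)^2 > 4 * (p$c - p$d - p$h))
}

#' @rdname holds_H1
#' @export
holds_H2 <- function(p) {
  stopifnot(inherits(p, "model_params"))
  4 * (p$c - p$d) - p$a * p$c * (p$b - 1)^2 > 0
}

#' Dimensional model parameters
#'
#' Container for the dimensional formulation of the model, in which the prey
#' grows with maximum per-capita rate `gamma` towards carrying capacity `K`
#' above an Allee threshold `Q0`, and predators capture prey at rate `G`,
#' convert it with efficiency `mu`, die at rate `L` and are harvested at
#' rate `H`; `d1`, `d2` are the diffusion coefficients.
#'
#' @param K carrying capacity (biomass, > 0).
#' @param gamma maximum per-capita prey growth rate (1/time, > 0).
#' @param G capturing rate (1/time, > 0).
#' @param mu conversion rate (dimensionless, > 0).
#' @param L predator death rate (1/time, > 0).
#' @param H harvesting rate (1/time, >= 0).
#' @param Q0 Allee threshold (biomass, >= 0); must satisfy `Q0 < K`.
#' @param d1,d2 diffusion coefficients (area/time, > 0).
#' @return An object of class `"dimensional_params"`.
#' @seealso [nondimensionalize()]
#' @export
dimensional_params <- function(K, gamma, G, mu, L, H = 0, Q0 = 0,
                               d1 = 1, d2 = 1) {
  vals <- c(K = K, gamma = gamma, G = G, mu = mu, L = L, d1 = d1, d2 = d2)
  if (any(vals <= 0)) {
    stop("all of K, gamma, G, mu, L, d1, d2 must be strictly positive")
  }
  if (H < 0 || Q0 < 0) stop("'H' and 'Q0' must be non-negative")
  if (Q0 >= K) stop("the Allee threshold 'Q0' must be below the carrying capacity 'K'")
  structure(list(K = K, gamma = gamma, G = G, mu = mu, L = L, H = H,
                 Q0 = Q0, d1 = d1, d2 = d2),
            class = "dimensional_params")
}

#' Convert dimensional parameters to the dimensionless set
#'
#' Applies the substitution
#' \deqn{a = \frac{4 \gamma K^2}{G (K - Q_0)^2}, \quad b = Q_0/K, \quad
#'       c = \mu, \quad d = L/G, \quad h = H/G, \quad D_0 = d_1/d_2,}
#' which rescales densities by `K` and time by `1/G`.
#'
#' @param q a [dimensional_params()] object.
#' @param G capturing rate used as the time scale; defaults to `q$G`.
#' @param l optional domain scale of the dimensionless problem.
#' @return A [model_params()] object.  `b = 0` is shifted to the smallest
#'   representable positive value only if exactly zero is supplied and a
#'   strict Allee threshold is required downstream; here `Q0 = 0` yields
#'   `b = 0`, returned as an ordinary list (not `model_params`) because the
#'   strong-Allee analysis requires `0 < b < 1`.
#' @export
nondimensionalize <- function(q, G = q$G, l = NA_real_) {
  stopifnot(inherits(q, "dimensional_params"))
  if (G <= 0) stop("'G' must be positive")
  a <- 4 * q$gamma * q$K^2 / (G * (q$K - q$Q0)^2)
  b <- q$Q0 / q$K
  out <- list(a = a, b = b, c = q$mu, d = q$L / G, h = q$H / G,
              D0 = q$d1 / q$d2, l = l)
  if (b > 0 && b < 1) {
    do.call(model_params, out)
  } else {
    # weak-Allee / degenerate boundary: return the raw substitution values
    out
  }
}
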