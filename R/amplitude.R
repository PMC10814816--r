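# The truncated planar amplitude system near the Turing-Hopf singularity:
#   rho'   = alpha1(mu) rho   + kappa11 rho^3      + kappa12 rho sigma^2
#   sigma' = alpha2(mu) sigma + kappa21 rho^2 sigma + kappa22 sigma^3
# with alpha_i(mu) linear in the unfolding (mu1, mu2), kappa11/kappa22 in
# {-1, +1}.  rho >= 0 is the (polar) Hopf amplitude; sigma is the signed
# Turing amplitude.

#' Construct a planar amplitude system
#'
#' Either supply the coefficient set explicitly, or pass an
#' `"nf_coefficients"` object to use the normal form computed from the
#' model.
#'
#' @param alpha1_coeffs length-2 numeric: slopes of \eqn{\alpha_1} in
#'   \eqn{(\mu_1, \mu_2)}.
#' @param alpha2_coeffs length-2 numeric: slopes of \eqn{\alpha_2}.
#' @param kappa11,kappa22 cubic self-coupling signs, each -1 or +1.
#' @param kappa12,kappa21 cubic cross couplings (real).
#' @param nf optionally an `"nf_coefficients"` object; when given the
#'   other arguments are ignored.
#' @return An object of class `"amplitude_system"`.
#' @seealso [reference_amplitude_system()] for the published worked-example
#'   coefficient set kept as comparison metadata.
#' @export
amplitude_system <- function(alpha1_coeffs, alpha2_coeffs,
                             kappa11, kappa12, kappa21, kappa22, nf = NULL) {
  if (!is.null(nf)) {
    stopifnot(inherits(nf, "nf_coefficients"))
    return(amplitude_system(c(nf$alpha1_mu1, nf$alpha1_mu2),
                            c(nf$alpha2_mu1, nf$alpha2_mu2),
                            nf$kappa11, nf$kappa12, nf$kappa21, nf$kappa22))
  }
  stopifnot(length(alpha1_coeffs) == 2, length(alpha2_coeffs) == 2,
            kappa11 %in% c(-1, 1), kappa22 %in% c(-1, 1))
  structure(list(alpha1_coeffs = as.numeric(alpha1_coeffs),
                 alpha2_coeffs = as.numeric(alpha2_coeffs),
                 kappa11 = kappa11, kappa12 = as.numeric(kappa12),
                 kappa21 = as.numeric(kappa21), kappa22 = kappa22),
            class = "amplitude_system")
}

#' Published worked-example amplitude system
#'
#' The amplitude system printed for the worked example at
#' \eqn{(h_H, D_0^*) = (0.05774, 0.17154)} (`a = 1.8`, `b = 0.2`,
#' `c = 0.5`, `d = 0.3`, `l = 2`),
#' \deqn{\dot\rho = \rho(-15.8798\mu_1 - \rho^2 - 0.2403\varsigma^2), \quad
#'       \dot\varsigma = \varsigma(-38.1544\mu_1 - 0.3003\mu_2
#'         + 11.3740\rho^2 - \varsigma^2),}
#' kept for comparison with the package's own computation.  The
#' \eqn{\varsigma^3} sign is taken as \eqn{-1}: only that reading is
#' consistent with the published equilibrium coordinates
#' \eqn{\tilde A_2^\pm = (0, \pm\sqrt{-38.1521\mu_1 - 0.3002\mu_2})},
#' \eqn{\tilde A_3^\pm} and the curves \eqn{T_1, T_2} (the source's
#' displayed "+" there is a typographical slip in its own terms).  Note
#' the package's oracle-validated normal form disagrees with this cubic
#' structure (it finds both the Hopf and Turing branches subcritical); see
#' the methods vignette.
#'
#' @return An `"amplitude_system"` object.
#' @export
reference_amplitude_system <- function() {
  amplitude_system(alpha1_coeffs = c(-15.8798, 0),
                   alpha2_coeffs = c(-38.1544, -0.3003),
                   kappa11 = -1, kappa12 = -0.2403,
                   kappa21 = 11.3740, kappa22 = -1)
}

#' @export
print.amplitude_system <- function(x, ...) {
  cat("Planar amplitude system\n")
  cat(sprintf("  rho'   = (%g mu1 + %g mu2) rho %+g rho^3 %+g rho sigma^2\n",
              x$alpha1_coeffs[1], x$alpha1_coeffs[2], x$kappa11, x$kappa12))
  cat(sprintf("  sigma' = (%g mu1 + %g mu2) sigma %+g rho^2 sigma %+g sigma^3\n",
              x$alpha2_coeffs[1], x$alpha2_coeffs[2], x$kappa21, x$kappa22))
  invisible(x)
}

alpha_at <- function(sys, mu) {
  c(alpha1 = sum(sys$alpha1_coeffs * mu), alpha2 = sum(sys$alpha2_coeffs * mu))
}

amp_jacobian <- function(sys, rho, sigma, al) {
  matrix(c(al[1] + 3 * sys$kappa11 * rho^2 + sys$kappa12 * sigma^2,
           2 * sys$kappa12 * rho * sigma,
           2 * sys$kappa21 * rho * sigma,
           al[2] + sys$kappa21 * rho^2 + 3 * sys$kappa22 * sigma^2),
         2, 2, byrow = TRUE)
}

amp_stability <- function(sys, rho, sigma, al, tol = 1e-12) {
  ev <- eigen(amp_jacobian(sys, rho, sigma, al), only.values = TRUE)$values
  re <- Re(ev)
  if (max(re) < -tol) "stable"
  else if (max(re) > tol) "unstable"
  else "non-hyperbolic"
}

#' Equilibria of the amplitude system
#'
#' Computes, at an unfolding point \eqn{\mu = (\mu_1, \mu_2)}:
#' the trivial state `A0` (always present); the pure Hopf state
#' `A1` \eqn{= (\sqrt{-\alpha_1/\kappa_{11}}, 0)} when the radicand is
#' positive; the pure Turing pair `A2+`, `A2-`
#' \eqn{= (0, \pm\sqrt{-\alpha_2/\kappa_{22}})}; and the mixed-mode pair
#' `A3+`, `A3-` obtained by solving the linear system in
#' \eqn{(\rho^2, \varsigma^2)}, retained only when both squares are
#' positive.  Equilibria with negative \eqn{\rho} are discarded
#' (\eqn{\rho} is a polar amplitude).  Stability is read from the planar
#' Jacobian's eigenvalues with threshold `1e-12`; marginal cases are
#' labelled `"non-hyperbolic"`.
#'
#' @param sys an [amplitude_system()].
#' @param mu numeric length-2, the unfolding point \eqn{(\mu_1, \mu_2)}.
#' @return A data frame with columns `label`, `rho`, `sigma`, `exists`,
#'   `stability`, plus attribute `"degenerate"` when the A3 linear system
#'   is singular (\eqn{\kappa_{11}\kappa_{22} - \kappa_{12}\kappa_{21} = 0}
#'   within `1e-12`).
#' @export
amplitude_equilibria <- function(sys, mu) {
  stopifnot(inherits(sys, "amplitude_system"), length(mu) == 2)
  al <- alpha_at(sys, mu)
  rows <- list(data.frame(label = "A0", rho = 0, sigma = 0, exists = TRUE,
                          stability = amp_stability(sys, 0, 0, al)))
  r1 <- -al[1] / sys$kappa11
  if (r1 > 0) {
    rho <- sqrt(r1)
    rows <- c(rows, list(data.frame(label = "A1", rho = rho, sigma = 0,
                                    exists = TRUE,
                                    stability = amp_stability(sys, rho, 0, al))))
  }
  s2 <- -al[2] / sys$kappa22
  if (s2 > 0) {
    sg <- sqrt(s2)
    rows <- c(rows, lapply(c(1, -1), function(s) {
      data.frame(label = if (s > 0) "A2+" else "A2-", rho = 0,
                 sigma = s * sg, exists = TRUE,
                 stability = amp_stability(sys, 0, s * sg, al))
    }))
  }
  det3 <- sys$kappa11 * sys$kappa22 - sys$kappa12 * sys$kappa21
  degenerate <- abs(det3) < 1e-12
  if (!degenerate) {
    rr <- (-al[1] * sys$kappa22 + sys$kappa12 * al[2]) / det3
    ss <- (-sys$kappa11 * al[2] + al[1] * sys$kappa21) / det3
    if (rr > 0 && ss > 0) {
      rho <- sqrt(rr); sg <- sqrt(ss)
      rows <- c(rows, lapply(c(1, -1), function(s) {
        data.frame(label = if (s > 0) "A3+" else "A3-", rho = rho,
                   sigma = s * sg, exists = TRUE,
                   stability = amp_stability(sys, rho, s * sg, al))
      }))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "degenerate") <- degenerate
  attr(out, "alpha") <- al
  out
}

#' Bifurcation curves of the amplitude system
#'
#' Returns the four curves partitioning the unfolding plane, each as a
#' linear form \eqn{c_1 \mu_1 + c_2 \mu_2 = 0} with a half-plane
#' restriction:
#' `H0` (\eqn{\alpha_1 = 0}, birth of A1), `T` (\eqn{\alpha_2 = 0}, birth
#' of A2), and `T1`, `T2`, the existence boundaries of the mixed mode A3
#' (\eqn{\varsigma^2 = 0} resp. \eqn{\rho^2 = 0} of the solved linear
#' system, each restricted to where the other square is positive).
#'
#' @param sys an [amplitude_system()].
#' @return A list of curves; each has `coef` (length 2), `slope`
#'   (\eqn{d\mu_2/d\mu_1}, `Inf` for vertical) and `restriction` (a
#'   function of \eqn{\mu} returning `TRUE` on the valid ray).
#' @examples
#' bifurcation_curves(reference_amplitude_system())  # T slope -127.057
#' @export
bifurcation_curves <- function(sys) {
  det3 <- sys$kappa11 * sys$kappa22 - sys$kappa12 * sys$kappa21
  rr_form <- (-sys$alpha1_coeffs * sys$kappa22 + sys$kappa12 * sys$alpha2_coeffs) / det3
  ss_form <- (-sys$kappa11 * sys$alpha2_coeffs + sys$alpha1_coeffs * sys$kappa21) / det3
  slope_of <- function(cf) if (abs(cf[2]) < 1e-300) Inf else -cf[1] / cf[2]
  list(
    H0 = list(coef = sys$alpha1_coeffs, slope = slope_of(sys$alpha1_coeffs),
              restriction = function(mu) TRUE),
    T = list(coef = sys$alpha2_coeffs, slope = slope_of(sys$alpha2_coeffs),
             restriction = function(mu) TRUE),
    T1 = list(coef = ss_form, slope = slope_of(ss_form),
              restriction = function(mu) sum(rr_form * mu) > 0),
    T2 = list(coef = rr_form, slope = slope_of(rr_form),
              restriction = function(mu) sum(ss_form * mu) > 0),
    rho2_form = rr_form, sigma2_form = ss_form)
}

#' Classify an unfolding point into the regions R1-R6
#'
#' Partitions a punctured neighbourhood of the origin of the
#' \eqn{(\mu_1,\mu_2)} plane into six sectors bounded by the rays of the
#' curves `H0`, `T`, `T1`, `T2` from [bifurcation_curves()].  Sectors are
#' labelled `R1` to `R6` counterclockwise, anchored so that `R1` is the
#' sector containing the positive \eqn{\mu_1} direction (where, for the
#' published coefficient structure, only the trivial state exists and is
#' stable).  Points within `1e-14` (relative) of a curve receive the
#' curve's name instead.
#'
#' @param sys an [amplitude_system()].
#' @param mu numeric length-2, nonzero.
#' @return An object of class `"region_label"`: list with `region` (one of
#'   `"R1"`..`"R6"` or a curve name), `equilibria` (the inventory data
#'   frame from [amplitude_equilibria()]), and `regime` (the PDE regime
#'   predicted by the stable equilibria, via [pde_interpretation()]).
#' @export
classify_region <- function(sys, mu) {
  stopifnot(length(mu) == 2)
  if (all(mu == 0)) stop("the origin mu = (0, 0) is the singularity itself")
  crv <- bifurcation_curves(sys)
  scale <- sqrt(sum(mu^2))
  # boundary detection on the linear forms
  for (nm in c("H0", "T", "T1", "T2")) {
    cf <- crv[[nm]]$coef
    val <- sum(cf * mu)
    if (abs(val) <= 1e-14 * scale * max(abs(cf)) && crv[[nm]]$restriction(mu)) {
      eq <- amplitude_equilibria(sys, mu)
      return(structure(list(region = nm, equilibria = eq,
                            regime = regime_from_inventory(eq)),
                       class = "region_label"))
    }
  }
  # collect rays: both directions for H0 and T, restricted for T1, T2
  rays <- list()
  dir_angle <- function(v) atan2(v[2], v[1]) %% (2 * pi)
  line_dirs <- function(cf) {
    d <- c(-cf[2], cf[1]) / sqrt(sum(cf^2))
    list(d, -d)
  }
  for (nm in c("H0", "T", "T1", "T2")) {
    cf <- crv[[nm]]$coef
    if (all(abs(cf) < 1e-300)) next
    for (d in line_dirs(cf)) {
      if (crv[[nm]]$restriction(d)) rays <- c(rays, list(dir_angle(d)))
    }
  }
  angs <- sort(unique(round(unlist(rays), 12)))
  if (length(angs) < 2) stop("degenerate curve arrangement; cannot form sectors")
  th <- dir_angle(mu)
  sector_of <- function(theta) {
    # index of the sector [angs[i], angs[i+1]) containing theta (cyclic)
    i <- findInterval(theta, angs)
    if (i == 0) i <- length(angs)
    i
  }
  anchor <- sector_of(0)          # sector containing the +mu1 axis -> R1
  idx <- sector_of(th)
  lab <- ((idx - anchor) %% length(angs)) + 1
  eq <- amplitude_equilibria(sys, mu)
  structure(list(region = paste0("R", lab), equilibria = eq,
                 regime = regime_from_inventory(eq)),
            class = "region_label")
}

#' @export
print.region_label <- function(x, ...) {
  cat(sprintf("Region %s: predicted PDE regime: %s\n", x$region, x$regime))
  print(x$equilibria)
  invisible(x)
}

regime_from_inventory <- function(eq) {
  st <- eq$label[eq$stability == "stable"]
  if (length(st) == 0) return("no stable amplitude equilibrium (dynamics leave the local neighbourhood)")
  pde_interpretation(st[1])
}

#' PDE regime predicted by an amplitude equilibrium
#'
#' Maps the amplitude-system equilibria to the spatiotemporal behaviour of
#' the reaction-diffusion system they represent: `A0` is the spatially
#' constant steady state, `A1` the spatially homogeneous periodic
#' solution (pure Hopf), `A2+`/`A2-` the nonconstant (patterned) steady
#' states (pure Turing), and `A3+`/`A3-` the spatially inhomogeneous
#' periodic solutions (mixed mode).
#'
#' @param label one of `"A0"`, `"A1"`, `"A2+"`, `"A2-"`, `"A3+"`, `"A3-"`
#'   (or an `amplitude_equilibria` row).
#' @return A regime string.
#' @export
pde_interpretation <- function(label) {
  if (is.data.frame(label)) label <- label$label
  base <- sub("[+-]$", "", label)
  unname(c(A0 = "constant steady state",
           A1 = "spatially homogeneous periodic solution",
           A2 = "nonconstant steady state",
           A3 = "spatially inhomogeneous periodic solution")[base])
}

#' Integrate the planar amplitude system
#'
#' Direct numerical integration of the truncated amplitude equations,
#' used as an oracle for the equilibrium/stability classification.  The
#' half-plane \eqn{\rho \ge 0} is invariant and enforced.
#'
#' @param sys an [amplitude_system()].
#' @param mu unfolding point.
#' @param init numeric `c(rho0, sigma0)` with `rho0 >= 0`.
#' @param t_end integration horizon.
#' @param n_out number of output times.
#' @return A matrix with columns `time`, `rho`, `sigma`.
#' @export
integrate_amplitude <- function(sys, mu, init, t_end, n_out = 400) {
  stopifnot(init[1] >= 0)
  al <- alpha_at(sys, mu)
  rhs <- function(t, y, parms) {
    rho <- max(y[1], 0); sg <- y[2]
    list(c(al[1] * rho + sys$kappa11 * rho^3 + sys$kappa12 * rho * sg^2,
           al[2] * sg + sys$kappa21 * rho^2 * sg + sys$kappa22 * sg^3))
  }
  out <- deSolve::ode(c(rho = init[1], sigma = init[2]),
                      seq(0, t_end, length.out = n_out), rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  colnames(out)[1] <- "time"
  out
}
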