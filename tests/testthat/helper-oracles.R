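# Shared fixtures and independent numerical oracles.

base_params <- function(h = NA_real_, D0 = NA_real_, l = 2) {
  model_params(1.8, 0.2, 0.5, 0.3, h = h, D0 = D0, l = l)
}
alt_params <- function(h = NA_real_) {
  model_params(1.82, 0.21, 0.5, 0.3, h = h)
}

# memoized heavy objects
.cache <- new.env(parent = emptyenv())
get_thb <- function() {
  if (is.null(.cache$thb)) .cache$thb <- turing_hopf_point(base_params())
  .cache$thb
}
get_nf <- function() {
  if (is.null(.cache$nf)) .cache$nf <- nf_coefficients(expand_linearization(get_thb()))
  .cache$nf
}

# central finite-difference Jacobian of the kinetics
fd_jacobian <- function(p, u, v, h = 1e-6) {
  f <- function(uu, vv) kinetics(uu, vv, p)
  cbind((f(u + h, v) - f(u - h, v)) / (2 * h),
        (f(u, v + h) - f(u, v - h)) / (2 * h))
}

# finite-difference Taylor coefficients (2nd/3rd order partials) of the
# kinetics at (u, v); an independent oracle for taylor_coeffs()
fd_taylor_coeffs <- function(p, u, v, h2 = 1e-4, h3 = 2e-3) {
  f <- function(du, dv) kinetics(u + du, v + dv, p)
  d2 <- function(i) {   # i = (iu, iv), iu + iv = 2
    if (i[1] == 2) (f(h2, 0) - 2 * f(0, 0) + f(-h2, 0)) / h2^2
    else if (i[2] == 2) (f(0, h2) - 2 * f(0, 0) + f(0, -h2)) / h2^2
    else (f(h2, h2) - f(h2, -h2) - f(-h2, h2) + f(-h2, -h2)) / (4 * h2^2)
  }
  d3_raw <- function(i, h) {   # third partials by nested central differences
    if (i[1] == 3) (f(2*h, 0) - 2*f(h, 0) + 2*f(-h, 0) - f(-2*h, 0)) / (2 * h^3)
    else if (i[2] == 3) (f(0, 2*h) - 2*f(0, h) + 2*f(0, -h) - f(0, -2*h)) / (2 * h^3)
    else if (i[1] == 2) ((f(h, h) - 2*f(0, h) + f(-h, h)) -
                           (f(h, -h) - 2*f(0, -h) + f(-h, -h))) / (2 * h^3)
    else ((f(h, h) - 2*f(h, 0) + f(h, -h)) -
            (f(-h, h) - 2*f(-h, 0) + f(-h, -h))) / (2 * h^3)
  }
  # Richardson extrapolation kills the O(h^2) truncation term
  d3 <- function(i) (4 * d3_raw(i, h3 / 2) - d3_raw(i, h3)) / 3
  q20 <- d2(c(2, 0)); q11 <- d2(c(1, 1)); q02 <- d2(c(0, 2))
  c30 <- d3(c(3, 0)); c21 <- d3(c(2, 1)); c12 <- d3(c(1, 2)); c03 <- d3(c(0, 3))
  structure(list(a1 = q20[1] / 2, a2 = q11[1], a3 = q02[1] / 2,
                 a4 = c30[1] / 6, a5 = c21[1] / 2, a6 = c12[1] / 2, a7 = c03[1] / 6,
                 b1 = q20[2] / 2, b2 = q11[2], b3 = q02[2] / 2,
                 b4 = c30[2] / 6, b5 = c21[2] / 2, b6 = c12[2] / 2, b7 = c03[2] / 6),
            class = "taylor_coeffs")
}

# does a perturbation of E2* by (du, 0) return to E2*?  (basin probe for the
# subcritical Hopf cycle radius)
returns_to_E2star <- function(p, du, t_end = 12000) {
  e <- interior_equilibria(p)$E2star
  out <- try(ode_simulate(p, e$u + du, e$v,
                          times = seq(0, t_end, length.out = 200)),
             silent = TRUE)
  if (inherits(out, "try-error")) return(FALSE)
  devs <- abs(out[, "u"] - e$u) + abs(out[, "v"] - e$v)
  n <- length(devs)
  # converging: contracted well below the initial offset without ever
  # making the large excursion that precedes collapse
  is.finite(devs[n]) && devs[n] < du / 3 && max(devs) < 0.2
}

basin_radius <- function(p, lo = 1e-4, hi = 0.2, iters = 14) {
  for (i in seq_len(iters)) {
    mid <- sqrt(lo * hi)
    if (returns_to_E2star(p, mid)) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# critical-mode projections of a simulation field, for the amplitude
# fitting oracles: z1 (complex, Hopf) and z3 (real, Turing mode n*)
mode_projections <- function(field, eig, thb) {
  lp <- thb$params$l * pi
  dx <- field$x[2] - field$x[1]
  g0 <- rep(1 / sqrt(lp), length(field$x))
  gn <- sqrt(2 / lp) * cos(thb$k0_star * field$x / thb$params$l)
  e <- thb$equilibrium
  du <- sweep(field$u, 2, e$u); dv <- sweep(field$v, 2, e$v)
  ip <- function(M, g) as.vector(M %*% (g * dx))
  list(t = field$times,
       z1 = eig$eta0[1] * ip(du, g0) + eig$eta0[2] * ip(dv, g0),
       z3 = Re(eig$etan[1]) * ip(du, gn) + Re(eig$etan[2]) * ip(dv, gn))
}

# pure-mode initial data at the Turing-Hopf point (z1 complex, z3 real)
thb_mode_ic <- function(thb, eig, nx, z1 = 0, z3 = 0) {
  lp <- thb$params$l * pi
  x <- (seq_len(nx) - 0.5) * lp / nx
  g0 <- 1 / sqrt(lp)
  gn <- sqrt(2 / lp) * cos(thb$k0_star * x / thb$params$l)
  e <- thb$equilibrium
  list(u0 = e$u + 2 * Re(z1 * eig$xi0[1]) * g0 + z3 * Re(eig$xin[1]) * gn,
       v0 = e$v + 2 * Re(z1 * eig$xi0[2]) * g0 + z3 * Re(eig$xin[2]) * gn)
}
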