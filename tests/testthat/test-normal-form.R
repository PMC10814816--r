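test_that("expanded linearization matches the Jacobian and its h-derivative", {
  thb <- get_thb()
  lin <- expand_linearization(thb)
  e <- thb$equilibrium
  expect_lt(max(abs(lin$L0 - jacobian_at(e$u, e$v, thb$params))), 1e-8)
  expect_identical(lin$L1_01, matrix(0, 2, 2))
  expect_identical(lin$D1_10, matrix(0, 2, 2))
  expect_equal(lin$D1_01, matrix(c(1, 0, 0, 0), 2, 2))
  # closed-form L1^(1,0) vs central finite differences of the Jacobian in h
  dh <- 1e-7   # the entries inherit the trace's large h-curvature
  jh <- function(h) {
    p <- model_params(1.8, 0.2, 0.5, 0.3, h = h)
    e <- interior_equilibria(p)$E2star
    jacobian_at(e$u, e$v, p)
  }
  L1fd <- (jh(thb$hH + dh) - jh(thb$hH - dh)) / (2 * dh)
  expect_lt(max(abs(lin$L1_10 - L1fd)), 1e-6)
  # mu1-dependence of the linear coefficients
  lin2 <- expand_linearization(thb, mu1 = 1e-3)
  expect_equal(lin2$b11, lin$L0[1, 1] + 1e-3 * lin$L1_10[1, 1])
})

test_that("the critical eigenstructure is biorthonormal", {
  thb <- get_thb()
  lin <- expand_linearization(thb)
  eig <- eigenstructure(lin)
  expect_lt(Mod(sum(eig$eta0 * eig$xi0) - 1), 1e-10)
  expect_lt(Mod(sum(eig$etan * eig$xin) - 1), 1e-10)
  expect_lt(Mod(sum(eig$eta0 * Conj(eig$xi0))), 1e-10)
  expect_equal(eig$xi0[1], 1 + 0i)
  expect_lt(abs(eig$omega0^2 - det(lin$L0)), 1e-8)
  # left-eigenvector property: eta0^T (i w0 I - L0) = 0
  M0 <- 1i * eig$omega0 * diag(2) - lin$L0
  expect_lt(max(Mod(t(eig$eta0) %*% M0)), 1e-8)
  # Turing-mode matrix is singular with etan its left null vector
  Mn <- eig$Mk(0, thb$k0_star)
  expect_lt(max(Mod(t(eig$etan) %*% Mn)), 1e-8)
})

test_that("linear unfolding coefficients equal eigenvalue derivatives", {
  thb <- get_thb()
  nf <- get_nf()
  l <- thb$params$l; ns <- thb$k0_star
  modematrix <- function(h, D0, n) {
    p <- model_params(1.8, 0.2, 0.5, 0.3, h = h, D0 = D0, l = l)
    e <- interior_equilibria(p)$E2star
    jacobian_at(e$u, e$v, p) - diag(c(D0, 1)) * n^2 / l^2
  }
  dh <- 1e-6
  # Hopf-mode complex eigenvalue derivative w.r.t. mu1
  lam0 <- function(h) {
    ev <- eigen(modematrix(h, thb$D0_star, 0), only.values = TRUE)$values
    ev[which.max(Im(ev))]
  }
  dlam <- (lam0(thb$hH + dh) - lam0(thb$hH - dh)) / (2 * dh)
  expect_lt(Mod(dlam - nf$B11) / Mod(nf$B11), 1e-4)
  # B21 = 0: the Hopf mode has no diffusion factor at wavenumber 0
  expect_identical(nf$B21, 0 + 0i)
  # Turing-mode real eigenvalue derivatives w.r.t. (mu1, mu2)
  lamn <- function(h, D0) {
    ev <- eigen(modematrix(h, D0, ns), only.values = TRUE)$values
    ev[which.max(Re(ev))]
  }
  d1 <- Re(lamn(thb$hH + dh, thb$D0_star) - lamn(thb$hH - dh, thb$D0_star)) / (2 * dh)
  d2 <- Re(lamn(thb$hH, thb$D0_star + dh) - lamn(thb$hH, thb$D0_star - dh)) / (2 * dh)
  expect_lt(abs(d1 - nf$B13) / abs(nf$B13), 1e-4)
  expect_lt(abs(d2 - nf$B23) / abs(nf$B23), 1e-4)
})

test_that("the Hopf-mode cubic coefficient is consistent with the kinetic Lyapunov coefficient", {
  # Re(B210) must equal 4 alpha / ((N0^2 + 1) l pi): both describe the cubic
  # radial growth of the uniform oscillation, computed through entirely
  # different code paths
  thb <- get_thb()
  nf <- get_nf()
  hr <- hopf_analysis(base_params())
  pred <- 4 * hr$alpha / ((hr$N0^2 + 1) * thb$params$l * pi)
  expect_lt(abs(Re(nf$B210) - pred) / abs(pred), 1e-6)
  expect_equal(nf$kappa11, 1)   # subcritical uniform oscillation
})

test_that("cubic coefficients match direct PDE amplitude fits at the singularity", {
  thb <- get_thb()
  nf <- get_nf()
  eig <- nf$intermediates$eig
  nx <- 128
  T0 <- 2 * pi / eig$omega0
  # pattern-mode self-coupling: d ln z3/dt = B003 z3^2 (alpha2 = 0 here)
  ic <- thb_mode_ic(thb, eig, nx, z3 = 0.004)
  fld <- pde_simulate(thb$params, ic, nx = nx, t_end = 2500, n_save = 500)
  pr <- mode_projections(fld, eig, thb)
  sel <- which(pr$t >= 100)
  lz <- log(pr$z3[sel]); zz <- pr$z3[sel]^2; tt <- pr$t[sel]
  chunk <- 40
  ks <- seq(1, length(sel) - chunk, by = chunk)
  est <- vapply(ks, function(k) (lz[k + chunk] - lz[k]) / (tt[k + chunk] - tt[k]), numeric(1))
  amp2 <- vapply(ks, function(k) mean(zz[k:(k + chunk)]), numeric(1))
  fit <- stats::lm(est ~ amp2)
  expect_lt(abs(coef(fit)[2] - nf$B003) / nf$B003, 0.05)
  expect_lt(abs(coef(fit)[1]), 1e-4)     # no linear growth at the singularity
  # cross coupling of the oscillation on the pattern: d ln z3/dt = B111 |z1|^2
  ic <- thb_mode_ic(thb, eig, nx, z1 = 0.02, z3 = 2e-4)
  np <- 400
  fld <- pde_simulate(thb$params, ic, nx = nx, t_end = 3 * T0, n_save = 3 * np)
  pr <- mode_projections(fld, eig, thb)
  idx <- (np + 1):(2 * np + 1)           # second whole oscillation period
  sl <- (log(abs(pr$z3[max(idx)])) - log(abs(pr$z3[min(idx)]))) / T0
  m1 <- mean(abs(pr$z1[idx])^2)
  expect_lt(abs(sl / m1 - nf$B111) / nf$B111, 0.08)
  # cross coupling of the pattern on the oscillation: d ln rho/dt = Re(B102) z3^2,
  # with rho demodulated at the Hopf frequency
  ic <- thb_mode_ic(thb, eig, nx, z1 = 2e-3, z3 = 0.012)
  fld <- pde_simulate(thb$params, ic, nx = nx, t_end = 4 * T0, n_save = 4 * np)
  pr <- mode_projections(fld, eig, thb)
  demod <- function(k) {
    idx <- ((k - 1) * np + 1):(k * np)
    abs(mean(pr$z1[idx] * exp(-1i * eig$omega0 * pr$t[idx])))
  }
  rho <- vapply(2:4, demod, numeric(1))
  z3m <- vapply(2:4, function(k) mean(pr$z3[((k - 1) * np + 1):(k * np)]^2), numeric(1))
  ests <- diff(log(rho)) / T0 / ((z3m[-3] + z3m[-1]) / 2)
  expect_lt(abs(ests[1] - Re(nf$B102)) / abs(Re(nf$B102)), 0.12)
  expect_lt(abs(ests[2] - Re(nf$B102)) / abs(Re(nf$B102)), 0.2)
})

test_that("the one-call wrapper reproduces the assembled coefficients", {
  nf <- get_nf()
  nf2 <- turing_hopf_normal_form(base_params())
  expect_equal(nf2$B11, nf$B11)
  expect_equal(nf2$B003, nf$B003)
  expect_equal(nf2$kappa21, nf$kappa21)
})
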