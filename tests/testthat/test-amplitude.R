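# Reference points: one published unfolding point per region of the
# published planar system (the sixth uses the sign-corrected point whose
# inventory actually matches the published table; the caption's point is
# exercised in the acceptance suite).
region_points <- list(R1 = c(0.0005, 0.001), R2 = c(-0.00001, 0.1),
                      R3 = c(-0.000003, 0.0004), R4 = c(-0.000003, 0),
                      R5 = c(-0.000003, -0.1), R6 = c(0.0001, -0.04))

inventory <- function(eq) sort(unique(sub("[+-]$", "", eq$label)))
stable_set <- function(eq) sort(unique(sub("[+-]$", "", eq$label[eq$stability == "stable"])))

test_that("equilibrium inventories and stability reproduce the published table", {
  sys <- reference_amplitude_system()
  expected <- list(
    R1 = list(inv = "A0", st = "A0"),
    R2 = list(inv = c("A0", "A1"), st = "A1"),
    R3 = list(inv = c("A0", "A1", "A3"), st = "A3"),
    R4 = list(inv = c("A0", "A1", "A2", "A3"), st = "A3"),
    R5 = list(inv = c("A0", "A1", "A2"), st = "A2"),
    R6 = list(inv = c("A0", "A2"), st = "A2"))
  for (rg in names(region_points)) {
    eq <- amplitude_equilibria(sys, region_points[[rg]])
    expect_identical(inventory(eq), expected[[rg]]$inv, label = rg)
    expect_identical(stable_set(eq), expected[[rg]]$st, label = rg)
  }
  # at the origin every branch collapses onto the trivial state
  eq0 <- amplitude_equilibria(sys, c(0, 0))
  expect_true(all(eq0$rho == 0 & eq0$sigma == 0))
})

test_that("amplitude equilibria match their closed forms", {
  sys <- reference_amplitude_system()
  mu <- c(-0.000003, 0)
  eq <- amplitude_equilibria(sys, mu)
  a1 <- sum(sys$alpha1_coeffs * mu); a2 <- sum(sys$alpha2_coeffs * mu)
  expect_equal(eq$rho[eq$label == "A1"], sqrt(-a1 / sys$kappa11))
  expect_equal(abs(eq$sigma[eq$label == "A2+"]), sqrt(-a2 / sys$kappa22))
  # the published mixed-mode coordinates (A3) for this coefficient set
  a3 <- eq[eq$label == "A3+", ]
  expect_lt(abs(a3$rho^2 - (-1.7973 * mu[1] + 0.0193 * mu[2])) / a3$rho^2, 5e-3)
  expect_lt(abs(a3$sigma^2 - (-58.5938 * mu[1] - 0.0804 * mu[2])) / a3$sigma^2, 5e-3)
})

test_that("bifurcation curves separate the branches they create", {
  sys <- reference_amplitude_system()
  crv <- bifurcation_curves(sys)
  expect_identical(crv$H0$slope, Inf)              # alpha1 has no mu2 slope
  expect_lt(abs(crv$T$slope - (-127.054)), 1e-2)   # alpha2 ratio
  # self-consistent mixed-mode boundaries, close to the published slopes
  expect_lt(abs(crv$T1$slope - (-728.5753)) / 728.5753, 0.01)
  expect_lt(abs(crv$T2$slope - 92.9795) / 92.9795, 0.01)
  # crossing H0 toggles A1; crossing T toggles A2
  has <- function(mu, lab) lab %in% amplitude_equilibria(sys, mu)$label
  expect_false(has(c(1e-5, 0), "A1")); expect_true(has(c(-1e-5, 0), "A1"))
  muT <- c(1e-5, 0)
  m2 <- -127.054 * 1e-5
  expect_false(has(c(1e-5, m2 + 1e-6), "A2+"))
  expect_true(has(c(1e-5, m2 - 1e-6), "A2+"))
})

test_that("region classification labels the published points", {
  sys <- reference_amplitude_system()
  for (rg in names(region_points)) {
    expect_identical(classify_region(sys, region_points[[rg]])$region, rg)
  }
  # points on curves get the curve's name
  expect_identical(classify_region(sys, c(0, 0.01))$region, "H0")
  expect_error(classify_region(sys, c(0, 0)), "singularity")
})

test_that("direct integration converges to the predicted attractor in every region", {
  sys <- reference_amplitude_system()
  set.seed(41)
  for (rg in names(region_points)) {
    mu <- region_points[[rg]]
    eq <- amplitude_equilibria(sys, mu)
    stab <- eq[eq$stability == "stable", ]
    scale <- max(sqrt(abs(sys$alpha1_coeffs[1] * mu[1])),
                 sqrt(abs(sum(sys$alpha2_coeffs * mu))), 1e-4)
    for (k in 1:20) {
      init <- c(runif(1, 0, 2 * scale), runif(1, -2 * scale, 2 * scale))
      out <- integrate_amplitude(sys, mu, init, t_end = 60 / max(abs(
        c(sys$alpha1_coeffs * mu, sys$alpha2_coeffs * mu))))
      fin <- out[nrow(out), c("rho", "sigma")]
      dists <- sqrt((stab$rho - fin[1])^2 + (stab$sigma - fin[2])^2)
      expect_lt(min(dists), 0.05 * max(scale, 1e-3), label = paste(rg, "start", k))
    }
  }
})

test_that("with the computed (fully subcritical) coefficients trajectories escape", {
  nf <- get_nf()
  sys <- amplitude_system(nf = nf)
  mu <- c(-1e-5, 0)
  lab <- classify_region(sys, mu)
  expect_match(lab$regime, "no stable amplitude equilibrium")
  # cubic growth escapes (the truncated system even blows up in finite
  # time); the amplitude at least triples before then
  out <- try(suppressWarnings(
    integrate_amplitude(sys, mu, c(0.05, 0.001), t_end = 190)), silent = TRUE)
  escaped <- inherits(out, "try-error") ||
    suppressWarnings(max(abs(out[, c("rho", "sigma")]), na.rm = TRUE)) > 0.15
  expect_true(escaped)
})

test_that("amplitude equilibria translate to the documented PDE regimes", {
  expect_identical(pde_interpretation("A0"), "constant steady state")
  expect_identical(pde_interpretation("A1"), "spatially homogeneous periodic solution")
  expect_identical(pde_interpretation("A2+"), "nonconstant steady state")
  expect_identical(pde_interpretation("A3-"), "spatially inhomogeneous periodic solution")
})
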