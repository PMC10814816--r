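# Named worked-example scenarios near the Turing-Hopf point of the
# a = 1.8, b = 0.2, c = 0.5, d = 0.3, l = 2 parameter set.  Each preset
# encodes the unfolding point (mu1, mu2) and the initial data of one of
# the published simulation figures, verbatim (including the base states
# rounded to 4 decimals as printed; set use_computed_equilibrium = TRUE
# to replace them with the exactly computed shifted equilibrium).

scenario_table <- function() {
  list(
    fig4 = list(mu = c(0.0005, 0.001),
                ic = list(base_u = 0.6498, base_v = 0.2572,
                          amp_u = -0.000001, amp_v = 0.000001,
                          mode_u = "sin", mode_v = "cos"),
                expected_region = "R1",
                expected_regime = "constant steady state",
                t_end = 6000),
    fig5 = list(mu = c(-0.00001, 0.1),
                ic = list(base_u = 0.6437, base_v = 0.256,
                          amp_u = -0.0002, amp_v = -0.00025,
                          mode_u = "sin", mode_v = "cos"),
                expected_region = "R2",
                expected_regime = "homogeneous periodic",
                t_end = 90000),
    fig6 = list(mu = c(-0.000003, 0.0004),
                ic = list(base_u = 0.6439, base_v = 0.2561,
                          amp_u = 0.00008, amp_v = 0.000006,
                          mode_u = "cos", mode_v = "sin"),
                expected_region = "R3",
                expected_regime = "inhomogeneous periodic",
                t_end = 250000),
    fig7 = list(mu = c(-0.000003, 0),
                ic = list(base_u = 0.6439, base_v = 0.2561,
                          amp_u = 0.00008, amp_v = 0.000006,
                          mode_u = "cos", mode_v = "sin"),
                expected_region = "R4",
                expected_regime = "inhomogeneous periodic",
                t_end = 250000),
    fig8 = list(mu = c(-0.000003, -0.1),
                ic = list(base_u = 0.6439, base_v = 0.2561,
                          amp_u = -0.00008, amp_v = -0.000006,
                          mode_u = "cos", mode_v = "sin"),
                expected_region = "R5",
                expected_regime = "inhomogeneous steady",
                t_end = 20000),
    fig9 = list(mu = c(-0.0001, 0.04),
                ic = list(base_u = 0.6452, base_v = 0.2563,
                          amp_u = -0.0002, amp_v = -0.00025,
                          mode_u = "sin", mode_v = "cos"),
                expected_region = "R6",
                expected_regime = "inhomogeneous steady",
                t_end = 60000))
}

#' Worked-example simulation scenarios
#'
#' Returns one of the named presets `"fig4"` .. `"fig9"`: the unfolding
#' point \eqn{(\mu_1, \mu_2)} relative to the Turing-Hopf singularity of
#' the `a = 1.8, b = 0.2, c = 0.5, d = 0.3, l = 2` parameter set, the
#' published initial data, the published expected region and PDE regime
#' (kept as reference metadata with source tags), and a default horizon
#' `t_end` long enough for the slow local growth rates
#' (of order \eqn{|\mu_1| \cdot 16}) to reach the attractor.
#'
#' The perturbations are `sin x` / `cos x` exactly as published; with
#' `l = 2` these correspond to `wavenumber = 2` in
#' [initial_condition()]'s `fun(w x / l)` parameterization.
#'
#' @param name scenario name, `"fig4"` .. `"fig9"`.
#' @param use_computed_equilibrium replace the published (rounded) base
#'   state by the exactly computed equilibrium \eqn{E_2^*(h_H + \mu_1)}.
#' @param thb optionally a precomputed `"turing_hopf_point"` for the base
#'   parameter set (recomputed if missing).
#' @return An object of class `"scenario"`: list with `name`, `params`
#'   (a [model_params()] with `h`, `D0` set from the unfolding), `mu`,
#'   `ic` (an [initial_condition()]), `t_end`, and `expected` (region and
#'   regime strings, each tagged `source = "published"`).
#' @export
scenario_preset <- function(name, use_computed_equilibrium = FALSE,
                            thb = NULL) {
  tab <- scenario_table()
  if (!name %in% names(tab)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(tab), collapse = ", "))
  }
  sc <- tab[[name]]
  if (is.null(thb)) {
    thb <- turing_hopf_point(model_params(1.8, 0.2, 0.5, 0.3, l = 2))
  }
  h <- thb$hH + sc$mu[1]
  D0 <- thb$D0_star + sc$mu[2]
  p <- model_params(1.8, 0.2, 0.5, 0.3, h = h, D0 = D0, l = 2)
  icd <- sc$ic
  if (use_computed_equilibrium) {
    e <- interior_equilibria(p)$E2star
    icd$base_u <- e$u; icd$base_v <- e$v
  }
  ic <- initial_condition(icd$base_u, icd$base_v, icd$amp_u, icd$amp_v,
                          mode_u = icd$mode_u, mode_v = icd$mode_v,
                          wavenumber = 2)
  structure(list(name = name, params = p, mu = sc$mu, ic = ic,
                 t_end = sc$t_end,
                 expected = list(region = sc$expected_region,
                                 regime = sc$expected_regime,
                                 source = "published")),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario %s: mu = (%g, %g), h = %.6g, D0 = %.6g, t_end = %g\n",
              x$name, x$mu[1], x$mu[2], x$params$h, x$params$D0, x$t_end))
  cat(sprintf("  published expectation: %s (%s)\n",
              x$expected$regime, x$expected$region))
  invisible(x)
}

#' Run a worked-example scenario
#'
#' Simulates a [scenario_preset()] with [pde_simulate()] and classifies
#' the outcome with [classify_attractor()].
#'
#' @param sc a `"scenario"` (or its name).
#' @param nx grid cells (default 200).
#' @param t_end override of the preset horizon.
#' @param ... further arguments to [pde_simulate()].
#' @return The classified `"simulation_field"`.
#' @export
run_scenario <- function(sc, nx = 200, t_end = NULL, ...) {
  if (is.character(sc)) sc <- scenario_preset(sc)
  stopifnot(inherits(sc, "scenario"))
  field <- pde_simulate(sc$params, sc$ic, nx = nx,
                        t_end = if (is.null(t_end)) sc$t_end else t_end, ...)
  classify_attractor(field)
}
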