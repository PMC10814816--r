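Package: turinghopf
Title: Turing-Hopf Bifurcation Analysis of a Diffusive Ratio-Dependent
    Predator-Prey Model with Allee Effect and Predator Harvesting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the complete local bifurcation analysis of a
    one-dimensional reaction-diffusion predator-prey model with
    ratio-dependent functional response, a strong Allee effect in the prey,
    and proportional predator harvesting.  Computes boundary and interior
    equilibria with stability classification, locates the Hopf threshold in
    the harvesting rate and evaluates the first Lyapunov coefficient,
    derives the mode-wise dispersion relation, Turing bifurcation curves and
    critical wavenumbers, assembles the third-order normal form at the
    Turing-Hopf codimension-two singularity, analyses the resulting planar
    amplitude system (equilibria, bifurcation curves, region
    classification), and integrates both the kinetic ODE system and the
    full PDE by the method of lines with Neumann boundary conditions,
    classifying the long-term spatiotemporal regime.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
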