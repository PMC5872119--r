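Package: phagegrid
Title: Spatially Structured Phage-Bacteria Dynamics with Fixed Phage Sinks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic lattice (torus) simulation of lytic bacteriophage and
    bacteria in which phage die by adsorbing to spatially fixed sinks:
    exopolysaccharide (EPS) laid down at fixed patches, and short-lived debris
    from lysed cells. Includes mass-action counterparts (a globally shuffled
    grid with identical parameters, and a delay differential equation model
    integrated with 'deSolve'), together with the equilibrium-referenced
    amplification statistics (alpha, alpha*b, C-hat, A_g, A_ode and their
    upper bounds) used to measure how much spatial self-organization around
    phage sinks elevates the density of sensitive cells above the mass-action
    equilibrium.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    jsonlite
Config/testthat/edition: 3
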