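Package: plastisim
Title: Individual-Based Simulation of Phenotypic Plasticity Evolution
    Under Spatial and Temporal Environmental Heterogeneity
Version: 0.1.0
Authors@R:
    person("Plastisim", "Developers", email = "plastisim@example.org",
           role = c("aut", "cre"))
Description: Forward-time, individual-based simulator of the evolution of
    linear reaction norms in a metapopulation arrayed along an environmental
    gradient. Diploid genotypes carry nonplastic (intercept) and plastic
    (environment-multiplied) loci; viability selection is Gaussian around a
    deme-specific optimum; dispersal follows a stepping-stone (Gaussian
    kernel) or island model; local density regulation is soft. Temporal
    heterogeneity is overlaid on the spatial gradient as an AR(1) process
    acting before development, before selection, or both, with a
    configurable within-generation correlation and optional spatial
    synchronization. The package provides replicate management with
    extinction accounting, plasticity summary statistics standardized to
    the optimal reaction norm, parameter-sweep helpers with figure-style
    presets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
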