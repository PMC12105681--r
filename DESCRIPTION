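Package: clusterpdf
Title: Solution-State Structure Determination of Small Clusters from Pair
    Distribution Function Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining the solution-state atomic structure of
    small metal clusters (such as DNA-stabilized silver nanoclusters) from
    X-ray total scattering. Implements real-space pair distribution function
    (PDF) simulation with Gaussian pair broadening, background subtraction
    and sine Fourier reduction of F(Q) data, two-stage least-squares
    refinement of atomic positions with an empirical exponentially damped
    sine solvation wave, perturbation-ensemble refinement to map positional
    distributions, principal-axis displacement and rotation analysis of the
    refined structures, and Biso-scan comparison of DNA conformations.
    A synthetic-data module generates ground-truth clusters, distortion
    fields and noisy observables so the whole pipeline is testable without
    experimental downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
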