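Package: foamfea
Title: Finite-Element Modeling of Prophylactic Foam Dressings Under
    Compression and Shear
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static nonlinear finite-element analysis of sacral soft
    tissue protected by silicone foam dressings, for pressure-injury
    biomechanics. Builds parametric layered meshes (mattress, dressing, soft
    tissue with an embedded bony prominence), solves nearly-incompressible
    neo-Hookean plane-strain problems with Coulomb-friction contact and
    force-targeted oblique loading, and quantifies tissue exposure through
    volume-weighted strain-energy-density histograms, damage-threshold
    pooling, and percent-SED-reduction comparisons across dressings. Also
    analyses flat-punch indentation curves to effective dressing moduli and
    generates synthetic inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
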