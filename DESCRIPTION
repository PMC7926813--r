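Package: phantomix
Title: Recipe Design for Tissue-Mimicking Liquid Phantoms in Microwave Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs Triton X-100/saline liquid mixtures whose complex
    permittivity mimics biological tissues over the 0.5-3 GHz band used in
    microwave medical imaging. Tissues are described by multi-pole Cole-Cole
    dispersion models, the surfactant by a Debye relaxation and the saline by
    a salinity- and temperature-parametric Debye model; the mixture
    permittivity follows one of five binary liquid mixing laws (Kraszewski,
    Bottcher, Lichtenecker, Looyenga, Bruggeman). A damped Gauss-Newton
    optimizer with analytic derivatives fits the saline volume fraction and
    NaCl concentration so the mixture matches a target tissue spectrum, and
    the result is turned into a bench-ready recipe (masses per batch volume,
    preparation protocol, viscosity warnings). A 1D transfer-matrix explorer
    ranks coupling media for field penetration through layered head stacks,
    and STL/manifest utilities bind phantom cavity geometry to fitted recipes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
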