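Package: anodpore
Title: Anodization Process-Structure Surrogates and Nanopore Drug-Release Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling nanoporous anodic alumina (NAA) used as a
    drug-releasing implant coating. Maps anodization process parameters
    (electrolyte type, voltage, temperature, time) to predicted pore diameter
    via regression surrogates (ordinary least-squares and a feed-forward
    neural network trained with Adam and early stopping), compares them by
    k-fold cross-validation, ranks feature importance from first-layer weights
    or standardized coefficients, and couples predicted pore geometry to
    release kinetics through a Renkin-corrected Higuchi square-root model
    (effective diffusivity, release constant, t50/t90, release profiles and
    one-at-a-time sensitivity). Includes a seeded synthetic-data generator
    emulating the statistical structure of literature anodization compilations
    so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
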