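Package: clmscreen
Title: Pooled Screening of Microbial Biocatalyst Libraries with Redox
    Kinetics and Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for combinatorial (pooled) screening of whole-cell
    biocatalyst libraries for ketone-reduction and alcohol-oxidation
    activity. Constructs and validates strain-by-batch pooling designs,
    computes assay-count economics of pooled versus strain-by-strain
    screening, simulates batch incubations from per-strain kinetic
    profiles via a coupled reduction/oxidation (stereoinversion) ODE
    model with oxygen- and biomass-dependent oxidation, deconvolves
    active strains from batch-level conversion readouts under a union
    (group-testing) model, flags tandem-activity anomalies such as
    non-monotone product curves, and provides exact enantiomeric-excess
    algebra including the oxidation-only yield bound used to infer
    concurrent re-reduction. Includes a least-squares fitter recovering
    rate constants from time-course observations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
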