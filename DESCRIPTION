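Package: vfrheo
Title: Fibril-Scale Visco-Hyperelastic Modelling of Vocal-Fold Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Micro-mechanical simulator for the finite-strain, rate-dependent
    mechanics of vocal-fold tissues (lamina propria and vocalis). The tissue is
    idealised as a periodic network of four wavy fibril bundles embedded in an
    incompressible neo-Hookean matrix; each bundle and each steric bundle-bundle
    interaction behaves as a non-linear Zener element whose Maxwell branch carries
    a Carreau shear-thinning viscosity. The package builds the representative
    elementary volume from histological descriptors, upscales fibril forces to the
    macroscopic Cauchy stress, drives the model through oscillatory shear (SAOS and
    LAOS) and cyclic tension/compression/shear programs, post-processes storage and
    loss moduli, Lissajous and Pipkin diagrams and hysteresis metrics, and
    identifies histo-mechanical parameters from rheometric data by bounded
    non-linear least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
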