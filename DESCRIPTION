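Package: LumenFBA
Title: Host-Microbe Co-Metabolism Flux Balance Analysis Through a Shared Gut Lumen
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constraint-based simulation of prebiotic supplementation acting on
    human metabolism through gut bacteria. Builds co-metabolism models that
    couple a host and a microbial genome-scale metabolic network through a
    shared lumen compartment, converts prebiotic doses in grams into exchange
    flux bounds, and maximizes 25-hydroxyvitamin D3 secretion as a proxy for
    vitamin D deficient demand. Includes readers and writers for SBML Level 3
    FBC and COBRA JSON models, a deterministic bounded-variable simplex
    backend with parsimonious FBA, reaction knock-off simulation, dose
    response and flux-mode analyses, subsystem flux-change statistics, and
    screening of microbe model collections for prebiotic-dependent secretion
    of acetate, lactate and pyruvate. Fully specified toy host and microbe
    generators make every analysis testable without external model downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'LumenFBA-package.R'
    'accessors.R'
    'lp.R'
    'model-build.R'
    'fba.R'
    'comodel.R'
    'conditions.R'
    'toys.R'
    'experiments.R'
    'config.R'
    'io-json.R'
    'io-sbml.R'
    'readWrite.R'
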