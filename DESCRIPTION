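Package: cgflux
Title: Constraint-Based Flux Analysis and Strain Design for the
    Corynebacterium glutamicum Central Carbon Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stoichiometric modelling toolkit for model-guided strain design
    in Corynebacterium glutamicum. Provides a metabolic network data model
    with SBML (Level 3 + FBC), JSON and TSV readers and writers, elemental
    balance checking, flux balance analysis (FBA), flux variability analysis
    (FVA) and geometric FBA on top of a built-in bounded-variable simplex
    solver; reaction essentiality classification (essential, substitutable,
    blocked), regulation-mode recommendation, theoretical product yields,
    biomass-constrained production simulation and relative-flux attenuation
    sweeps; a curated central-carbon core model of C. glutamicum with
    genotype presets (anaplerosis knockouts, isocitrate-dehydrogenase
    attenuation, glyoxylate-shunt activation) and phosphoketolase (bifido
    shunt) pathway augmentation; and antisense small-RNA binding-sequence
    design utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    MASS,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
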