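Package: sumoscreen
Title: Proteome-Scale Discovery and Surface Mapping of Non-Covalent polySUMO2 Receptors
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for identifying non-covalent
    polySUMO2 receptors and mapping their SUMO-binding surfaces.
    Implements microarray signal-to-noise normalisation, print-tip and
    spatial loess correction of bound-minus-mock M-values and
    population-SD hit calling; carbene-footprinting fractional
    modification quantitation with t-test masking classification and
    residue painting; NMR titration intensity-loss and chemical-shift
    perturbation threshold-ladder classification; XRCC4-like SIM motif
    proteome scanning with acidic-context annotation and Fisher
    enrichment; and equilibrium single-site binding-constant fitting
    with and without ligand depletion. Includes seeded synthetic-data
    generators emulating each assay's statistical structure and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    grDevices,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
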