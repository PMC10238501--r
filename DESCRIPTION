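Package: dipscreen
Title: Simulation and Analysis of Domain-Insertion Optogenetic Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for domain-insertion profiling (DIP-seq) screens that
    insert a photoswitchable AsLOV2 domain at every nucleotide position of
    a target coding sequence. Models transposon-mediated construct
    arithmetic (target-site duplication, frame-variant scars, reading-frame
    classification, amino-acid site naming), simulates sheared-amplicon
    sequencing reads and iterative dark/light FACS selection, maps
    junction-spanning reads back to insertion positions, computes library
    coverage and enrichment statistics with hit clustering, and fits
    ligand-depletion-corrected one-site binding models to fluorescence
    anisotropy titrations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
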