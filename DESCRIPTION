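Package: peptriact
Title: Enzymatic Hydrolysis Assays, Box-Behnken Response-Surface Modelling
    and Virtual Screening of Bioactive Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational chain behind enzymatic production
    and screening of food-derived bioactive peptides: pH-stat degree-of-
    hydrolysis mathematics with temperature-dependent alpha-amino pKa,
    initial-rate estimation from kinetic progress curves, enzyme
    activation/inhibition and radical-scavenging assay statistics, three-
    factor Box-Behnken design construction with coded-unit quadratic
    least-squares fits, partial-SS ANOVA with lack-of-fit partitioning,
    Derringer-Suich multi-response desirability optimization, sequence-
    based peptide physicochemical properties (mass, net charge,
    isoelectric point), and a staged virtual-screening funnel with
    pluggable external scores. Includes seeded simulators for kinetic
    traces, design responses and peptide identification tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
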