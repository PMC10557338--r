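Package: bloodmealSTR
Title: Combined Human-Mosquito STR Profiling of Aedes albopictus Blood Meals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a combined human-Aedes albopictus short tandem
    repeat (STR) panel used to identify the human hosts bitten by field-collected
    mosquitoes. Models the 35-locus three-multiplex panel, bins sized capillary
    electropherogram peaks into allele calls and multilocus profiles, computes
    Nei's D_A genetic distances between individual profiles with principal
    coordinates analysis, matches blood-meal-derived profiles against a saliva
    reference database under a D_A threshold rule, detects and deconvolves
    multiple feedings from per-locus allele counts and relative peak heights,
    models host-DNA decay with digestion time as a descending sigmoid, and
    assembles bipartite human-mosquito biting networks. A seeded synthetic
    electropherogram generator emulates Hardy-Weinberg populations, Mendelian
    families, mixed blood meals, preservation effects, digestion decay and
    amplicon-length-dependent dropout, with full ground-truth ledgers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
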