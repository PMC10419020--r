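Package: cdclamp
Title: Cyclodextrin Host-Guest Modelling: Methylation Trees, Atypical
    Hydrogen-Bond Census and Binding Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing host-guest complexes of lipophilic drugs
    with methylated beta-cyclodextrins. Reads annotated XYZ geometries and
    detects intermolecular hydrogen bonds, including atypical Fe...H-O
    contacts and two-bond "clamps" on a single glucose unit; explores
    cyclodextrin methylation states by greedy generation-based mutation
    trees scored through a pluggable energy oracle; aggregates trees into
    per-series statistics; fits apparent 1:1 association constants by the
    Benesi-Hildebrand double-reciprocal method and classifies
    Higuchi-Connors phase-solubility profiles. Seeded generators produce
    every synthetic input the pipeline consumes: toy ring geometries with
    planted contacts, energy landscapes with known optima, and noisy
    titration curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
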