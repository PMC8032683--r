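Package: betagrain
Title: Beta-Sheet Detection in MARTINI Coarse-Grained Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects putative beta-sheets in MARTINI coarse-grained peptide
    structures from backbone-grain coordinates alone. Near-collinear triples of
    grains on distinct peptides are identified with an angular and a distance
    threshold, glued into sheet components through a triple-overlap graph, and
    summarised per frame (triple and component counts, fraction of grains in
    sheets, residue-type compositions and ratios). Includes a Gromos87 (.gro)
    reader/writer for single structures and concatenated trajectory frames, a
    PDB backbone coarse-graining mapper, deterministic synthetic-structure
    generators (ideal sheets, helices, random coils) for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    bio3d,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
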