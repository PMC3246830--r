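Package: xtalsearch
Title: Search Engines for Small-Molecule Crystal-Structure Databases
Version: 0.1.0
Authors@R:
    person("Ivo", "Renner", email = "ivo.renner@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for building and searching local
    databases of small-molecule crystal-structure entries. Provides 2D
    substructure search with necessary-condition bit screens and
    smallest-ring constraints, path-based 2040-bit molecular fingerprints
    scored with Tanimoto and Dice coefficients, combined text/numeric/date
    field search over a tokenized inverted index, and angle-aware reduced
    unit-cell search based on Niggli reduction with nearly-Buerger related
    cells. Includes readers for V2000 SDF/MOL, a linear molecular notation,
    and minimal CIF cell blocks, plus deterministic synthetic fixture
    generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
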