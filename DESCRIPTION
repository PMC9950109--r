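Package: fragverse
Title: Mining Protein-Fragment Complexes for Versatile Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies versatile small-molecule fragments, i.e. fragments
    observed with two or more distinct protein-bound binding modes and in two
    or more dissimilar binding cavities, from collections of protein-fragment
    crystal structures. Binding modes are encoded as complete graphs of typed
    interaction pseudo-atoms and compared with a subgraph matching kernel;
    binding cavities are encoded as pharmacophore-labeled point clouds and
    compared by rigid registration. Includes the chemistry characterization
    of selected fragments (descriptors, rule-of-three, plane of best fit,
    PAINS flags, Bemis-Murcko scaffolds, substructure contribution), sequence
    relatedness of the binding proteins, and a synthetic-complex generator
    with planted ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
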