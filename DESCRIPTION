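Package: rhizodyn
Title: Multi-Kingdom Root Microbiota Dynamics: Stability, Convergence and
    Metabolite Covariation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for amplicon-based surveys of soil- and
    root-associated microbial communities sampled across compartments
    (bulk soil, rhizosphere, root) and host growth stages. Implements
    rarefaction-based alpha diversity, Bray-Curtis beta diversity with
    (constrained) principal-coordinate analysis and PERMANOVA, the
    stable/dynamic taxon partition with its stable-to-dynamic ratio,
    a community-convergence analysis against initial and final reference
    communities at ASV and phylum levels, and a random-forest plus
    Spearman-correlation procedure linking taxa to metabolite profiles.
    Ships a Dirichlet-multinomial simulator of field-experiment-shaped
    count tables with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    biomformat,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
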