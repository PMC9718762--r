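Package: casProspector
Title: Mining Metagenome Assemblies for CRISPR-Cas12a Effectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for discovering Cas12a (Cpf1) effector candidates in
    metagenome assemblies. Detects CRISPR repeat-spacer arrays in contigs
    with a CRT-style seed-and-extend scanner, calls open reading frames in
    the 15-kb neighbourhood of each array, screens them against a panel of
    known Cas12a bait proteins with local protein alignment and the
    800-1500 residue / methionine-start filters, analyses direct repeats
    (orientation, crRNA maturation cut, mature 5' handle stem-loop,
    classification against known handle families), places candidates on a
    neighbor-joining phylogeny with bootstrap support, and predicts
    PAM-guided in-silico digestion products together with band-intensity
    based cleavage and editing efficiencies. Includes a deterministic
    synthetic-metagenome generator with planted ground truth so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
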