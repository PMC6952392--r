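Package: ever
Title: Evolution-Simulating Genetic Algorithm for Predicting Drug-Resistance Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-resistance point mutations in a drug-binding site by
    simulating evolution at the DNA level. Binding-site residues are
    back-translated into their real codons, random single-nucleotide
    substitutions are introduced in large offspring populations, mutants are
    evaluated for drug and ATP binding (via an external side-chain
    repacking/docking adapter or a deterministic surrogate landscape), and a
    resistance score that rewards weakened drug binding while preserving ATP
    binding drives selection over generations. Includes replicate aggregation
    into mutation-frequency distributions and an IC50 safety-window triage
    classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
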