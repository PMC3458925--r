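Package: acidostab
Title: Comparative Sequence Analysis of Acid-Stable Proteins and Their
    Neutral-Cytoplasm Orthologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the comparative study of proteins from organisms with
    acidic cytoplasm (AP) against orthologs from neutral-cytoplasm organisms
    (NP). Builds non-redundant AP-NP ortholog pair sets by reciprocal best
    hits with similarity, length and redundancy filters; computes an
    889-entry sequence feature catalogue (amino acid and dipeptide
    composition, charge and residue-category statistics, isoelectric point,
    instability index, aliphatic index, GRAVY); derives a directional 20x20
    amino acid substitution propensity matrix from pairwise alignments with
    Fisher exact bias calls; fits a linear relative-difference scoring
    function for relative acidostability by hill climbing; and ranks
    features by Random Forest Gini importance with pair-aware
    cross-validation. Includes a synthetic ortholog-pair simulator so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
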