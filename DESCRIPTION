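Package: molmc
Title: Monte Carlo Ligand Design in Chemical Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metropolis Monte Carlo search in small-molecule chemical space.
    A starting compound is evolved by elementary chemical moves (adding
    substituents, removing atoms, changing atom and bond types, forming,
    breaking and aromatizing rings, rearranging bonds) or by BRICS
    fragment recombination, under a composite objective combining a
    pluggable protein-ligand structure-prediction confidence score with
    synthetic-accessibility, aqueous-solubility and drug-likeness biases.
    A dice-similarity objective on atom-pair fingerprints supports
    target-ligand recovery experiments with no external backend.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp, ChemmineR, ChemmineOB, jsonlite, yaml, Biostrings
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
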