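Package: dermovasc
Title: Dermal Shield Vascularization: Porosity Quantification and
    Phylogenetic Comparative Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies bone porosity (vascular area fraction) from binary
    cross-section images of dermal plates, including crest bridging so that
    ornamentation pits count as vascular space, and analyses the resulting
    trait on time-scaled phylogenies: Blomberg's K with a randomization
    test, Pagel's lambda by maximum likelihood, phylogenetic ANOVA with a
    Brownian-motion simulation null, squared-change parsimony ancestral
    state reconstruction, and per-lifestyle descriptive statistics. Ships
    a transcribed specimen dataset of turtle (Testudinata) and
    crocodylian-line (Pseudosuchia) dermal plates plus synthetic-data
    generators (trees, traits, sections) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    png,
    tiff,
    stats,
    utils
Suggests:
    phytools,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
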