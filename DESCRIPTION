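Package: ligscreen
Title: Ligand-Based Virtual Screening of Compound Libraries with
    Descriptor-Space Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ligand-based virtual screening of kinase-inhibitor
    and other activity classes from large compound libraries. Molecules read
    from SMILES or SDF input are featurized with a fixed registry of 98 1D/2D
    molecular descriptors (simple counts, chemical properties, molecular
    connectivity and shape indices, and Kier-Hall electrotopological state
    sums). Compound libraries are clustered into chemical-space families for
    putative non-inhibitor generation, and four screening engines are
    provided on the shared descriptor space: a hard-margin RBF-kernel support
    vector machine, Tanimoto similarity searching, k-nearest-neighbour, and a
    Parzen-window probabilistic neural network. An evaluation harness
    computes sensitivity, specificity, overall accuracy and the Matthews
    correlation coefficient under stratified 5-fold cross-validation, plus
    screening-level yield, virtual-hit and false-hit statistics and
    family-novelty analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    ChemmineR,
    e1071,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
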