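Package: treegrm
Title: Branch Genetic Relatedness Matrices on Succinct Tree Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with the branch genetic relatedness matrix (GRM)
    defined on an ancestral recombination graph stored as a succinct tree
    sequence. Provides the tree-sequence data model with validation and table
    input/output, materialized relatedness matrices (divergence, uncentered and
    centered branch GRM, eGRM, genotype GRM, allele-match covariance, pedigree
    kinship) and the algebraic identities connecting them, an exact incremental
    O(n + t log n) branch-GRM-vector product that never materializes the matrix,
    randomized principal component analysis of the branch GRM built on that
    product, and simulators (sequential coalescent with recombination, Poisson
    mutation dropping, additive traits, synthetic pedigrees, gene-dropping and
    recapitation) that make every identity testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
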