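Package: rnapopstruct
Title: Population Structure Inference and Control from RNA-Seq Derived Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-variant-calling toolkit for estimating genetic population
    structure from genotypes called out of RNA-seq reads and for controlling
    that structure in downstream expression analyses. Implements PLINK-style
    genotype quality control and linkage-disequilibrium pruning, strand-flip
    aware harmonization and concordance against a paired genotype set,
    reference-panel intersection, standardized-genotype principal component
    analysis, canonical correlation analysis with Wilks' Lambda sequential
    tests, the systematic-inflation metric m for differential expression, a
    genomic-relationship-matrix REML mixed model, and a Balding-Nichols
    simulator of paired array/RNA-seq genotype views with confounded
    negative-binomial expression counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ggplot2
Config/testthat/edition: 3
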