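Package: gutrules
Title: Gut Microbiota Group Comparison and Predictive Association Rule Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking gut microbial composition to adolescent
    obesity status. Provides a synthetic cohort generator for percent-abundance
    taxa tables with planted group differences, zero inflation and
    taxon-covariate correlations; pyrosequencing read quality filters and
    abundance normalization; taxonomic rank roll-ups and the
    Firmicutes-to-Bacteroidetes ratio; Shannon and Bray-Curtis diversity with
    principal coordinates ordination; Mann-Whitney group tests with
    Benjamini-Hochberg correction, median fold changes and age/gender-adjusted
    partial correlations; and a CPAR (Classification based on Predictive
    Association Rules) miner that discretizes taxa into quartile categories and
    induces obese/normal classification rules scored by Laplace accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vegan,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr
Config/testthat/edition: 3
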