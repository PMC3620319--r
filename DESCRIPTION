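Package: methdriver
Title: Driver Gene Identification from Promoter Methylation and Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrates paired promoter methylation (beta-value) and gene
    expression matrices from tumor/normal cohorts to separate driver from
    passenger methylation alterations. Discretizes per-sample methylation
    against a normal reference (Z-score, Z-test, BH adjustment) into a
    ternary hyper/none/hypo matrix, then calls driver loci by three
    conditions: a direction-concordant cis effect on the gene's own
    expression, a permutation-tested excess of downstream differentially
    expressed genes, and hypergeometric enrichment of those downstream
    genes in cancer-associated pathways. Includes validation against known
    cancer-gene lists and a protein-interaction network, subtype analysis
    by Jaccard-distance hierarchical clustering of ternary driver profiles,
    and a synthetic-data generator with planted ground truth for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
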