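Package: clonekin
Title: Clonal, Kinship and Ploidy Analysis of Germplasm SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterising gene bank (germplasm) collections from
    genotyping-by-sequencing SNP data: a reproducible SNP filter cascade
    (genotype depth, positional thinning, missingness, mean-depth percentile
    cap, Hardy-Weinberg exact test, minor allele frequency), method-of-moments
    identity-by-descent estimation for all sample pairs, clonal-duplicate and
    first-degree relationship networks, diploid/triploid classification from
    the bimodal distribution of individual heterozygosity, and PCA-based
    population structure with rank-based group tests. Includes a synthetic
    collection simulator (clone groups, parent-offspring trios, triploids from
    unreduced gametes) with full ground truth for validating every inference
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
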