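Package: genocurate
Title: Genotype-Based Curation of Gene Bank Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating crop gene bank collections from
    genotyping-by-sequencing SNP data: quality filtering of variant calls
    (including a Fisher exact test against disassociated alleles expected
    for inbred material), detection of genetically identical accessions by
    pairwise identity-by-state with automatic threshold discovery,
    passport-versus-genotype misclassification flagging via
    neighbour-joining trees, relationship-matrix PCA and nearest-neighbour
    voting, Nei gene diversity and Weir-Cockerham F_ST statistics, a
    smoothed genome-wide F_ST selection scan, and greedy core-collection
    selection by allele coverage. A Balding-Nichols simulator generates
    synthetic selfing collections with planted duplicates, sweeps and
    mislabels so the whole pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
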