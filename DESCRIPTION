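Package: consangmap
Title: Homozygosity Mapping and Rare Homozygous Variant Prioritisation in
    Consanguineous Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Family-based genetic analysis of consanguineous multiplex
    pedigrees: pedigree kinship and inbreeding coefficients by the standard
    recursion, SNP-array quality control (missingness, Hardy-Weinberg exact
    test, X-homozygosity sex check, robust kinship verification), detection
    of runs of homozygosity and case-shared identical regions with
    control-overlap and gene/GWAS-locus annotation, gene-dropping meiosis
    simulation with recombination to estimate shared autozygosity
    probabilities, exome variant quality filtering and homozygous-candidate
    prioritisation under dual-population frequency rules, exact 2x2 gene-set
    enrichment, and a synthetic family-data generator that plants
    recoverable regions and variants for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
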