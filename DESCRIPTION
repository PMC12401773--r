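Package: rohscape
Title: Runs of Homozygosity, Genomic Inbreeding and ROH Islands
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Sliding-window detection of runs of homozygosity (ROH) in diploid
    SNP genotypes with PLINK-compatible parameters, length-class summaries,
    genomic inbreeding coefficients (F_ROH from ROH content, Wright's F_IS
    from homozygote excess), classification of the origin of autozygosity
    (systematic consanguinity versus drift in small or isolated populations),
    and detection of ROH islands by exact binomial window enrichment with
    reciprocal-overlap matching across populations and metapopulations.
    Includes readers and writers for PLINK bed/bim/fam and ped/map genotype
    files, quality-control filters (missingness, exact Hardy-Weinberg test,
    method-of-moments pihat relatedness), and a pedigree gene-dropping and
    Wright-Fisher simulator that produces genotype datasets with known
    autozygous tracts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
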