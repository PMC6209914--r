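Package: genofp
Title: Genotype Fingerprints for Fast, Privacy-Preserving Genotype Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Summarizes SNP-array genotypes as 'genotype fingerprints': a
    locality-sensitive 4 x L matrix of observed-minus-expected allele counts,
    hashed by dbSNP rsid modulo L. Fingerprints support ultrafast comparison of
    individuals by Spearman correlation for identity checks, detection of close
    relatives, nearest-population assignment with leave-one-out evaluation, and
    population-structure analysis by PCA, while preventing reconstruction of
    individual marker states. Includes readers for direct-to-consumer genotype
    files, rsid panels, allele-frequency tables and VCF extraction; a
    KING-robust kinship estimator as an independent relatedness baseline; and a
    Balding-Nichols population and Mendelian pedigree simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
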