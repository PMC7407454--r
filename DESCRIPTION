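Package: sealpanel
Title: SNP Array Design, Genotype QC, Genomic Inbreeding and Relatedness for
    Pedigreed Wild Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building and analysing custom SNP genotyping arrays in
    non-model diploid species, developed around an Antarctic fur seal
    (Arctocephalus gazella) breeding-colony study design. Covers candidate-SNP
    prioritisation for array submission (design-score, mapping-uniqueness,
    flanking-sequence and spacing rules), post-genotyping sample and locus
    quality control with an exact Hardy-Weinberg test, genomic inbreeding
    estimation (standardised multi-locus heterozygosity, the
    correlation-of-uniting-gametes estimator, a sliding-window
    runs-of-homozygosity caller and F_ROH, and the g2 identity-disequilibrium
    measure), pairwise relatedness (KING-robust kinship, R0/R1,
    method-of-moments Z0/Z1/Z2/PI_HAT) with rule-based relationship
    classification, a binomial conversion-success model, and a pedigree
    gene-dropping simulator that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
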