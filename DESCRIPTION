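Package: amstruct
Title: Assortative Mating and Induced Genetic Structure in Family-Based
    Genotype Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies phenotypic, ancestry-related and polygenic-score
    based assortative mating in family-based genotype cohorts, together
    with the intra-locus (Wright's F) and inter-locus (cross-chromosome
    D^2) correlation structure that such mate choice induces.  Provides
    PLINK 1.x input/output, variant- and sample-level quality control,
    reference-anchored ancestry principal component analysis, polygenic
    scoring with the polygenic transmission disequilibrium test, an
    odd/even-chromosome estimator of score-based assortment, spousal
    correlation statistics with Fisher-z comparisons and power utilities,
    two-locus EM haplotype-frequency estimation with a 1000-iteration
    SNP-resampling comparison of ancestry-informative versus less
    informative markers, and a forward simulator of admixed quartet
    families under configurable ancestry- and trait-based mate choice.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
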