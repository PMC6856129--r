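Package: kinstr
Title: Validation Metrics and Kinship Statistics for Supplementary Forensic STR Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the internal validation of multiplex autosomal STR
    genotyping kits and for the population-genetic and kinship statistics
    that accompany such studies. Provides a panel/locus data model with
    delimited-text readers and writers for genotype, peak, and
    allele-frequency tables; a seeded synthetic electropherogram generator
    (allele frequencies, Hardy-Weinberg genotypes, peak heights with
    heterozygote imbalance, stutter, sizing noise, degradation and
    template-driven dropout); kit performance metrics (profile completeness,
    peak balance, stutter ratios, sizing precision and accuracy, allelic
    ladder coverage, inter-kit concordance); forensic identity and paternity
    statistics (match probability, powers of discrimination and exclusion,
    paternity index, polymorphic information content, combined indices and
    posterior probability of paternity); an exact Hardy-Weinberg test via a
    Guo-Thompson Markov chain with an exhaustive-enumeration oracle; and
    linkage tools (Kosambi map-function conversions, syntenic-pair
    enumeration, EM haplotype-frequency estimation and a permutation
    likelihood-ratio test of linkage disequilibrium).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
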