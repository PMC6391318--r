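Package: founderhap
Title: Founder Haplotype Analysis and Mutation Age Estimation for
    Repeat-Expansion Disorders
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Haplotype-based founder analysis of dominant repeat-expansion
    diseases, built around the marker panel used for Machado-Joseph disease
    (spinocerebellar ataxia type 3). Provides pedigree-based segregation
    phasing and an EM haplotype-frequency estimator for unphased genotypes,
    classification of disease haplotypes against the ancestral Machado and
    Joseph SNP lineages, Hardy-Weinberg and case-control association
    statistics including the linkage-disequilibrium delta statistic,
    minimum-spanning networks over flanking microsatellite haplotypes, and
    founder-age estimation from STR diversity under a stepwise mutation
    model, with a seeded simulator of founder STR evolution and nuclear
    families for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
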