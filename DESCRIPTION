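Package: pgxprofiler
Title: Population Pharmacogenetic Profiling from Phased Cohort Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling pharmacogenetic variation in a genotyped
    cohort. Calls star-allele diplotypes by exact matching of phased
    haplotypes against allele-definition tables, maps diplotypes to
    CPIC-style drug-response phenotypes, quantifies the per-individual and
    cohort-level burden of nontypical drug response across level-A gene/drug
    pairs, screens clinically annotated variants for allele-frequency
    differentiation against a reference population (with Fisher exact tests
    and Benjamini-Hochberg FDR control), estimates pairwise identity-by-descent
    to prune cohorts to unrelated subsets, and simulates phased cohorts with
    known star-allele truth under Hardy-Weinberg equilibrium for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
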