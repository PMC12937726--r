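Package: acemod
Title: Blood ACE Phenotyping and Modifier-Variant Screening
Version: 0.1.0
Authors@R:
    person("FMBA", "Pipeline Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting blood angiotensin I-converting enzyme
    (ACE) measurements in carriers of damaging ACE mutations such as Y215C
    (rs3730025). Provides immunoassay normalization against control pools,
    correction of plasma ACE levels for the ACE I/D genotype, the 5B3/1G12
    monoclonal-antibody binding ratio as a circulating-mutant marker, a
    calibrated filtering cascade over plasma-protein GWAS (pQTL) summary
    statistics producing modifier-variant lists, per-carrier phenotype
    reliability calls (possible false-positive or false-negative blood ACE),
    and a case/control exclusive-variant protective screen with genotype QC,
    allelic association, genomic-inflation estimation, and a recurrence
    window. A synthetic-cohort simulator with Hardy-Weinberg genotypes,
    multiplicative genotype effects, allele-dosage mutant expression and
    log-normal assay noise makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    VariantAnnotation
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
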