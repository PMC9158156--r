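Package: famalz
Title: Family-Based Genetic Analysis of Early-Onset Alzheimer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint genetic work-up of small familial early-onset
    Alzheimer's disease (EOAD) cohorts: pedigree reconstruction from pairwise
    kinship coefficients estimated on common variants, family-based rare-variant
    segregation filtering, gene-panel screening and rule-based variant
    classification, cross-family prioritization of candidate genes, a
    proportional-odds (EOAD > LOAD > control) rare-variant burden test with
    FDR control, polygenic and APOE risk scoring on a population-mean-centred
    log-odds scale with family averaging, subgroup statistics, and a rule-based
    clinical actionability categorization of families. A synthetic-cohort
    generator emulating the statistical structure such an analysis assumes is
    included for validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    vcfR
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
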