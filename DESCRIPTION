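Package: duomics
Title: Concordance Analysis for Dual Sample-Preparation Proteo-Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess whether two sample-preparation routes for
    combined proteomic and metabolomic profiling recover the same biology.
    Provides quality filtering for label-free proteomic intensity and
    targeted metabolomic concentration matrices, blocked linear models with
    empirical-Bayes moderated t-statistics, physico-chemical bias
    diagnostics (GRAVY hydropathy and isoelectric point), set-overlap and
    concordance statistics, permutation-normalised weighted-mean pathway
    enrichment over a mixed gene and metabolite hallmark ontology, and
    enzyme-centred metabolic-imbalance scoring on a bipartite
    metabolite-enzyme reaction network. A synthetic-cohort generator
    produces paired tumour/normal two-method cohorts with known ground
    truth so the full workflow can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
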