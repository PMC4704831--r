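Package: methfunnel
Title: Two-Stage Blood DNA Methylation Biomarker Discovery for
    Alzheimer's Disease and Amnesic Mild Cognitive Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a two-stage blood
    DNA-methylation biomarker discovery analysis for Alzheimer's disease
    (AD) and amnesic mild cognitive impairment (aMCI).  Stage one screens
    Infinium 450K-style beta values genome-wide through a nested candidate
    funnel (pairwise group t-tests, triple intersection, monotone
    disease-progression filter, and annotation filters for accession,
    promoter region and CpG island), then ranks survivors by Spearman
    correlation with MMSE and FAB cognitive scores.  Stage two validates
    the selected candidate on a larger cohort with age-adjusted ANCOVA,
    pairwise contrasts, covariate correlations, cross-platform Pearson
    concordance and an APOE e4 carrier comparison.  A synthetic-data
    module emulates the cohort, array and pyrosequencing structure so the
    whole pipeline is testable end to end, and an in-silico bisulfite
    conversion module supports pyrosequencing assay design checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
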