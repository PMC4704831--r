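# methfunnel

Two-stage blood DNA-methylation biomarker discovery for Alzheimer's
disease (AD) and amnesic mild cognitive impairment (aMCI), as a tested,
reusable R pipeline.

Blood DNA methylation is a practical biomarker substrate for dementia:
sampling is minimally invasive, and site-specific methylation can
distinguish normal controls (NC), aMCI and AD.  `methfunnel` implements
the full discovery analysis such a study runs:

1. **Genome-wide candidate funnel** (discovery subset, 4 subjects per
   group): per-locus unpaired t-tests for each group pair (NC–aMCI,
   NC–AD, aMCI–AD) at α = 0.05 → intersection of the three significant
   sets → strict monotone-progression filter on the group means
   (NC → aMCI → AD, either direction) → annotation filters (RefSeq
   accession present; ≥ 1 transcript in TSS1500/TSS200/5'UTR/1stExon;
   CpG island).
2. **Cognitive-score ranking**: Spearman correlation of survivor betas
   with MMSE and FAB over the scored aMCI/AD subjects; the top candidate
   maximises the weaker |ρ| among loci significant on both scores.
3. **Validation** (full cohort, 30/28/30): per-CpG pyrosequencing
   percent methylation tested by ANCOVA with age as covariate
   (`value ~ age + group`, extra-sum-of-squares F, adjusted means at the
   grand mean age, pairwise contrasts), Spearman correlations with
   MMSE/FAB/age/duration/onset, sex and APOE ε4 carrier t-tests, and
   cross-platform Pearson concordance against the array betas.

A synthetic-data module (`sim_config()`, `simulate_study()`) generates
cohorts, 450K-style manifests, beta matrices with planted monotone
effects, and pyrosequencing replicates with platform noise and optional
orientation inversion, so every stage is testable without any external
data.  An assay module provides in-silico bisulfite conversion, primer
compatibility checks and CpG enumeration for pyrosequencing designs.

## Worked example

The numbered scripts under `analysis/` run the whole two-stage analysis
on one simulated study (`Rscript analysis/01_simulate.R`, then 02–05).
Equivalently, in R:

```r
library(methfunnel)
res <- run_pipeline(run_config(seed = 7, sim = sim_config(n_loci = 2000)))
print(res$funnel)
#> Candidate funnel (alpha = 0.05 )
#>   loci analysed                              2000
#>   CpG loci                                   1981
#>   significant in all 3 comparisons              4
#>   strictly monotone with progression            2
#>   accession present                             2
#>   promoter region (TSS/5'UTR/1stExon)           2
#>   CpG island                                    1
res$candidate
#> [1] "cg00000001"        # the planted candidate locus, recovered
res$validation$summary[, c("cpg", "adj_mean_nc", "adj_mean_amci",
                           "adj_mean_ad", "group_p")]
#>   cpg adj_mean_nc adj_mean_amci adj_mean_ad      group_p
#> 1   1    60.52728      40.18532    44.71231 3.797159e-19
#> 2   2    62.48237      40.99469    43.69644 7.820385e-23
#> 3   3    60.78679      40.18280    43.68606 1.684959e-24
#> 4   4    60.32894      39.99748    42.61814 7.870546e-19
```

Reading the output: of 2,000 simulated loci, the funnel narrows to a
single CpG-island promoter locus; it is the planted score-linked
candidate.  At validation, its age-adjusted mean percent methylation is
~60% in NC versus ~40% (aMCI) and ~44% (AD) — hypomethylation in both
patient groups, aMCI lowest — and the age-adjusted group effect is
overwhelming at every assayed CpG (p < 1e-18).  `cohort_table(res$study$cohort)`
prints the clinical characteristics table (mean ± SEM per group with
ANOVA/chi-square/t-test p-values), and
`res$validation$summary$r_platform` holds the per-CpG array–pyro
Pearson correlations over the 12 discovery subjects.

## Layout

```
R/                    package code: io, stats_core, synthetic_data,
                      screening, correlate, validate, assay, pipeline
analysis/             numbered narrative drivers (01_simulate ... 05_assay)
tests/testthat/       unit, property and acceptance tests with
                      independent formula/brute-force oracles
scripts/acceptance.R  headline-quantity reproduction script
vignettes/            methods vignette: model, parameters, conventions
```
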