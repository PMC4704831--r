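---
title: "A two-stage blood DNA methylation biomarker funnel for AD and aMCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage blood DNA methylation biomarker funnel for AD and aMCI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis this package implements

Blood DNA methylation is an attractive substrate for dementia biomarkers:
it is cheap to sample, and site-specific methylation differences between
normal controls (NC), amnesic mild cognitive impairment (aMCI) and
Alzheimer's disease (AD) patients have been reported at individual CpG
loci.  `methfunnel` implements a two-stage discovery design over Infinium
450K-style data:

1. **Discovery.** On a small age- and sex-matched subset (4 subjects per
   group), every CpG locus' beta values are compared between each pair of
   groups with unpaired pooled-variance t-tests.  Loci significant in
   *all three* pairwise comparisons are intersected, then filtered to
   those whose group mean betas are *strictly monotone* along the
   clinical progression NC → aMCI → AD, then filtered on annotation:
   at least one RefSeq accession, at least one transcript in a
   promoter-proximal group (TSS1500, TSS200, 5'UTR, 1stExon), and CpG
   island membership.  Survivors are ranked by Spearman correlation of
   their betas with MMSE and FAB cognitive scores over the scored
   (aMCI/AD) subjects, and the top candidate is selected.
2. **Validation.** The candidate is re-measured by pyrosequencing
   (4 CpGs of the assay amplicon) on the full cohort (30/28/30) and
   tested with an age-adjusted ANCOVA, pairwise adjusted-mean contrasts,
   covariate correlations, cross-platform concordance, and an APOE ε4
   carrier comparison.

Every stage is an exported function (`run_funnel()`,
`score_correlations()`, `select_top()`, `validate_candidate()`), and
`run_pipeline()` composes them.  Because cohort data of this kind are
not publicly available, the package ships a synthetic-data module that
generates studies with the same statistical structure, so the whole
pipeline is exercised end to end by the test suite.

## Data model

A *beta value* is the methylated fraction of a locus in a sample,
$\beta = M/(M+U+a)$ for methylated/unmethylated intensities $M, U$ and a
stabilising offset $a$ (default 100; `intensities_to_beta()`).  The
generator models measurement noise on the logit scale:

$$\beta_{ij} = \mathrm{logit}^{-1}\!\big(\mathrm{logit}(\mu_{g(j),i}) + \varepsilon_{ij}\big),
\qquad \varepsilon_{ij} \sim N(0, \sigma^2),$$

with $\mu$ the per-locus group mean (a per-locus baseline drawn uniform
on (0.05, 0.95) for null loci).  The logit-normal form keeps betas in
(0, 1) and yields the heteroscedasticity real arrays show near the
boundaries: the beta-scale sd is approximately
$\sigma\,\beta(1-\beta)$, i.e. largest mid-range.  The default
$\sigma = 0.2$ corresponds to a beta-scale sd of about 0.05 at
$\beta = 0.5$, a typical between-replicate spread for a blood 450K CpG.

## Cohort conditions the generator targets

`generate_cohort()` draws three groups of 30/28/30 subjects with these
marginals (mean ± SEM for continuous variables, counts for alleles):

| variable | NC | aMCI | AD |
|---|---|---|---|
| age (years) | 70.5 ± 1.0 | 72.0 ± 0.9 | 71.8 ± 0.9 |
| % female | 60.0 | 53.6 | 53.3 |
| MMSE (0–30) | — | 27.2 ± 0.4 | 18.5 ± 1.0 |
| FAB (0–18) | — | 14.8 ± 0.4 | 12.0 ± 0.7 (23 of 30 scored) |
| duration (months) | — | 26.5 ± 4.4 | 28.2 ± 3.5 |
| APOE ε2/ε3/ε4 alleles | 3/46/11 | 1/43/12 | 0/35/25 |

Ages are truncated normal on [55, 90] with sd recovered as
SEM·√n; durations are lognormal (moment-matched — a right-skewed
positive quantity); onset age is derived as `age − duration/12`, which
reproduces the onset-age means above exactly.  Cognitive scores are
integer, clipped to their scale ranges, and present only for aMCI/AD
subjects — the screening and validation code treats NC scores as
missing by design, which is why correlation sample sizes are 58 at
validation and 8 (MMSE) or fewer (FAB) at discovery.

## The planted candidate and the score link

The first planted locus is the *candidate*: its array profile is
strictly monotone hypomethylation (NC 0.8 > aMCI 0.6 > AD 0.4 by
default), and a configurable fraction (`link_share`, default 0.9) of
each group's within-group MMSE/FAB variance is carried by the subject's
methylation deviation at that locus.  The high default share is what a
discovery-stage rank correlation of |ρ| ≈ 0.9 at n = 8 implies; with a
weaker link the selection stage loses power rapidly.

One modelling point deserves emphasis.  With hypomethylation along
disease progression *and* scores declining along progression, the
pooled aMCI+AD correlation between **array** beta and MMSE is
necessarily positive (both quantities are higher in aMCI).  Negative
methylation–score correlations therefore arise on the
**pyrosequencing** scale, where the group ordering differs (below).
The selection rule ranks absolute correlations, so the sign convention
does not affect candidate recovery; the per-locus signs are reported,
not enforced.

## Two platforms, two profiles

The validation-stage pyrosequencing measurement has its own per-group
means (`pyro_profile`, default NC 60% > AD 45% > aMCI 40%), distinct
from the monotone array profile.  This deliberately emulates a
discovery/validation discordance in group ordering: a small 4-per-group
design can select a locus whose full-cohort ordering differs in the
middle groups, and the generator lets both shapes coexist so the
validation module is tested under realistic conditions (it makes no
ordering assumption — all contrasts are reported).

Each subject carries over a fraction `array_link` (default 0.3) of
their array logit deviation to the pyro scale, plus independent subject
noise (`subject_sd`, default 0.15) and per-CpG platform noise
(`pyro_sd`, default 5 percentage points).  These defaults put the
cross-platform Pearson r near 0.5–0.7 over 12 shared subjects and the
validation-stage MMSE correlation near −0.15 to −0.3 — modest, as
expected when group structure and within-group links pull in opposite
directions.  An `orientation = "inverted"` flag models an assay reading
the complementary strand scale (percent → 100 − percent), which flips
the sign of every cross-platform correlation; it exists because strand
orientation is an easy real-world way to end up with systematically
negative platform concordance.

## Statistical conventions

* **Pairwise screen**: Student's pooled-variance t-test (Welch by
  flag), two-sided, α = 0.05 per test, *unadjusted* — the screen is a
  funnel, not an inference, and the triple-intersection requirement is
  itself a stringent conjunction (its null rate is far below α³ of
  independent tests would suggest, but also far above it when measured
  naively; the test suite measures it empirically).  Optional
  Benjamini–Hochberg within each pair is available behind a flag.
* **Monotone filter**: strict inequalities; exact ties fail (a
  measure-zero event under the noise model, and the conservative
  reading of "progression").
* **Promoter filter**: ANY-transcript semantics — one qualifying
  transcript suffices, so annotations mixing `Body` with `1stExon`
  pass.  TSS1500 and TSS200 both count as TSS-proximal.
* **Spearman p-values**: t approximation by default (what common
  software reports at these n); exact permutation enumeration for
  n ≤ 9, which matters at discovery sample sizes (n = 8 with one score,
  6 with both).
* **ANCOVA**: `value ~ age + group` by least squares; the group test is
  the extra-sum-of-squares F over the age-only model; adjusted means
  are evaluated at the grand mean age; contrasts use the model residual
  variance, unadjusted for multiplicity by default (Bonferroni et al.
  by flag).  The age covariate is mandatory and missing ages are an
  error, not a silent drop.
* **Degenerate inputs**: identical-constant samples give t = 0, p = 1
  (distinct constants t = ±∞, p = 0); an all-constant ANOVA gives
  F = 0, p = 1; a perfect covariate fit gives group F = 0, p = 1.
  These conventions are documented so that pipelines over thousands of
  simulated loci never crash on measure-zero corners, while zero-variance
  *correlations* error (a flagged `NA` in the ranking, never a value).
* **Carrier**: at least one ε4 allele.
* **Assay coordinates**: 0-based, top strand, throughout; bisulfite
  conversion is assumed complete, and the strand asymmetry of the
  chemistry is handled by the explicit orientation flag rather than by
  coordinate arithmetic.

## Design choices that were genuinely open

* **The selection rule.** "Strongest correlation with the lowest p" is
  formalised as: among loci significant on both scores, maximise the
  weaker absolute correlation min(|ρ_MMSE|, |ρ_FAB|); tie-break on the
  larger p, then lexicographic id; fall back to the MMSE-only criterion
  (with a warning) when no locus passes both.  This is the strictest
  reading that is well-defined for arbitrary rankings and reduces to
  the obvious choice when exactly one locus dominates both columns.
* **Triple intersection.** The screen requires significance in all
  three pairwise comparisons.  Weaker Venn readings (e.g. any two) are
  representable via the returned `PairwiseScreen` sets but are not the
  default.
* **Discovery subset.** The first k = 4 subjects per group after age
  sorting, nested inside the full cohort — reproducible and
  approximately age-matched.  A disjoint design can be simulated by
  generating two cohorts with different seeds.
* **Annotation fractions.** The synthetic manifest draws is_cpg with
  probability 0.993 (the CpG fraction of a 485k-locus array), and
  accession/promoter/island indicators at 0.83/0.44/0.19 — the
  conditional pass rates a funnel of this shape exhibits — so that
  stage-to-stage attrition on synthetic data resembles the real
  annotation structure at reduced scale.

## What the generator does not model

Probe-type (Infinium I/II) chemistry differences, batch effects,
cell-composition confounding, sex chromosomes, probe quality filtering,
partial bisulfite conversion, and PCR amplification bias between
methylated and unmethylated templates.  Passing tests on synthetic data
therefore demonstrate the *statistical* correctness and power of the
pipeline under its stated noise model, not robustness to the full
artefact spectrum of real arrays.

## Problem sizes used by the test suite

The suite checks oracle equivalence on ≥ 1000 random instances per
statistical operation (tolerance 1e-8), funnel equivalence against a
brute-force implementation on matrices up to 200 × 12, null calibration
on 100 seeds × 10,000 loci (pairwise rejection rates within binomial
99% bounds of α; split-half agreement of the triple-intersection rate;
KS uniformity of null ANCOVA p-values at the 1% level), planted
recovery (stage-5 sensitivity and candidate selection ≥ 90% over 100
seeds), 50 end-to-end pipeline runs, and byte-identical reruns under a
fixed seed.  These sizes keep the default suite under a couple of
minutes while leaving the binomial bounds tight enough to detect a
miscalibration of a few tenths of a percentage point.

## Known limitations

The screening stage is deliberately faithful to an unadjusted
multiple-testing design: at 450k loci and α = 0.05 the stage-1 set is
dominated by false positives unless effects are large, and the funnel's
specificity comes from the conjunction of filters rather than from any
per-locus error control.  The package reports stage sets and
per-locus statistics so users can apply FDR control (`fdr = TRUE`)
when they want calibrated discovery instead of a reproduction of the
funnel design.
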