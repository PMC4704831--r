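#!/usr/bin/env Rscript
# Stage 1a: the genome-wide candidate funnel on the discovery subset.
#
# Restricts the beta matrix to the 12 age-sorted discovery subjects
# (4 per group), then runs: per-locus pairwise t-tests (NC-aMCI, NC-AD,
# aMCI-AD) at alpha 0.05 -> triple intersection -> strict monotone
# progression filter -> accession / promoter / CpG-island annotation
# filters.  Writes the stage sets and counts to results/funnel.json.

library(methfunnel)

dat <- "results/data"
cohort <- read_sample_sheet(file.path(dat, "samples.csv"))
manifest <- read_manifest(file.path(dat, "manifest.csv"))
beta <- read_beta_matrix(file.path(dat, "beta.tsv"))
disc_ids <- readLines(file.path(dat, "discovery_ids.txt"))

disc <- cohort[match(disc_ids, cohort$sample_id), ]
funnel <- run_funnel(beta[, disc_ids], disc, manifest, alpha = 0.05)
print(funnel)

jsonlite::write_json(
  list(alpha = funnel$alpha, counts = as.list(funnel$counts),
       stage5_island = funnel$stage5_island),
  "results/funnel.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("\nSurvivors of all five stages:",
    paste(funnel$stage5_island, collapse = ", "), "\n")
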