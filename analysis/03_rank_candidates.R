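#!/usr/bin/env Rscript
# Stage 1b: rank funnel survivors by cognitive-score correlation.
#
# Spearman correlation of each surviving locus' discovery-subset betas
# with MMSE and FAB over the scored aMCI/AD subjects (NC has no scores),
# then selection of the top candidate: significant on both scores with
# the strongest weaker correlation, falling back to the MMSE-only rule.

library(methfunnel)

dat <- "results/data"
cohort <- read_sample_sheet(file.path(dat, "samples.csv"))
beta <- read_beta_matrix(file.path(dat, "beta.tsv"))
disc_ids <- readLines(file.path(dat, "discovery_ids.txt"))
survivors <- jsonlite::read_json("results/funnel.json",
                                 simplifyVector = TRUE)$stage5_island

disc <- cohort[match(disc_ids, cohort$sample_id), ]
ranking <- score_correlations(beta[, disc_ids], disc, survivors)
print(ranking)
write.table(ranking, "results/ranking.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

candidate <- select_top(ranking, alpha = 0.05)
cat("\nSelected candidate:", candidate,
    "\nRationale:", attr(candidate, "rationale"), "\n")
truth <- read.csv(file.path(dat, "planted_truth.csv"))
cat("Planted candidate:", truth$locus_id[1],
    if (identical(as.character(candidate), truth$locus_id[1]))
      "(recovered)\n" else "(NOT recovered)\n")
writeLines(as.character(candidate), "results/candidate.txt")
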