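#!/usr/bin/env Rscript
# In-silico pyrosequencing assay check.
#
# Builds a synthetic promoter-region template shaped like the study
# assay (five CpGs, four of them downstream of the sequencing primer),
# bisulfite-converts it, and verifies the assay's primer set against
# the converted top strand: composition (no C outside CpG), exact
# occurrence, amplicon coordinates, and the assayable CpG set.

library(methfunnel)

forward <- "GTTTAAATTGGTGGTAGTTTAAAGT"
reverse <- "TCCACCTCCCAATTCTTAATAAAATC"     # biotinylated in the wet assay
seqprimer <- "TTTGGGAGGGAATAGTAAAA"

# synthetic template (not the real promoter sequence): primer sites
# joined by spacers carrying one upstream CpG and four downstream CpGs
reference <- paste0(
  forward,
  "ATTACAGGTA", "ACGA",                      # converting C; CpG upstream of assay
  seqprimer,
  "ATCGATTACGGATTTACGATTACGTT", "AGAT",      # the four assayed CpGs
  reverse_complement(reverse), "TTTT")

converted <- bisulfite_convert(reference)    # fully unmethylated template
design <- assay_design(forward, reverse, seqprimer, target_cpg_count = 4)
report <- check_primer_compatibility(design, converted, reference = reference)
cat("Primer compatibility on the converted synthetic template:\n")
print(report)

amp <- c(report$amplicon[["start"]], report$amplicon[["end"]])
cpgs <- enumerate_cpgs(reference, amp, seqprimer)
cat(sprintf("\nCpGs in the reference: %d; assayable downstream of the sequencing primer: %d (offsets %s)\n",
            length(find_cpg_sites(reference)), length(cpgs),
            paste(cpgs, collapse = ", ")))

# percent methylation from simulated read counts at a 40% methylated CpG
set.seed(1)
counts <- cbind(methylated = rbinom(4, 500, 0.4), total = 500)
cat("Percent methylation from 500-read counts at p = 0.40:",
    paste(sprintf("%.1f", quantify_methylation(counts)), collapse = ", "), "\n")

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(
  list(compatible = report$compatible,
       amplicon = as.list(report$amplicon),
       assayable_cpg_offsets = cpgs),
  "results/assay_report.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
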