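# Shared constants and small internal helpers.

GROUP_LEVELS  <- c("NC", "aMCI", "AD")
SEX_LEVELS    <- c("F", "M")
APOE_ALLELES  <- c("e2", "e3", "e4")
REFGENE_GROUPS <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")
PROMOTER_GROUPS <- c("TSS1500", "TSS200", "5'UTR", "1stExon")
ISLAND_RELATIONS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                      "OpenSea")

SAMPLE_SHEET_COLS <- c("sample_id", "group", "age", "sex", "mmse", "fab",
                       "apoe_a1", "apoe_a2", "duration_months", "onset_age")
MANIFEST_COLS <- c("target_id", "is_cpg", "gene", "accession",
                   "refgene_group", "island_relation", "chr", "pos")
PYRO_COLS <- c("sample_id", "cpg_index", "percent_methylation")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mf <- function(...) stop(sprintf(...), call. = FALSE)

# Derive a sub-stream seed from a master seed; kept inside 32-bit range so
# set.seed() accepts it for any small master seed.
mix_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1013L + as.numeric(stream) * 7L) %% 2147483647)
}

is_missing_num <- function(x) is.na(x)

# logit / inverse-logit on the beta scale, used by the noise model
logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
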