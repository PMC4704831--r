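# Readers and writers for the analysis' file formats:
#   * sample sheet  - CSV, one row per subject (clinical covariates)
#   * beta matrix   - TSV, loci x samples methylation fractions
#   * manifest      - CSV, 450K-style locus annotation with
#                     semicolon-separated per-transcript fields
#   * pyro table    - CSV, per-subject per-CpG percent methylation
#   * assay FASTA   - plain DNA sequences for the assay module
#
# All readers validate against the type invariants and refuse to coerce
# silently; missing values are empty cells on disk and NA in memory.

#' Read a clinical sample sheet
#'
#' Parses a CSV sample sheet with one row per subject.  The expected
#' header is `sample_id,group,age,sex,mmse,fab,apoe_a1,apoe_a2,
#' duration_months,onset_age`.  Cognitive scores (MMSE 0-30, FAB 0-18),
#' disease duration and onset age may be missing (empty cells) — they are
#' administered to aMCI and AD patients only, so NC rows are typically
#' blank there.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` with typed columns: `group` and `sex` as factors
#'   with levels `NC, aMCI, AD` and `F, M`; `mmse`/`fab` integer; APOE
#'   alleles as character (`e2`, `e3`, `e4`).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_sample_sheet(generate_cohort(sim_config(seed = 1)), f)
#' head(read_sample_sheet(f))
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_mf("sample sheet not found: %s", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = "")
  if (!identical(names(raw), SAMPLE_SHEET_COLS))
    stop_mf("sample sheet header must be exactly: %s",
            paste(SAMPLE_SHEET_COLS, collapse = ","))
  n <- nrow(raw)
  bad <- function(i, field, why)
    stop_mf("sample sheet row %d, field '%s': %s", i, field, why)

  num_field <- function(col, lo = -Inf, hi = Inf, integer = FALSE) {
    out <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      v <- raw[[col]][i]
      if (is.na(v)) next
      x <- suppressWarnings(as.numeric(v))
      if (is.na(x)) bad(i, col, sprintf("not a number: '%s'", v))
      if (x < lo || x > hi)
        bad(i, col, sprintf("value %s outside [%s, %s]", v, lo, hi))
      if (integer && x != round(x)) bad(i, col, "not an integer")
      out[i] <- x
    }
    out
  }
  enum_field <- function(col, levels, allow_na = FALSE) {
    v <- raw[[col]]
    for (i in seq_len(n)) {
      if (is.na(v[i])) {
        if (!allow_na) bad(i, col, "missing value not allowed")
      } else if (!v[i] %in% levels) {
        bad(i, col, sprintf("'%s' not one of {%s}", v[i],
                            paste(levels, collapse = ", ")))
      }
    }
    v
  }

  sample_id <- raw$sample_id
  if (anyNA(sample_id)) stop_mf("sample sheet has a missing sample_id")
  if (anyDuplicated(sample_id))
    stop_mf("duplicate sample_id: %s",
            sample_id[duplicated(sample_id)][1])

  out <- data.frame(
    sample_id = sample_id,
    group = factor(enum_field("group", GROUP_LEVELS), levels = GROUP_LEVELS),
    age = num_field("age"),
    sex = factor(enum_field("sex", SEX_LEVELS), levels = SEX_LEVELS),
    mmse = as.integer(num_field("mmse", 0, 30, integer = TRUE)),
    fab = as.integer(num_field("fab", 0, 18, integer = TRUE)),
    apoe_a1 = enum_field("apoe_a1", APOE_ALLELES),
    apoe_a2 = enum_field("apoe_a2", APOE_ALLELES),
    duration_months = num_field("duration_months", 0),
    onset_age = num_field("onset_age"),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$age)) bad(which(is.na(out$age))[1], "age", "missing value")
  out
}

#' Write a clinical sample sheet
#'
#' Inverse of [read_sample_sheet()]; missing values become empty cells.
#'
#' @param cohort Data frame as returned by [read_sample_sheet()] or
#'   [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(cohort, path) {
  stopifnot(all(SAMPLE_SHEET_COLS %in% names(cohort)))
  write.csv(cohort[SAMPLE_SHEET_COLS], path, row.names = FALSE, na = "",
            quote = FALSE)
  invisible(path)
}

#' Read a beta-value matrix
#'
#' Parses a TSV whose first column holds locus identifiers and remaining
#' columns one sample each.  Every value must be a methylation fraction in
#' \[0, 1\] or blank (missing).  Ragged rows, duplicate locus or sample
#' ids, and out-of-range values are rejected with informative errors.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (loci x samples) with locus ids as rownames
#'   and sample ids as colnames; missing values are `NA`.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) stop_mf("beta matrix not found: %s", path)
  raw <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", fill = FALSE,
                    na.strings = "", quote = "", comment.char = "")
  if (ncol(raw) < 2) stop_mf("beta matrix needs a locus column and >= 1 sample")
  if (names(raw)[1] != "locus_id")
    stop_mf("beta matrix first column must be 'locus_id', got '%s'",
            names(raw)[1])
  loci <- raw[[1]]
  samples <- names(raw)[-1]
  if (anyDuplicated(loci))
    stop_mf("duplicate locus_id: %s", loci[duplicated(loci)][1])
  if (anyDuplicated(samples))
    stop_mf("duplicate sample id: %s", samples[duplicated(samples)][1])
  vals <- matrix(NA_real_, nrow(raw), length(samples),
                 dimnames = list(loci, samples))
  for (j in seq_along(samples)) {
    v <- raw[[j + 1]]
    x <- suppressWarnings(as.numeric(v))
    conv_fail <- !is.na(v) & is.na(x)
    if (any(conv_fail))
      stop_mf("beta matrix: non-numeric value '%s' at locus %s, sample %s",
              v[conv_fail][1], loci[conv_fail][1], samples[j])
    out_rng <- !is.na(x) & (x < 0 | x > 1)
    if (any(out_rng))
      stop_mf("beta value %s outside [0,1] at locus %s, sample %s",
              v[out_rng][1], loci[out_rng][1], samples[j])
    vals[, j] <- x
  }
  vals
}

#' Write a beta-value matrix
#'
#' Inverse of [read_beta_matrix()]. Values are printed with 17 significant
#' digits so a write/read round trip preserves doubles exactly.
#'
#' @param beta Numeric matrix with locus rownames and sample colnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  txt <- matrix(sprintf("%.17g", beta), nrow(beta))
  txt[is.na(beta)] <- ""
  lines <- c(paste(c("locus_id", colnames(beta)), collapse = "\t"),
             paste(rownames(beta), apply(txt, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a locus annotation manifest
#'
#' Parses a CSV in the Illumina-manifest dialect where the gene,
#' accession and RefGene-group columns carry semicolon-separated
#' per-transcript lists (e.g.
#' `NM_152299;NM_033200;NM_152299;NM_014551;NM_014551`).  The three lists
#' must be length-aligned within every row; empty cells yield empty lists
#' (an intergenic locus).  An empty island-relation cell is normalised to
#' `OpenSea`.
#'
#' @param path Path to a CSV with header
#'   `target_id,is_cpg,gene,accession,refgene_group,island_relation,chr,pos`.
#' @return A `data.frame` with one row per locus: `target_id`, logical
#'   `is_cpg`, list-columns `gene_names`, `accessions`, `refgene_groups`,
#'   factor `island_relation`, `chromosome`, integer `position`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_mf("manifest not found: %s", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = NULL)
  if (!identical(names(raw), MANIFEST_COLS))
    stop_mf("manifest header must be exactly: %s",
            paste(MANIFEST_COLS, collapse = ","))
  if (anyDuplicated(raw$target_id))
    stop_mf("duplicate target_id: %s", raw$target_id[duplicated(raw$target_id)][1])

  split_semi <- function(x) {
    out <- strsplit(x, ";", fixed = TRUE)
    out[x == ""] <- list(character(0))
    out
  }
  genes <- split_semi(raw$gene)
  accs  <- split_semi(raw$accession)
  grps  <- split_semi(raw$refgene_group)
  for (i in seq_len(nrow(raw))) {
    ln <- c(length(genes[[i]]), length(accs[[i]]), length(grps[[i]]))
    if (length(unique(ln)) != 1)
      stop_mf("manifest row %s: semicolon lists not aligned (gene %d, accession %d, group %d)",
              raw$target_id[i], ln[1], ln[2], ln[3])
    bad <- setdiff(grps[[i]], REFGENE_GROUPS)
    if (length(bad))
      stop_mf("manifest row %s: unknown RefGene group '%s'",
              raw$target_id[i], bad[1])
  }
  isl <- raw$island_relation
  isl[isl == ""] <- "OpenSea"
  if (!all(isl %in% ISLAND_RELATIONS))
    stop_mf("unknown island relation '%s' at %s",
            setdiff(isl, ISLAND_RELATIONS)[1],
            raw$target_id[!isl %in% ISLAND_RELATIONS][1])
  cpg <- raw$is_cpg
  if (!all(cpg %in% c("TRUE", "FALSE")))
    stop_mf("is_cpg must be TRUE/FALSE; got '%s'",
            setdiff(cpg, c("TRUE", "FALSE"))[1])
  pos <- suppressWarnings(as.integer(raw$pos))
  if (anyNA(pos) || any(pos < 1))
    stop_mf("manifest pos must be a positive integer (1-based)")

  out <- data.frame(target_id = raw$target_id,
                    is_cpg = cpg == "TRUE",
                    island_relation = factor(isl, levels = ISLAND_RELATIONS),
                    chromosome = raw$chr,
                    position = pos,
                    stringsAsFactors = FALSE)
  out$gene_names <- genes
  out$accessions <- accs
  out$refgene_groups <- grps
  out
}

#' Write a locus annotation manifest
#'
#' Inverse of [read_manifest()]; list-columns are re-joined with
#' semicolons.
#'
#' @param manifest Data frame as returned by [read_manifest()] or
#'   [generate_manifest()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  join <- function(col) vapply(manifest[[col]], paste, "", collapse = ";")
  out <- data.frame(target_id = manifest$target_id,
                    is_cpg = manifest$is_cpg,
                    gene = join("gene_names"),
                    accession = join("accessions"),
                    refgene_group = join("refgene_groups"),
                    island_relation = as.character(manifest$island_relation),
                    chr = manifest$chromosome,
                    pos = manifest$position)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pyrosequencing percent-methylation table
#'
#' CSV with header `sample_id,cpg_index,percent_methylation`; one row per
#' subject and assayed CpG, percent in \[0, 100\].
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` with character `sample_id`, integer `cpg_index`
#'   and numeric `percent_methylation`.
#' @export
read_pyro_table <- function(path) {
  if (!file.exists(path)) stop_mf("pyro table not found: %s", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), PYRO_COLS))
    stop_mf("pyro table header must be exactly: %s",
            paste(PYRO_COLS, collapse = ","))
  idx <- suppressWarnings(as.integer(raw$cpg_index))
  if (anyNA(idx) || any(idx < 1))
    stop_mf("cpg_index must be a positive integer")
  pct <- suppressWarnings(as.numeric(raw$percent_methylation))
  if (anyNA(pct))
    stop_mf("non-numeric percent_methylation at row %d", which(is.na(pct))[1])
  if (any(pct < 0 | pct > 100))
    stop_mf("percent_methylation %s outside [0,100] (sample %s, CpG %d)",
            pct[pct < 0 | pct > 100][1],
            raw$sample_id[pct < 0 | pct > 100][1],
            idx[pct < 0 | pct > 100][1])
  data.frame(sample_id = raw$sample_id, cpg_index = idx,
             percent_methylation = pct, stringsAsFactors = FALSE)
}

#' Write a pyrosequencing percent-methylation table
#'
#' Inverse of [read_pyro_table()].
#'
#' @param pyro Data frame with columns `sample_id`, `cpg_index`,
#'   `percent_methylation`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pyro_table <- function(pyro, path) {
  stopifnot(identical(names(pyro)[1:3], PYRO_COLS))
  out <- pyro[PYRO_COLS]
  out$percent_methylation <- sprintf("%.17g", out$percent_methylation)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read assay template sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning plain
#' upper-case character sequences for the assay module.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of DNA sequences.
#' @export
read_assay_fasta <- function(path) {
  if (!file.exists(path)) stop_mf("FASTA not found: %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(seqs)), names(seqs))
}
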