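# In-silico bisulfite conversion and pyrosequencing assay utilities.
#
# Bisulfite treatment converts unmethylated cytosines to uracil (read as
# thymine after PCR) while methylated cytosines are protected.  On the
# top strand this means every C outside the methylation map becomes T;
# A, G and T never change.  PCR primers for a converted template must
# therefore avoid C except at CpG sites (whose conversion state is
# unknown), which is the composition check applied to assay designs.
# Coordinates are 0-based top-strand offsets throughout.

dna_check <- function(seq, what = "sequence") {
  if (length(seq) != 1 || !nzchar(seq)) stop_mf("%s must be a single non-empty string", what)
  s <- toupper(seq)
  if (grepl("[^ACGT]", s)) stop_mf("%s contains non-ACGT characters", what)
  s
}

#' Reverse complement of a DNA sequence
#'
#' @param seq DNA string over A, C, G, T.
#' @return The reverse-complemented string.
#' @export
#' @examples
#' reverse_complement("TCCACCTCCCAATTCTTAATAAAATC")
reverse_complement <- function(seq) {
  s <- dna_check(seq)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

#' CpG cytosine positions in a sequence
#'
#' @param seq DNA string.
#' @return Integer vector of 0-based positions of the C of every CpG
#'   dinucleotide.
#' @export
find_cpg_sites <- function(seq) {
  s <- dna_check(seq)
  m <- gregexpr("CG", s, fixed = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L
}

#' In-silico bisulfite conversion (top strand)
#'
#' Converts every cytosine that is not in the methylation map to
#' thymine; methylated cytosines are retained; all other bases are
#' unchanged, so the output has the input's length.  Conversion is
#' assumed complete (no partial-conversion model).
#'
#' @param sequence DNA string over A, C, G, T.
#' @param methylation Integer vector of 0-based positions of methylated
#'   CpG cytosines; every position must hold a C followed by G in
#'   `sequence`.
#' @return The converted DNA string.
#' @export
#' @examples
#' bisulfite_convert("ACGT", methylation = 1L)   # "ACGT" (protected)
#' bisulfite_convert("ACGT")                     # "ATGT"
bisulfite_convert <- function(sequence, methylation = integer(0)) {
  s <- dna_check(sequence)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  methylation <- as.integer(methylation)
  if (length(methylation)) {
    if (any(methylation < 0 | methylation > n - 1))
      stop_mf("methylation position %d outside the sequence", methylation[1])
    is_cpg_c <- chars[methylation + 1] == "C" &
      c(chars, "")[methylation + 2] == "G"
    if (!all(is_cpg_c))
      stop_mf("methylation position %d is not a CpG cytosine",
              methylation[!is_cpg_c][1])
  }
  convert <- chars == "C"
  convert[methylation + 1] <- FALSE
  chars[convert] <- "T"
  paste(chars, collapse = "")
}

#' Pyrosequencing assay design
#'
#' Container for the three assay primers.  The reverse primer is the
#' biotinylated one (its strand is captured for sequencing); the
#' sequencing primer anneals inside the amplicon just upstream of the
#' quantified CpGs.
#'
#' @param forward_primer,reverse_primer,sequencing_primer DNA strings.
#' @param target_cpg_count Number of CpGs the assay quantifies.
#' @return An `mf_assay_design` list.
#' @export
assay_design <- function(forward_primer, reverse_primer, sequencing_primer,
                         target_cpg_count = 4) {
  structure(list(forward_primer = dna_check(forward_primer, "forward primer"),
                 reverse_primer = dna_check(reverse_primer, "reverse primer"),
                 sequencing_primer = dna_check(sequencing_primer, "sequencing primer"),
                 target_cpg_count = as.integer(target_cpg_count)),
            class = "mf_assay_design")
}

#' Converted-template composition check for one primer
#'
#' A primer that must match a fully bisulfite-converted top strand can
#' contain C only where the template retains one, i.e. at a (possibly
#' methylated) CpG.  The necessary composition condition checked here:
#' every C in the primer is immediately followed by G.  A primer with a
#' C at a non-CpG position can never match any fully converted template.
#'
#' @param primer DNA string.
#' @return List: `ok` (logical) and `bad_positions` (0-based positions
#'   of C not followed by G).
#' @export
check_converted_composition <- function(primer) {
  s <- dna_check(primer, "primer")
  chars <- strsplit(s, "")[[1]]
  cs <- which(chars == "C")
  bad <- cs[c(chars, "")[cs + 1] != "G"]
  list(ok = length(bad) == 0, bad_positions = as.integer(bad - 1L))
}

#' Check primer compatibility against a converted template
#'
#' Verifies that the forward and sequencing primers occur as exact
#' substrings of the converted top strand and that the reverse primer
#' occurs via its reverse complement; reports the amplicon coordinates
#' (forward primer start to reverse-primer-site end, 0-based inclusive)
#' when both outer primers are found.  Any primer whose composition is
#' incompatible with a fully converted template (a C not followed by G)
#' raises an error — such a design cannot work regardless of template.
#' Primers overlapping a CpG position are flagged with a warning field
#' (conversion-state ambiguity under the primer); CpG positions are
#' taken from `reference` when supplied, otherwise from retained CG
#' dinucleotides in the converted strand.
#'
#' @param design An [assay_design()].
#' @param converted_top_strand Converted top-strand DNA string.
#' @param reference Optional unconverted reference (same coordinates) to
#'   locate CpG sites exactly.
#' @return An `mf_assay_report` list: per-primer `found`/`start` (0-based),
#'   `covers_cpg`, plus `amplicon` (c(start, end) or NULL) and
#'   `compatible`.
#' @export
check_primer_compatibility <- function(design, converted_top_strand,
                                       reference = NULL) {
  stopifnot(inherits(design, "mf_assay_design"))
  tmpl <- dna_check(converted_top_strand, "converted template")
  cpgs <- if (is.null(reference)) find_cpg_sites(tmpl)
          else find_cpg_sites(dna_check(reference, "reference"))
  probe <- list(forward = design$forward_primer,
                sequencing = design$sequencing_primer,
                reverse_site = reverse_complement(design$reverse_primer))
  out <- list()
  for (nm in names(probe)) {
    p <- probe[[nm]]
    comp <- check_converted_composition(p)
    if (!comp$ok)
      stop_mf("%s primer has a C at non-CpG position %d; incompatible with a fully converted template",
              nm, comp$bad_positions[1])
    hit <- regexpr(p, tmpl, fixed = TRUE)
    found <- hit != -1
    start <- if (found) as.integer(hit) - 1L else NA_integer_
    covers <- found && any(cpgs >= start & cpgs <= start + nchar(p) - 1)
    out[[nm]] <- list(found = found, start = start, covers_cpg = covers)
  }
  amplicon <- NULL
  if (out$forward$found && out$reverse_site$found) {
    amplicon <- c(start = out$forward$start,
                  end = out$reverse_site$start +
                    nchar(probe$reverse_site) - 1L)
  }
  structure(c(out, list(amplicon = amplicon,
                        compatible = all(vapply(out, `[[`, TRUE, "found")))),
            class = "mf_assay_report")
}

#' @export
print.mf_assay_report <- function(x, ...) {
  for (nm in c("forward", "sequencing", "reverse_site"))
    cat(sprintf("  %-13s found = %-5s start = %-6s covers CpG = %s\n", nm,
                x[[nm]]$found, x[[nm]]$start, x[[nm]]$covers_cpg))
  if (!is.null(x$amplicon))
    cat(sprintf("  amplicon: [%d, %d]\n", x$amplicon[1], x$amplicon[2]))
  cat("  compatible:", x$compatible, "\n")
  invisible(x)
}

#' Enumerate assayable CpGs downstream of the sequencing primer
#'
#' Locates the sequencing primer inside the amplicon by matching it
#' against the bisulfite space of the reference (at CpG cytosines the
#' template may read C or T depending on methylation, so both are
#' accepted there) and returns the reference CpG positions strictly
#' downstream of the primer's 3' end and inside the amplicon.
#'
#' @param sequence Unconverted reference top-strand DNA string.
#' @param amplicon `c(start, end)`, 0-based inclusive bounds.
#' @param sequencing_primer DNA string (bisulfite space).
#' @return Integer vector of 0-based CpG cytosine offsets on the
#'   reference.
#' @export
enumerate_cpgs <- function(sequence, amplicon, sequencing_primer) {
  s <- dna_check(sequence)
  p <- dna_check(sequencing_primer, "sequencing primer")
  if (length(amplicon) != 2 || amplicon[1] > amplicon[2] ||
      amplicon[1] < 0 || amplicon[2] > nchar(s) - 1)
    stop_mf("amplicon must be c(start, end), 0-based, inside the sequence")
  cpgs_all <- find_cpg_sites(s)
  conv <- strsplit(bisulfite_convert(s), "")[[1]]  # fully converted (all C->T)
  at_cpg <- logical(nchar(s)); at_cpg[cpgs_all + 1] <- TRUE
  pc <- strsplit(p, "")[[1]]
  np <- length(pc)
  if (amplicon[2] - np + 1 < amplicon[1])
    stop_mf("sequencing primer not found inside the amplicon")
  starts0 <- amplicon[1]:(amplicon[2] - np + 1)
  hit <- NA_integer_
  for (st in starts0) {
    win <- seq.int(st + 1, st + np)
    ok <- (pc == conv[win]) | (at_cpg[win] & pc %in% c("C", "T"))
    if (all(ok)) { hit <- st; break }
  }
  if (is.na(hit))
    stop_mf("sequencing primer not found inside the amplicon")
  three_prime <- hit + np - 1L
  cpgs_all[cpgs_all > three_prime & cpgs_all + 1 <= amplicon[2]]
}

#' Percent methylation from per-CpG read counts
#'
#' The pyrosequencing quantification: `100 * methylated / total` per
#' CpG.
#'
#' @param read_counts Two-column matrix or data frame: methylated count,
#'   total count (one row per CpG); totals must be >= 1.
#' @return Numeric vector of percents in \[0, 100\].
#' @export
#' @examples
#' quantify_methylation(cbind(methylated = c(7, 0), total = c(10, 50)))
quantify_methylation <- function(read_counts) {
  m <- as.matrix(read_counts)
  if (ncol(m) != 2) stop_mf("read_counts needs 2 columns: methylated, total")
  if (any(m[, 2] < 1)) stop_mf("total read count must be >= 1 for every CpG")
  if (any(m[, 1] < 0) || any(m[, 1] > m[, 2]))
    stop_mf("methylated counts must lie in [0, total]")
  unname(100 * m[, 1] / m[, 2])
}
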