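# The genome-wide candidate funnel: pairwise group t-tests on every
# locus, triple intersection of the significant sets, a strict monotone
# disease-progression filter on the group means, and three annotation
# filters (accession present, promoter region, CpG island).  Stage sets
# are nested by construction:
#   stage5_island <= stage4_promoter <= stage3_accession
#     <= stage2_monotone <= stage1_common <= cpg_set <= all loci.

GROUP_PAIRS <- list(c("NC", "aMCI"), c("NC", "AD"), c("aMCI", "AD"))
PAIR_LABELS <- vapply(GROUP_PAIRS, paste, "", collapse = "-")

# Vectorised per-row pooled-variance t-test between two column sets.
# Rows with any missing value in either column set get NA (skipped).
row_t_test <- function(X, idx1, idx2) {
  X1 <- X[, idx1, drop = FALSE]
  X2 <- X[, idx2, drop = FALSE]
  n1 <- length(idx1); n2 <- length(idx2)
  skip <- rowSums(is.na(X1)) > 0 | rowSums(is.na(X2)) > 0
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tt <- (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- 2 * pt(-abs(tt), df)
  p[!is.na(tt) & is.infinite(tt)] <- 0          # zero pooled variance, means differ
  p[!is.na(tt) & is.nan(tt)] <- 1               # all values identical
  tt[is.nan(tt)] <- 0
  p[skip] <- NA_real_
  list(t = tt, p = p, df = df, skipped = skip)
}

group_columns <- function(beta, cohort) {
  if (!all(colnames(beta) %in% cohort$sample_id))
    stop_mf("beta matrix sample %s not present in the cohort",
            setdiff(colnames(beta), cohort$sample_id)[1])
  grp <- cohort$group[match(colnames(beta), cohort$sample_id)]
  lapply(setNames(GROUP_LEVELS, GROUP_LEVELS),
         function(g) which(grp == g))
}

#' Pairwise two-group significance screen
#'
#' For every locus and each of the three group pairs (NC-aMCI, NC-AD,
#' aMCI-AD) runs an unpaired pooled-variance t-test on the beta values;
#' a locus enters a pair's significant set iff its two-sided p < alpha.
#' Loci with any missing value in a pair's groups are skipped for that
#' pair and recorded in the `skipped` field.
#'
#' @param beta Beta matrix (loci x samples).
#' @param cohort Sample sheet covering every beta column.
#' @param alpha Per-test significance threshold (unadjusted).
#' @param fdr Apply Benjamini-Hochberg within each pair before
#'   thresholding (off by default, mirroring an unadjusted screen).
#' @return An `mf_pairwise_screen`: `sets` (list of three locus-id
#'   vectors named `NC-aMCI`, `NC-AD`, `aMCI-AD`), `p_values` (loci x 3
#'   matrix), `venn_counts` (sizes of the 7 intersection regions),
#'   `alpha`, `skipped`.
#' @export
pairwise_screen <- function(beta, cohort, alpha = 0.05, fdr = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop_mf("alpha must lie in (0, 1)")
  cols <- group_columns(beta, cohort)
  for (g in GROUP_LEVELS)
    if (length(cols[[g]]) < 2)
      stop_mf("group %s has %d usable samples; need >= 2", g, length(cols[[g]]))
  pmat <- matrix(NA_real_, nrow(beta), 3,
                 dimnames = list(rownames(beta), PAIR_LABELS))
  skipped <- matrix(FALSE, nrow(beta), 3,
                    dimnames = list(rownames(beta), PAIR_LABELS))
  for (k in seq_along(GROUP_PAIRS)) {
    pr <- GROUP_PAIRS[[k]]
    res <- row_t_test(beta, cols[[pr[1]]], cols[[pr[2]]])
    p <- res$p
    if (fdr) p <- p.adjust(p, method = "BH")
    pmat[, k] <- p
    skipped[, k] <- res$skipped
  }
  sets <- lapply(seq_len(3), function(k) {
    rownames(beta)[!is.na(pmat[, k]) & pmat[, k] < alpha]
  })
  names(sets) <- PAIR_LABELS
  structure(list(sets = sets, p_values = pmat,
                 venn_counts = venn_counts(sets), alpha = alpha,
                 skipped = skipped),
            class = "mf_pairwise_screen")
}

# Sizes of the 7 exclusive regions of a 3-set Venn diagram.
venn_counts <- function(sets) {
  stopifnot(length(sets) == 3)
  u <- unique(unlist(sets))
  inA <- u %in% sets[[1]]; inB <- u %in% sets[[2]]; inC <- u %in% sets[[3]]
  lab <- names(sets)
  c(setNames(sum(inA & !inB & !inC), paste(lab[1], "only")),
    setNames(sum(!inA & inB & !inC), paste(lab[2], "only")),
    setNames(sum(!inA & !inB & inC), paste(lab[3], "only")),
    setNames(sum(inA & inB & !inC), paste(lab[1], "&", lab[2])),
    setNames(sum(inA & !inB & inC), paste(lab[1], "&", lab[3])),
    setNames(sum(!inA & inB & inC), paste(lab[2], "&", lab[3])),
    setNames(sum(inA & inB & inC), "all three"))
}

#' @export
print.mf_pairwise_screen <- function(x, ...) {
  cat("Pairwise significance screen (alpha =", x$alpha, ")\n")
  for (nm in names(x$sets))
    cat(sprintf("  %-10s %6d significant loci\n", nm, length(x$sets[[nm]])))
  cat("  triple intersection:", x$venn_counts[["all three"]], "\n")
  invisible(x)
}

#' Triple intersection of the pairwise significant sets
#'
#' Loci showing a significant two-group difference in all three pairwise
#' comparisons simultaneously.
#'
#' @param screen An `mf_pairwise_screen`.
#' @return Character vector of locus ids.
#' @export
intersect_common <- function(screen) {
  stopifnot(inherits(screen, "mf_pairwise_screen"))
  Reduce(intersect, screen$sets)
}

#' Monotone disease-progression filter
#'
#' Keeps a locus iff its group mean betas are strictly monotone along
#' the clinical progression NC -> aMCI -> AD, in either direction;
#' exactly tied means fail (a conservative reading, and a measure-zero
#' event under continuous noise).
#'
#' @param beta Beta matrix.
#' @param cohort Sample sheet covering the beta columns.
#' @param loci Locus ids to test (subset of rownames(beta)).
#' @return Data frame with columns `locus_id` and `direction`
#'   (`"decreasing"` = hypomethylation with disease, or `"increasing"`),
#'   one row per kept locus.
#' @export
monotone_filter <- function(beta, cohort, loci) {
  if (!all(loci %in% rownames(beta)))
    stop_mf("locus %s not in the beta matrix", setdiff(loci, rownames(beta))[1])
  if (!length(loci))
    return(data.frame(locus_id = character(0), direction = character(0),
                      stringsAsFactors = FALSE))
  cols <- group_columns(beta, cohort)
  sub <- beta[loci, , drop = FALSE]
  m <- vapply(GROUP_LEVELS,
              function(g) rowMeans(sub[, cols[[g]], drop = FALSE], na.rm = TRUE),
              numeric(length(loci)))
  if (length(loci) == 1) m <- matrix(m, nrow = 1, dimnames = list(loci, GROUP_LEVELS))
  dec <- m[, "NC"] > m[, "aMCI"] & m[, "aMCI"] > m[, "AD"]
  inc <- m[, "NC"] < m[, "aMCI"] & m[, "aMCI"] < m[, "AD"]
  keep <- dec | inc
  data.frame(locus_id = loci[keep],
             direction = ifelse(dec[keep], "decreasing", "increasing"),
             stringsAsFactors = FALSE)
}

#' Annotation filters (accession, promoter region, CpG island)
#'
#' Applies the three nested annotation predicates: stage 3 keeps loci
#' with at least one accession; stage 4 additionally requires at least
#' one transcript annotated to a promoter-region group (TSS1500, TSS200,
#' 5'UTR or 1stExon) — ANY-transcript semantics, so a locus annotated
#' `Body` on one transcript and `1stExon` on another passes; stage 5
#' additionally requires island relation `Island`.
#'
#' @param loci Locus ids (all must be present in the manifest).
#' @param manifest Annotation manifest.
#' @return List of character vectors `stage3_accession`,
#'   `stage4_promoter`, `stage5_island` (each nested in the previous).
#' @export
annotation_filters <- function(loci, manifest) {
  miss <- setdiff(loci, manifest$target_id)
  if (length(miss)) stop_mf("locus %s missing from the manifest", miss[1])
  idx <- match(loci, manifest$target_id)
  has_acc <- lengths(manifest$accessions[idx]) > 0
  any_prom <- vapply(manifest$refgene_groups[idx],
                     function(g) any(g %in% PROMOTER_GROUPS), logical(1))
  island <- manifest$island_relation[idx] == "Island"
  stage3 <- loci[has_acc]
  stage4 <- loci[has_acc & any_prom]
  stage5 <- loci[has_acc & any_prom & island]
  list(stage3_accession = stage3, stage4_promoter = stage4,
       stage5_island = stage5)
}

#' Run the full candidate funnel
#'
#' Restricts the matrix to CpG loci, then composes
#' [pairwise_screen()] -> [intersect_common()] -> [monotone_filter()] ->
#' [annotation_filters()].  All stage sets and per-stage counts are
#' recorded; the output is deterministic in the inputs and invariant to
#' sample and locus ordering.
#'
#' @param beta Beta matrix (loci x samples).
#' @param cohort Sample sheet covering the beta columns.
#' @param manifest Annotation manifest covering the beta rows.
#' @param alpha Per-test significance threshold.
#' @param fdr Benjamini-Hochberg within each pairwise comparison.
#' @return An `mf_funnel`: `n_total`, `cpg_set`, `screen`
#'   (the `mf_pairwise_screen`), `stage1_common`, `stage2_monotone`
#'   (data frame with direction), `stage3_accession`, `stage4_promoter`,
#'   `stage5_island`, `alpha`, and a named `counts` vector.
#' @export
run_funnel <- function(beta, cohort, manifest, alpha = 0.05, fdr = FALSE) {
  miss <- setdiff(rownames(beta), manifest$target_id)
  if (length(miss)) stop_mf("locus %s missing from the manifest", miss[1])
  cpg_ids <- manifest$target_id[manifest$is_cpg]
  cpg_set <- rownames(beta)[rownames(beta) %in% cpg_ids]
  sub <- beta[cpg_set, , drop = FALSE]
  screen <- pairwise_screen(sub, cohort, alpha = alpha, fdr = fdr)
  stage1 <- intersect_common(screen)
  stage2 <- monotone_filter(sub, cohort, stage1)
  ann <- annotation_filters(stage2$locus_id, manifest)
  counts <- c(n_total = nrow(beta),
              cpg = length(cpg_set),
              stage1_common = length(stage1),
              stage2_monotone = nrow(stage2),
              stage3_accession = length(ann$stage3_accession),
              stage4_promoter = length(ann$stage4_promoter),
              stage5_island = length(ann$stage5_island))
  structure(list(n_total = nrow(beta), cpg_set = cpg_set, screen = screen,
                 stage1_common = stage1, stage2_monotone = stage2,
                 stage3_accession = ann$stage3_accession,
                 stage4_promoter = ann$stage4_promoter,
                 stage5_island = ann$stage5_island,
                 alpha = alpha, counts = counts),
            class = "mf_funnel")
}

#' @export
print.mf_funnel <- function(x, ...) {
  lab <- c("loci analysed", "CpG loci", "significant in all 3 comparisons",
           "strictly monotone with progression", "accession present",
           "promoter region (TSS/5'UTR/1stExon)", "CpG island")
  cat("Candidate funnel (alpha =", x$alpha, ")\n")
  for (i in seq_along(x$counts))
    cat(sprintf("  %-38s %8d\n", lab[i], x$counts[i]))
  invisible(x)
}
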