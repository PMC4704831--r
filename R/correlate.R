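# Cognitive-score correlation ranking of funnel survivors and selection
# of the top candidate.  NC subjects carry no scores by design, so the
# correlations run over aMCI + AD subjects; missing scores are dropped
# pairwise, which is why the FAB n can be smaller than the MMSE n.

#' Rank loci by correlation with cognitive scores
#'
#' For each locus computes the Spearman correlation of its beta values
#' with MMSE and with FAB over the scored (aMCI/AD) subjects, dropping
#' incomplete pairs per score.  Loci with fewer than 3 complete pairs or
#' zero rank variance for a score get `NA` entries for that score rather
#' than a fabricated value.
#'
#' @param beta Beta matrix whose columns cover the scored subjects.
#' @param cohort Sample sheet.
#' @param loci Non-empty set of locus ids (rows of `beta`).
#' @param exact Use the exact permutation Spearman p (n <= 9).
#' @return An `mf_ranking` data frame: `locus_id`, `rho_mmse`, `p_mmse`,
#'   `n_mmse`, `rho_fab`, `p_fab`, `n_fab`.
#' @export
score_correlations <- function(beta, cohort, loci, exact = FALSE) {
  if (!length(loci)) stop_mf("score_correlations needs a non-empty locus set")
  if (!all(loci %in% rownames(beta)))
    stop_mf("locus %s not in the beta matrix", setdiff(loci, rownames(beta))[1])
  scored <- cohort[cohort$group %in% c("aMCI", "AD"), , drop = FALSE]
  scored <- scored[scored$sample_id %in% colnames(beta), , drop = FALSE]
  one_score <- function(b, score) {
    keep <- complete.cases(b, score)
    if (sum(keep) < 3 || length(unique(b[keep])) < 2 ||
        length(unique(score[keep])) < 2)
      return(c(rho = NA_real_, p = NA_real_, n = sum(keep)))
    r <- spearman_cor(b[keep], score[keep], exact = exact)
    c(rho = r$estimate, p = r$p_value, n = r$n)
  }
  res <- t(vapply(loci, function(l) {
    b <- beta[l, scored$sample_id]
    c(one_score(b, scored$mmse), one_score(b, scored$fab))
  }, numeric(6)))
  out <- data.frame(locus_id = loci,
                    rho_mmse = res[, 1], p_mmse = res[, 2],
                    n_mmse = as.integer(res[, 3]),
                    rho_fab = res[, 4], p_fab = res[, 5],
                    n_fab = as.integer(res[, 6]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("mf_ranking", "data.frame")
  out
}

#' Select the top-ranked candidate locus
#'
#' Formalises "the correlations were the strongest and the P value was
#' the lowest": among loci significant on BOTH scores (p < alpha for
#' MMSE and FAB), picks the one maximising the weaker absolute
#' correlation `min(|rho_mmse|, |rho_fab|)`; ties are broken by the
#' smaller `max(p_mmse, p_fab)`, then lexicographic locus id.  If no
#' locus is significant on both scores the rule falls back, with a
#' warning, to the MMSE-only criterion (largest `|rho_mmse|` among loci
#' with `p_mmse < alpha`).  Absolute correlations are used; the sign is
#' reported but not enforced.
#'
#' @param ranking An `mf_ranking` from [score_correlations()].
#' @param alpha Significance threshold for each score.
#' @return The selected locus id (character scalar) with attribute
#'   `rationale` describing which rule fired.
#' @export
select_top <- function(ranking, alpha = 0.05) {
  if (!nrow(ranking)) stop_mf("select_top: the ranking is empty")
  r <- ranking
  both <- !is.na(r$p_mmse) & !is.na(r$p_fab) &
    r$p_mmse < alpha & r$p_fab < alpha
  pick <- function(rows, key1, key2) {
    # maximise key1, then minimise key2, then lexicographic id
    ord <- order(-key1, key2, rows$locus_id)
    rows$locus_id[ord[1]]
  }
  if (any(both)) {
    rows <- r[both, , drop = FALSE]
    sel <- pick(rows, pmin(abs(rows$rho_mmse), abs(rows$rho_fab)),
                pmax(rows$p_mmse, rows$p_fab))
    return(structure(sel, rationale = "significant on both scores; strongest weaker correlation"))
  }
  mmse_only <- !is.na(r$p_mmse) & r$p_mmse < alpha
  if (any(mmse_only)) {
    warning("no locus significant on both scores; falling back to the MMSE-only criterion",
            call. = FALSE)
    rows <- r[mmse_only, , drop = FALSE]
    sel <- pick(rows, abs(rows$rho_mmse), rows$p_mmse)
    return(structure(sel, rationale = "MMSE-only fallback; strongest MMSE correlation"))
  }
  stop_mf("select_top: no locus reaches p < %g on any score", alpha)
}
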