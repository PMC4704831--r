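# Confirmation-stage statistics on the full cohort: per-CpG age-adjusted
# three-group ANCOVA with pairwise contrasts, Spearman correlations with
# cognitive scores and background covariates, a sex comparison, the
# cross-platform (array vs pyrosequencing) Pearson concordance, and an
# APOE e4 carrier comparison.

#' APOE e4 carrier status
#'
#' A subject is an e4 carrier iff at least one of the two APOE alleles
#' is e4 (the standard convention).
#'
#' @param cohort A sample sheet data frame (or any data frame with
#'   `apoe_a1`/`apoe_a2` columns).
#' @return Logical vector, one value per row.
#' @export
carrier_status <- function(cohort) {
  cohort$apoe_a1 == "e4" | cohort$apoe_a2 == "e4"
}

#' Validate the candidate locus on the full cohort
#'
#' For each assayed CpG of the pyrosequencing table computes:
#' the age-adjusted ANCOVA over the three groups with all pairwise
#' adjusted-mean contrasts; Spearman correlations of percent methylation
#' with MMSE and FAB (scored aMCI/AD subjects), with age (all subjects),
#' and with disease duration and onset age (aMCI/AD only — NC has no
#' disease); an unpaired t-test between the sexes; the Pearson
#' correlation against the supplied array betas over the subjects
#' present on both platforms (the discovery subset, typically); and an
#' unpaired t-test between APOE e4 carriers and non-carriers.
#'
#' @param pyro Pyro table (`sample_id`, `cpg_index`,
#'   `percent_methylation`) covering >= 3 subjects per group per CpG.
#' @param cohort Sample sheet covering every pyro subject; `age` must be
#'   complete (the ANCOVA covariate is mandatory).
#' @param array_beta_for_locus Optional named numeric vector of array
#'   betas for the candidate locus (names = sample ids); enables the
#'   cross-platform concordance.
#' @return An `mf_validation`: `per_cpg` (list keyed by CpG index with
#'   fields `ancova`, `mmse`, `fab`, `age`, `duration`, `onset`, `sex`,
#'   `cross_platform`, `apoe`) and `summary` (one tidy row per CpG).
#' @export
validate_candidate <- function(pyro, cohort, array_beta_for_locus = NULL) {
  miss <- setdiff(pyro$sample_id, cohort$sample_id)
  if (length(miss)) stop_mf("pyro subject %s missing from the cohort", miss[1])
  if (anyNA(cohort$age[cohort$sample_id %in% pyro$sample_id]))
    stop_mf("ANCOVA covariate (age) missing for a pyrosequenced subject")
  cpgs <- sort(unique(pyro$cpg_index))
  per_cpg <- list()
  rows <- list()
  for (k in cpgs) {
    sub <- pyro[pyro$cpg_index == k, , drop = FALSE]
    idx <- match(sub$sample_id, cohort$sample_id)
    d <- cbind(sub, cohort[idx, setdiff(names(cohort), "sample_id")])
    tab <- table(d$group)
    if (any(tab[GROUP_LEVELS] < 3) || anyNA(tab[GROUP_LEVELS]))
      stop_mf("CpG %d: fewer than 3 subjects in some group", k)
    y <- d$percent_methylation
    anc <- ancova_group_age(y, d$group, d$age)
    scored <- d$group %in% c("aMCI", "AD")
    res <- list(
      ancova = anc,
      mmse = spearman_cor(y[scored], d$mmse[scored]),
      fab  = spearman_cor(y[scored], d$fab[scored]),
      age  = spearman_cor(y, d$age),
      duration = spearman_cor(y[scored], d$duration_months[scored]),
      onset = spearman_cor(y[scored], d$onset_age[scored]),
      sex = t_test_unpaired(y[d$sex == "F"], y[d$sex == "M"]),
      apoe = t_test_unpaired(y[carrier_status(d)], y[!carrier_status(d)]),
      cross_platform = NULL
    )
    if (!is.null(array_beta_for_locus)) {
      common <- intersect(d$sample_id, names(array_beta_for_locus))
      if (length(common) >= 3) {
        yk <- y[match(common, d$sample_id)]
        res$cross_platform <- pearson_cor(array_beta_for_locus[common], yk)
      }
    }
    per_cpg[[as.character(k)]] <- res
    ctr <- anc$contrasts
    cp <- function(g1, g2) ctr$p[ctr$group1 == g1 & ctr$group2 == g2]
    rows[[as.character(k)]] <- data.frame(
      cpg = k,
      adj_mean_nc = anc$adjusted_group_means[["NC"]],
      adj_mean_amci = anc$adjusted_group_means[["aMCI"]],
      adj_mean_ad = anc$adjusted_group_means[["AD"]],
      group_F = anc$group_F, group_p = anc$group_p,
      p_nc_amci = cp("NC", "aMCI"), p_nc_ad = cp("NC", "AD"),
      p_amci_ad = cp("aMCI", "AD"),
      rho_mmse = res$mmse$estimate, p_mmse = res$mmse$p_value,
      rho_fab = res$fab$estimate, p_fab = res$fab$p_value,
      rho_age = res$age$estimate, p_age = res$age$p_value,
      rho_duration = res$duration$estimate, p_duration = res$duration$p_value,
      rho_onset = res$onset$estimate, p_onset = res$onset$p_value,
      p_sex = res$sex$p_value, p_apoe = res$apoe$p_value,
      r_platform = if (is.null(res$cross_platform)) NA_real_
                   else res$cross_platform$estimate,
      p_platform = if (is.null(res$cross_platform)) NA_real_
                   else res$cross_platform$p_value
    )
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(per_cpg = per_cpg, summary = summary),
            class = "mf_validation")
}

#' @export
print.mf_validation <- function(x, ...) {
  cat("Candidate validation over", nrow(x$summary), "CpGs\n")
  print(x$summary[, c("cpg", "adj_mean_nc", "adj_mean_amci", "adj_mean_ad",
                      "group_F", "group_p", "rho_mmse", "p_mmse")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

#' Cohort characteristics summary
#'
#' Builds a subject-characteristics table in the usual clinical layout:
#' per-group mean +/- SEM for age, duration of disease, age at onset,
#' MMSE and FAB; female:male percentages; APOE allele counts; plus the
#' conventional tests — one-way ANOVA for age across the groups present,
#' chi-square for the sex ratio, unpaired t-tests (aMCI vs AD) for
#' scores/duration/onset, and a per-allele chi-square built as an
#' allele-vs-other-alleles by group contingency table (each subject
#' contributes two alleles).  Disease-specific fields stay blank for NC.
#' With fewer than two groups the group tests are `NA` (not applicable).
#'
#' @param cohort A sample sheet data frame.
#' @return An `mf_cohort_table` list: `summary` (data frame: variable,
#'   one column per group, P), `allele_counts` (3 x groups matrix) and
#'   `tests` (named list of `mf_test` or `NA`).
#' @export
cohort_table <- function(cohort) {
  if (!nrow(cohort)) stop_mf("cohort_table needs a non-empty cohort")
  groups <- GROUP_LEVELS[GROUP_LEVELS %in% cohort$group]
  by_group <- lapply(setNames(groups, groups),
                     function(g) cohort[cohort$group == g, , drop = FALSE])
  fmt <- function(x) {
    if (all(is.na(x))) return("-")
    sprintf("%.1f ± %.1f", mean(x, na.rm = TRUE), sem(x))
  }
  sex_pct <- function(d)
    sprintf("%.1f: %.1f", 100 * mean(d$sex == "F"), 100 * mean(d$sex == "M"))
  vars <- c(age = "Age", duration_months = "Duration of disease (months)",
            onset_age = "Age at onset", mmse = "MMSE score", fab = "FAB score")

  multi <- length(groups) >= 2
  has_both <- all(c("aMCI", "AD") %in% groups)
  tests <- list(
    age = if (multi) one_way_anova(lapply(by_group, `[[`, "age")) else NA,
    sex = if (multi) {
      tab <- vapply(by_group, function(d) c(sum(d$sex == "F"), sum(d$sex == "M")),
                    numeric(2))
      chi_square_independence(tab)
    } else NA
  )
  tt_or_na <- function(col) {
    if (!has_both) return(NA)
    x <- by_group$aMCI[[col]]; y <- by_group$AD[[col]]
    if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) return(NA)
    t_test_unpaired(x, y)
  }
  tests$duration_months <- tt_or_na("duration_months")
  tests$onset_age <- tt_or_na("onset_age")
  tests$mmse <- tt_or_na("mmse")
  tests$fab <- tt_or_na("fab")

  allele_counts <- vapply(by_group, function(d) {
    a <- c(d$apoe_a1, d$apoe_a2)
    vapply(APOE_ALLELES, function(al) sum(a == al), numeric(1))
  }, numeric(3))
  rownames(allele_counts) <- APOE_ALLELES
  for (al in APOE_ALLELES) {
    tests[[paste0("apoe_", al)]] <- if (multi && sum(allele_counts[al, ]) > 0) {
      tab <- rbind(allele_counts[al, ],
                   colSums(allele_counts) - allele_counts[al, ])
      chi_square_independence(tab)
    } else NA
  }

  p_of <- function(t) if (identical(t, NA)) NA_real_ else t$p_value
  rows <- lapply(names(vars), function(v) {
    vals <- vapply(by_group, function(d) fmt(d[[v]]), "")
    tname <- if (v == "age") "age" else v
    data.frame(variable = vars[[v]], t(vals), P = p_of(tests[[tname]]),
               check.names = FALSE)
  })
  sex_row <- data.frame(variable = "Female: male (%)",
                        t(vapply(by_group, sex_pct, "")),
                        P = p_of(tests$sex), check.names = FALSE)
  al_rows <- lapply(APOE_ALLELES, function(al)
    data.frame(variable = paste("APOE allele", al),
               t(setNames(as.character(allele_counts[al, ]), groups)),
               P = p_of(tests[[paste0("apoe_", al)]]), check.names = FALSE))
  summary <- do.call(rbind, c(rows[1], list(sex_row), rows[-1], al_rows))
  names(summary) <- c("variable", paste0(groups, " (n = ",
                                         vapply(by_group, nrow, 0L), ")"), "P")
  rownames(summary) <- NULL
  structure(list(summary = summary, allele_counts = allele_counts,
                 tests = tests),
            class = "mf_cohort_table")
}

#' @export
print.mf_cohort_table <- function(x, ...) {
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
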