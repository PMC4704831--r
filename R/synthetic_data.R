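# Synthetic cohort / array / pyrosequencing generator.
#
# The generator emulates the statistical structure the two-stage analysis
# assumes: three diagnostic groups (NC, aMCI, AD) of sizes 30/28/30 with
# the reference cohort covariate marginals; a loci x samples beta matrix
# whose null loci carry logit-normal measurement noise around a per-locus
# baseline and whose planted loci follow configurable per-group mean
# profiles; cognitive scores optionally linked to the planted candidate
# locus; and pyrosequencing replicate measurements with platform noise
# and an optional orientation inversion (an inverted-scale assay reads
# 100 - percent, which produces negative cross-platform correlations).

# Cohort marginals the generator targets for the 30/28/30 study groups
# (means +/- SEM for continuous variables, allele counts for APOE).
.cohort_targets <- list(
  n = c(NC = 30, aMCI = 28, AD = 30),
  age_mean = c(NC = 70.5, aMCI = 72.0, AD = 71.8),
  age_sem  = c(NC = 1.0, aMCI = 0.9, AD = 0.9),
  female_frac = c(NC = 0.600, aMCI = 0.536, AD = 0.533),
  mmse_mean = c(aMCI = 27.2, AD = 18.5),
  mmse_sem  = c(aMCI = 0.4, AD = 1.0),
  fab_mean  = c(aMCI = 14.8, AD = 12.0),
  fab_sem   = c(aMCI = 0.4, AD = 0.7),
  fab_n     = c(aMCI = 28, AD = 23),
  duration_mean = c(aMCI = 26.5, AD = 28.2),
  duration_sem  = c(aMCI = 4.4, AD = 3.5),
  apoe_counts = list(NC   = c(e2 = 3, e3 = 46, e4 = 11),
                     aMCI = c(e2 = 1, e3 = 43, e4 = 12),
                     AD   = c(e2 = 0, e3 = 35, e4 = 25))
)

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator.  Defaults are
#' the study conditions: group sizes 30/28/30 with the reference
#' covariate marginals, one planted candidate locus with a strictly
#' monotone hypomethylation profile on the array scale
#' (NC 0.8 > aMCI 0.6 > AD 0.4) and a validation-shaped profile on the
#' pyrosequencing scale (NC 60% > AD 45% > aMCI 40%), logit-scale noise
#' sd 0.2 (about 0.05 on the beta scale at beta = 0.5), and a strong
#' methylation-score link (90% of within-group score variance).
#'
#' @param group_sizes Integer triple (NC, aMCI, AD).
#' @param n_loci Number of array loci to simulate.
#' @param n_planted Number of planted effect loci (the first planted
#'   locus is the score-linked candidate).
#' @param effect_profile Per-group array beta means for planted loci:
#'   a length-3 vector (recycled) or an `n_planted` x 3 matrix, columns
#'   NC, aMCI, AD, values in (0, 1).
#' @param pyro_profile Per-group mean methylation fraction of the
#'   candidate locus on the pyrosequencing scale (NC, aMCI, AD).  The
#'   default is validation-shaped (NC > AD > aMCI), distinct from the
#'   monotone screening profile.
#' @param noise_sd Measurement noise sd on the logit(beta) scale.
#' @param covariate_model List: `enabled`; `link_share`, the fraction of
#'   within-group MMSE/FAB variance carried by the candidate locus'
#'   methylation deviation (0 disables the link while keeping the
#'   marginals).
#' @param annotation_fractions List of probabilities: `is_cpg`,
#'   `accession` (any accession present), `promoter` (at least one
#'   transcript in TSS1500/TSS200/5'UTR/1stExon), `island`.
#' @param platform List: `pyro_sd` (percent-scale replicate noise sd),
#'   `orientation` (`"same"` or `"inverted"`), `n_cpgs` (CpGs per assay),
#'   `array_link` (fraction of the array's subject-level logit deviation
#'   carried over to the pyro scale; the two platforms assay overlapping
#'   but distinct CpGs, so subject-level concordance is partial) and
#'   `subject_sd` (independent subject-level logit noise on the pyro
#'   scale).
#' @param fab_missing_ad Probability an AD subject lacks a FAB score
#'   (23 of 30 scored in the study).
#' @param discovery_k Discovery-subset size per group.
#' @param seed Integer master seed; every generator derives its own
#'   sub-stream from it, so outputs are bit-identical across runs.
#' @return An object of class `mf_sim_config`.
#' @export
sim_config <- function(group_sizes = c(30, 28, 30),
                       n_loci = 2000,
                       n_planted = 1,
                       effect_profile = c(0.8, 0.6, 0.4),
                       pyro_profile = c(0.60, 0.40, 0.45),
                       noise_sd = 0.2,
                       covariate_model = list(enabled = TRUE, link_share = 0.9),
                       annotation_fractions = list(is_cpg = 0.993,
                                                   accession = 0.83,
                                                   promoter = 0.44,
                                                   island = 0.19),
                       platform = list(pyro_sd = 5, orientation = "same",
                                       n_cpgs = 4, array_link = 0.3,
                                       subject_sd = 0.15),
                       fab_missing_ad = 7 / 30,
                       discovery_k = 4,
                       seed = 1) {
  group_sizes <- as.integer(group_sizes)
  if (length(group_sizes) != 3 || anyNA(group_sizes) || any(group_sizes < 0))
    stop_mf("group_sizes must be 3 non-negative integers")
  if (n_loci < 0 || n_planted < 0 || n_planted > n_loci)
    stop_mf("need 0 <= n_planted <= n_loci")
  ep <- effect_profile
  if (is.null(dim(ep))) ep <- matrix(ep, nrow = max(n_planted, 1), ncol = 3,
                                     byrow = TRUE)
  if (ncol(ep) != 3) stop_mf("effect_profile must have 3 columns (NC, aMCI, AD)")
  if (any(ep <= 0) || any(ep >= 1))
    stop_mf("effect_profile group means must lie strictly in (0, 1)")
  if (length(pyro_profile) != 3 || any(pyro_profile <= 0) || any(pyro_profile >= 1))
    stop_mf("pyro_profile must be 3 fractions in (0, 1)")
  af <- annotation_fractions
  probs <- unlist(af[c("is_cpg", "accession", "promoter", "island")])
  if (any(probs < 0) || any(probs > 1))
    stop_mf("annotation fractions must be probabilities in [0, 1]")
  if (noise_sd < 0) stop_mf("noise_sd must be non-negative")
  if (!platform$orientation %in% c("same", "inverted"))
    stop_mf("platform orientation must be 'same' or 'inverted'")
  cm <- covariate_model
  cm$enabled <- isTRUE(cm$enabled)
  cm$link_share <- cm$link_share %||% 0.9
  if (cm$link_share < 0 || cm$link_share >= 1)
    stop_mf("covariate_model link_share must lie in [0, 1)")
  platform$subject_sd <- platform$subject_sd %||% 0
  platform$array_link <- platform$array_link %||% 1
  if (platform$array_link < 0 || platform$array_link > 1)
    stop_mf("platform array_link must lie in [0, 1]")
  if (fab_missing_ad < 0 || fab_missing_ad > 1)
    stop_mf("fab_missing_ad must be a probability")
  if (discovery_k < 2) stop_mf("discovery_k must be >= 2")

  structure(list(group_sizes = setNames(group_sizes, GROUP_LEVELS),
                 n_loci = as.integer(n_loci),
                 n_planted = as.integer(n_planted),
                 effect_profile = ep,
                 pyro_profile = setNames(pyro_profile, GROUP_LEVELS),
                 noise_sd = noise_sd,
                 covariate_model = cm,
                 annotation_fractions = af,
                 platform = platform,
                 fab_missing_ad = fab_missing_ad,
                 discovery_k = as.integer(discovery_k),
                 seed = as.integer(seed)),
            class = "mf_sim_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  while (any(bad <- out < lo | out > hi))
    out[bad] <- rnorm(sum(bad), mean, sd)
  out
}

# lognormal draws matched to a target mean and sd (durations are
# right-skewed positive quantities, so a lognormal is the natural shape)
rlnorm_match <- function(n, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic clinical cohort
#'
#' Draws a cohort whose group sizes, age, sex, cognitive-score, disease
#' duration and APOE allele distributions target the reference cohort
#' marginals (see the methods vignette).  Ages are truncated normal on \[55, 90\] with sd recovered
#' from the target SEMs; durations are lognormal (moment-matched);
#' onset age is `age - duration/12`, which keeps age, duration and onset
#' mutually consistent; MMSE/FAB are integer scores clipped to their scale ranges and
#' present only for aMCI/AD (FAB missing for some AD subjects); APOE
#' alleles are drawn per group from the reference allele frequencies.
#'
#' @param config An [sim_config()] object.
#' @return A sample-sheet `data.frame` (see [read_sample_sheet()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "mf_sim_config"))
  set.seed(mix_seed(config$seed, 1))
  tg <- .cohort_targets
  rows <- list()
  counter <- 0L
  for (g in GROUP_LEVELS) {
    n <- config$group_sizes[[g]]
    if (n == 0) next
    age <- rtrunc_norm(n, tg$age_mean[[g]], tg$age_sem[[g]] * sqrt(tg$n[[g]]),
                       55, 90)
    sex <- ifelse(runif(n) < tg$female_frac[[g]], "F", "M")
    if (g == "NC") {
      mmse <- rep(NA_integer_, n); fab <- rep(NA_integer_, n)
      dur <- rep(NA_real_, n); onset <- rep(NA_real_, n)
    } else {
      mmse <- as.integer(round(clamp(
        rnorm(n, tg$mmse_mean[[g]], tg$mmse_sem[[g]] * sqrt(tg$n[[g]])), 0, 30)))
      fab <- as.integer(round(clamp(
        rnorm(n, tg$fab_mean[[g]], tg$fab_sem[[g]] * sqrt(tg$fab_n[[g]])), 0, 18)))
      if (g == "AD") fab[runif(n) < config$fab_missing_ad] <- NA_integer_
      dur <- rlnorm_match(n, tg$duration_mean[[g]],
                          tg$duration_sem[[g]] * sqrt(tg$n[[g]]))
      onset <- age - dur / 12
    }
    pa <- tg$apoe_counts[[g]] / sum(tg$apoe_counts[[g]])
    a1 <- sample(APOE_ALLELES, n, replace = TRUE, prob = pa)
    a2 <- sample(APOE_ALLELES, n, replace = TRUE, prob = pa)
    rows[[g]] <- data.frame(
      sample_id = sprintf("S%03d", counter + seq_len(n)),
      group = factor(g, levels = GROUP_LEVELS),
      age = age, sex = factor(sex, levels = SEX_LEVELS),
      mmse = mmse, fab = fab, apoe_a1 = a1, apoe_a2 = a2,
      duration_months = dur, onset_age = onset,
      stringsAsFactors = FALSE)
    counter <- counter + n
  }
  if (!length(rows))
    return(data.frame(sample_id = character(), group = factor(levels = GROUP_LEVELS),
                      age = numeric(), sex = factor(levels = SEX_LEVELS),
                      mmse = integer(), fab = integer(),
                      apoe_a1 = character(), apoe_a2 = character(),
                      duration_months = numeric(), onset_age = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic 450K-style annotation manifest
#'
#' Draws per-locus annotation categories independently with the
#' configured fractions.  The first `n_planted` loci are forced to
#' satisfy all four funnel annotation predicates (CpG locus, accession
#' present, at least one promoter-region transcript, island relation
#' `Island`) so planted effects can, by construction, survive the
#' annotation stages.
#'
#' @param config An [sim_config()] object.
#' @return A manifest `data.frame` (see [read_manifest()]); locus ids are
#'   `cg00000001 ...`, planted loci first.
#' @export
generate_manifest <- function(config) {
  stopifnot(inherits(config, "mf_sim_config"))
  set.seed(mix_seed(config$seed, 2))
  n <- config$n_loci
  af <- config$annotation_fractions
  planted <- seq_len(n) <= config$n_planted
  is_cpg <- runif(n) < af$is_cpg | planted
  has_acc <- runif(n) < af$accession | planted
  any_prom <- runif(n) < af$promoter | planted
  island <- ifelse(runif(n) < af$island | planted, "Island",
                   sample(c("N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea"),
                          n, replace = TRUE,
                          prob = c(0.2, 0.2, 0.1, 0.1, 0.4)))
  genes <- vector("list", n); accs <- vector("list", n); grps <- vector("list", n)
  non_prom <- c("Body", "3'UTR")
  n_tx <- sample(1:5, n, replace = TRUE)
  for (i in seq_len(n)) {
    if (!has_acc[i]) {
      genes[[i]] <- character(0); accs[[i]] <- character(0); grps[[i]] <- character(0)
      next
    }
    k <- n_tx[i]
    genes[[i]] <- rep(sprintf("GENE%06d", i), k)
    accs[[i]] <- sprintf("NM_%06d", i * 10L + seq_len(k))
    if (any_prom[i]) {
      gk <- sample(REFGENE_GROUPS, k, replace = TRUE)
      if (!any(gk %in% PROMOTER_GROUPS))
        gk[sample.int(k, 1)] <- sample(PROMOTER_GROUPS, 1)
    } else {
      gk <- sample(non_prom, k, replace = TRUE)
    }
    grps[[i]] <- gk
  }
  out <- data.frame(target_id = sprintf("cg%08d", seq_len(n)),
                    is_cpg = is_cpg,
                    island_relation = factor(island, levels = ISLAND_RELATIONS),
                    chromosome = paste0("chr", sample(1:22, n, replace = TRUE)),
                    position = sample.int(2e8, n, replace = TRUE),
                    stringsAsFactors = FALSE)
  out$gene_names <- genes
  out$accessions <- accs
  out$refgene_groups <- grps
  out
}

#' Generate a synthetic beta matrix with planted effects
#'
#' Null loci draw a baseline beta uniformly in (0.05, 0.95); each
#' subject's value is `inv_logit(logit(baseline) + N(0, noise_sd))`, i.e.
#' logit-normal measurement noise and no group effect.  Planted loci
#' (the first `n_planted` manifest loci) replace the baseline with the
#' configured per-group means.  When the covariate model is enabled,
#' MMSE and FAB scores of aMCI/AD subjects are re-generated so that a
#' `link_share` fraction of each group's score variance is carried by the
#' subject's methylation deviation at the candidate (first planted)
#' locus; the group score means/variances stay at their cohort targets
#' and the FAB missingness pattern is preserved.
#'
#' @param cohort Cohort from [generate_cohort()].
#' @param manifest Manifest from [generate_manifest()].
#' @param config The same [sim_config()] used to generate both.
#' @return List: `beta` (loci x samples matrix), `truth` (data frame of
#'   planted locus ids, per-group means and direction), `cohort` (the
#'   cohort, with scores re-generated if the covariate model is on).
#' @export
generate_beta <- function(cohort, manifest, config) {
  stopifnot(inherits(config, "mf_sim_config"))
  if (nrow(manifest) != config$n_loci)
    stop_mf("manifest has %d loci but config says %d", nrow(manifest), config$n_loci)
  set.seed(mix_seed(config$seed, 3))
  n_s <- nrow(cohort)
  n_l <- config$n_loci
  g_idx <- as.integer(cohort$group)     # 1 = NC, 2 = aMCI, 3 = AD
  mu <- matrix(NA_real_, n_l, n_s)
  baseline <- runif(n_l, 0.05, 0.95)
  mu[] <- baseline                      # recycled down columns
  if (config$n_planted > 0) {
    for (k in seq_len(config$n_planted))
      mu[k, ] <- config$effect_profile[k, g_idx]
  }
  beta <- inv_logit(logit(mu) + matrix(rnorm(n_l * n_s, 0, config$noise_sd),
                                       n_l, n_s))
  dimnames(beta) <- list(manifest$target_id, cohort$sample_id)

  truth <- data.frame(locus_id = character(0), mean_nc = numeric(0),
                      mean_amci = numeric(0), mean_ad = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  if (config$n_planted > 0) {
    ep <- config$effect_profile[seq_len(config$n_planted), , drop = FALSE]
    dir <- ifelse(ep[, 1] > ep[, 2] & ep[, 2] > ep[, 3], "decreasing",
                  ifelse(ep[, 1] < ep[, 2] & ep[, 2] < ep[, 3], "increasing",
                         "none"))
    truth <- data.frame(locus_id = manifest$target_id[seq_len(config$n_planted)],
                        mean_nc = ep[, 1], mean_amci = ep[, 2], mean_ad = ep[, 3],
                        direction = dir, stringsAsFactors = FALSE)
  }

  cm <- config$covariate_model
  if (cm$enabled && cm$link_share > 0 && config$n_planted > 0 && n_s > 0) {
    tg <- .cohort_targets
    cand <- beta[1, ]
    # standardised within-group methylation deviation of the candidate
    dev <- (logit(cand) - logit(config$effect_profile[1, g_idx])) /
      max(config$noise_sd, 1e-12)
    share <- cm$link_share
    for (g in c("aMCI", "AD")) {
      idx <- which(cohort$group == g)
      if (!length(idx)) next
      sd_m <- tg$mmse_sem[[g]] * sqrt(tg$n[[g]])
      sd_f <- tg$fab_sem[[g]] * sqrt(tg$fab_n[[g]])
      mmse <- tg$mmse_mean[[g]] + sqrt(share) * sd_m * dev[idx] +
        rnorm(length(idx), 0, sqrt(1 - share) * sd_m)
      fab <- tg$fab_mean[[g]] + sqrt(share) * sd_f * dev[idx] +
        rnorm(length(idx), 0, sqrt(1 - share) * sd_f)
      was_na <- is.na(cohort$fab[idx])
      cohort$mmse[idx] <- as.integer(round(clamp(mmse, 0, 30)))
      cohort$fab[idx] <- as.integer(round(clamp(fab, 0, 18)))
      cohort$fab[idx][was_na] <- NA_integer_
    }
  }
  list(beta = beta, truth = truth, cohort = cohort)
}

#' Generate a pyrosequencing replicate measurement for one locus
#'
#' Per subject and assayed CpG the measured percent methylation is
#' `clamp(100 * (o + s * beta) + N(0, pyro_sd), 0, 100)` where the
#' orientation `(o, s)` is `(0, +1)` for a same-scale assay and
#' `(1, -1)` for an inverted-scale assay (an assay reading the opposite
#' strand reports the complementary fraction, which makes cross-platform
#' correlations negative).
#'
#' @param beta_locus Named numeric vector: the locus' methylation
#'   fraction per subject (names are sample ids).
#' @param config An [sim_config()] object (`platform` settings are used).
#' @return A pyro-table `data.frame` (see [read_pyro_table()]).
#' @export
generate_pyro <- function(beta_locus, config) {
  stopifnot(inherits(config, "mf_sim_config"), !is.null(names(beta_locus)))
  set.seed(mix_seed(config$seed, 4))
  k <- config$platform$n_cpgs
  o <- if (config$platform$orientation == "inverted") 1 else 0
  s <- if (config$platform$orientation == "inverted") -1 else 1
  n <- length(beta_locus)
  pct <- clamp(100 * (o + s * rep(beta_locus, each = k)) +
                 rnorm(n * k, 0, config$platform$pyro_sd), 0, 100)
  data.frame(sample_id = rep(names(beta_locus), each = k),
             cpg_index = rep(seq_len(k), times = n),
             percent_methylation = pct,
             stringsAsFactors = FALSE)
}

#' Convert Infinium intensities to a beta value
#'
#' The standard definition `beta = M / (M + U + offset)` for methylated
#' signal M and unmethylated signal U; the offset (default 100, the
#' platform convention) stabilises low-intensity probes and keeps the
#' result in \[0, 1).
#'
#' @param methylated_signal,unmethylated_signal Non-negative intensities
#'   (vectorised).
#' @param offset Non-negative stabilising constant.
#' @return Beta fraction(s) in \[0, 1\].
#' @export
#' @examples
#' intensities_to_beta(1000, 0, offset = 100)  # 0.9091
intensities_to_beta <- function(methylated_signal, unmethylated_signal,
                                offset = 100) {
  if (any(methylated_signal < 0) || any(unmethylated_signal < 0) || offset < 0)
    stop_mf("intensities and offset must be non-negative")
  denom <- methylated_signal + unmethylated_signal + offset
  if (any(denom == 0))
    stop_mf("beta undefined: M + U + offset = 0")
  methylated_signal / denom
}

#' Select the discovery subset
#'
#' Returns the first `k` subjects per group after sorting each group by
#' age, emulating a small age-matched discovery design nested inside the
#' full cohort.
#'
#' @param cohort A cohort data frame.
#' @param k Subjects per group.
#' @return The subsetted cohort (rows in NC, aMCI, AD order).
#' @export
discovery_subset <- function(cohort, k = 4) {
  if (k < 2) stop_mf("discovery subset needs k >= 2 per group")
  parts <- lapply(GROUP_LEVELS, function(g) {
    sub <- cohort[cohort$group == g, , drop = FALSE]
    if (nrow(sub) < k)
      stop_mf("group %s has %d subjects, fewer than k = %d", g, nrow(sub), k)
    sub[order(sub$age), , drop = FALSE][seq_len(k), , drop = FALSE]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Simulate a complete two-stage study
#'
#' Generates, under one master seed: the cohort, the annotation manifest,
#' the array beta matrix with planted effects (and score linkage), the
#' age-sorted discovery subset, and the pyrosequencing table for the
#' candidate locus on the full cohort.  The candidate's pyrosequencing
#' group means follow `pyro_profile` (validation-shaped by default, so
#' the group ordering can differ between platforms, as observed when a
#' small discovery design is re-measured at scale) and each subject
#' carries over a fraction `array_link` of their array-scale logit
#' deviation plus independent pyro-scale noise `subject_sd`, giving
#' partial within-group cross-platform concordance.
#'
#' @param config An [sim_config()] object.
#' @return List: `config`, `cohort`, `manifest`, `beta`, `truth`,
#'   `discovery` (cohort subset), `candidate_locus` (id or `NA`),
#'   `pyro_beta` (per-subject pyro-scale fraction) and `pyro` (table),
#'   the last three `NULL`/`NA` when nothing is planted.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "mf_sim_config"))
  cohort <- generate_cohort(config)
  manifest <- generate_manifest(config)
  gb <- generate_beta(cohort, manifest, config)
  cohort <- gb$cohort
  disc <- discovery_subset(cohort, config$discovery_k)
  out <- list(config = config, cohort = cohort, manifest = manifest,
              beta = gb$beta, truth = gb$truth, discovery = disc,
              candidate_locus = NA_character_, pyro_beta = NULL, pyro = NULL)
  if (config$n_planted > 0) {
    cand <- gb$truth$locus_id[1]
    g_idx <- as.integer(cohort$group)
    arr_mu <- config$effect_profile[1, g_idx]
    pyro_mu <- config$pyro_profile[g_idx]
    dev <- logit(gb$beta[cand, ]) - logit(arr_mu)
    set.seed(mix_seed(config$seed, 5))
    dev <- config$platform$array_link * dev +
      rnorm(length(dev), 0, config$platform$subject_sd)
    pyro_beta <- inv_logit(logit(pyro_mu) + dev)
    names(pyro_beta) <- cohort$sample_id
    out$candidate_locus <- cand
    out$pyro_beta <- pyro_beta
    out$pyro <- generate_pyro(pyro_beta, config)
  }
  out
}
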