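# Orchestration of the full two-stage analysis:
#   simulate -> screen (discovery subset) -> correlate -> validate,
# with all artifacts written under one output directory and a run log
# sufficient to regenerate every output exactly.

#' Pipeline run configuration
#'
#' @param out_dir Output directory (created if needed); `NULL` disables
#'   all file output (the pipeline then returns its objects only).
#' @param alpha Significance threshold used at every screening and
#'   selection stage.
#' @param discovery_k Discovery-subset size per group.
#' @param seed Master seed (overrides `sim$seed`).
#' @param fdr Benjamini-Hochberg within each pairwise screen.
#' @param exact_spearman Exact permutation p-values in the ranking stage.
#' @param orientation Pyrosequencing orientation, `"same"` or
#'   `"inverted"` (overrides `sim$platform$orientation`).
#' @param sim An [sim_config()] describing the synthetic study.
#' @return An `mf_run_config` list.
#' @export
run_config <- function(out_dir = NULL, alpha = 0.05, discovery_k = 4,
                       seed = 1, fdr = FALSE, exact_spearman = FALSE,
                       orientation = NULL, sim = sim_config()) {
  if (alpha <= 0 || alpha >= 1) stop_mf("alpha must lie in (0, 1)")
  if (discovery_k < 2) stop_mf("discovery_k must be >= 2")
  sim$seed <- as.integer(seed)
  sim$discovery_k <- as.integer(discovery_k)
  if (!is.null(orientation)) {
    if (!orientation %in% c("same", "inverted"))
      stop_mf("orientation must be 'same' or 'inverted'")
    sim$platform$orientation <- orientation
  }
  structure(list(out_dir = out_dir, alpha = alpha,
                 discovery_k = as.integer(discovery_k),
                 seed = as.integer(seed), fdr = isTRUE(fdr),
                 exact_spearman = isTRUE(exact_spearman), sim = sim),
            class = "mf_run_config")
}

#' Run the full two-stage pipeline
#'
#' Simulates a study under the configured seed, screens the discovery
#' subset through the candidate funnel, ranks the island-stage survivors
#' by cognitive-score correlation, selects the top candidate, and — when
#' the planted candidate's pyrosequencing table is available — validates
#' the selected locus on the full cohort (cross-platform concordance is
#' computed over the discovery subjects, the subjects measured on both
#' platforms).  With an `out_dir`, writes the simulated inputs
#' (`samples.csv`, `manifest.csv`, `beta.tsv`, `pyro.csv`,
#' `planted_truth.csv`), the stage outputs (`funnel.json`,
#' `ranking.tsv`, `report.json`, `validation.tsv`) and `run_log.txt`.
#' Identical configuration and seed produce byte-identical outputs.
#'
#' @param config An [run_config()].
#' @return List: `config`, `study` (see [simulate_study()]), `funnel`,
#'   `ranking`, `candidate` (selected locus id or `NA`), `validation`
#'   (or `NULL`), `files` (named paths when writing).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "mf_run_config"))
  study <- simulate_study(config$sim)
  disc_ids <- study$discovery$sample_id
  beta_disc <- study$beta[, disc_ids, drop = FALSE]

  funnel <- run_funnel(beta_disc, study$discovery, study$manifest,
                       alpha = config$alpha, fdr = config$fdr)

  ranking <- NULL
  candidate <- NA_character_
  if (length(funnel$stage5_island)) {
    ranking <- score_correlations(beta_disc, study$discovery,
                                  funnel$stage5_island,
                                  exact = config$exact_spearman)
    candidate <- tryCatch(
      suppressWarnings(as.character(select_top(ranking, config$alpha))),
      error = function(e) NA_character_)
  }

  validation <- NULL
  if (!is.na(candidate) && !is.null(study$pyro)) {
    array_disc <- study$beta[candidate, disc_ids]
    validation <- validate_candidate(study$pyro, study$cohort,
                                     array_beta_for_locus = array_disc)
  }

  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    pth <- function(f) file.path(config$out_dir, f)
    write_sample_sheet(study$cohort, pth("samples.csv"))
    write_manifest(study$manifest, pth("manifest.csv"))
    write_beta_matrix(study$beta, pth("beta.tsv"))
    write.csv(study$truth, pth("planted_truth.csv"), row.names = FALSE,
              quote = FALSE)
    if (!is.null(study$pyro)) write_pyro_table(study$pyro, pth("pyro.csv"))
    jsonlite::write_json(
      list(alpha = funnel$alpha, counts = as.list(funnel$counts),
           stage1_common = funnel$stage1_common,
           stage2_monotone = funnel$stage2_monotone,
           stage3_accession = funnel$stage3_accession,
           stage4_promoter = funnel$stage4_promoter,
           stage5_island = funnel$stage5_island),
      pth("funnel.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(ranking))
      write.table(ranking, pth("ranking.tsv"), sep = "\t", row.names = FALSE,
                  quote = FALSE)
    report <- list(seed = config$seed, alpha = config$alpha,
                   candidate = candidate,
                   planted_candidate = study$candidate_locus)
    if (!is.null(validation)) {
      report$validation <- validation$summary
      write.table(validation$summary, pth("validation.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    log_lines <- c(
      "methfunnel run log",
      paste0("package_version: ", as.character(utils::packageVersion("methfunnel"))),
      paste0("r_version: ", R.version.string),
      paste0("seed: ", config$seed),
      paste0("alpha: ", config$alpha),
      paste0("discovery_k: ", config$discovery_k),
      paste0("fdr: ", config$fdr),
      paste0("exact_spearman: ", config$exact_spearman),
      paste0("orientation: ", config$sim$platform$orientation),
      paste0("n_loci: ", config$sim$n_loci),
      paste0("n_planted: ", config$sim$n_planted),
      paste0("noise_sd: ", config$sim$noise_sd),
      paste0("group_sizes: ", paste(config$sim$group_sizes, collapse = "/")),
      paste0("selected_candidate: ", candidate))
    writeLines(log_lines, pth("run_log.txt"))
    files <- vapply(list.files(config$out_dir), pth, "")
  }

  list(config = config, study = study, funnel = funnel, ranking = ranking,
       candidate = candidate, validation = validation, files = files)
}
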