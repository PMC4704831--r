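test_that("generators are bit-identical under a fixed seed", {
  cfg <- sim_config(n_loci = 300, seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$pyro, s2$pyro)
  s3 <- simulate_study(sim_config(n_loci = 300, seed = 100))
  expect_false(identical(s1$beta, s3$beta))
})

test_that("cohort has configured sizes, NC without scores, plausible marginals", {
  cohort <- generate_cohort(sim_config(seed = 5))
  expect_equal(nrow(cohort), 88)
  expect_equal(as.integer(table(cohort$group)[c("NC", "aMCI", "AD")]),
               c(30L, 28L, 30L))
  expect_true(all(is.na(cohort$mmse[cohort$group == "NC"])))
  expect_true(all(is.na(cohort$duration_months[cohort$group == "NC"])))
  expect_true(all(!is.na(cohort$mmse[cohort$group != "NC"])))
  expect_true(all(cohort$age >= 55 & cohort$age <= 90))
  expect_true(all(cohort$mmse >= 0 & cohort$mmse <= 30, na.rm = TRUE))
  expect_true(all(cohort$apoe_a1 %in% c("e2", "e3", "e4")))
  # onset consistent with duration
  amci <- cohort[cohort$group == "aMCI", ]
  expect_equal(amci$onset_age, amci$age - amci$duration_months / 12)
  expect_equal(nrow(generate_cohort(sim_config(group_sizes = c(0, 0, 0)))), 0)
  expect_error(sim_config(group_sizes = c(-1, 4, 4)), "non-negative")
})

test_that("cohort score means hit their targets over repeated draws", {
  mm <- t(vapply(1:200, function(s) {
    co <- generate_cohort(sim_config(seed = s))
    c(amci = mean(co$mmse[co$group == "aMCI"]),
      ad = mean(co$mmse[co$group == "AD"]),
      fab_ad_n = sum(!is.na(co$fab[co$group == "AD"])))
  }, numeric(3)))
  expect_lt(abs(mean(mm[, "amci"]) - 27.2), 3 * 0.4)
  expect_lt(abs(mean(mm[, "ad"]) - 18.5), 3 * 1.0)
  expect_gt(mean(mm[, "fab_ad_n"]), 18)     # most AD subjects have FAB
  expect_lt(mean(mm[, "fab_ad_n"]), 28)
})

test_that("manifest category fractions follow the configuration", {
  cfg <- sim_config(n_loci = 10000, n_planted = 0, seed = 7)
  man <- generate_manifest(cfg)
  expect_equal(nrow(man), 10000)
  phat <- mean(man$is_cpg)
  p0 <- 0.993
  expect_lt(abs(phat - p0), 2.58 * sqrt(p0 * (1 - p0) / 10000))
  # all-pass configuration
  cfg1 <- sim_config(n_loci = 200, n_planted = 0, seed = 7,
                     annotation_fractions = list(is_cpg = 1, accession = 1,
                                                 promoter = 1, island = 1))
  man1 <- generate_manifest(cfg1)
  expect_true(all(man1$is_cpg))
  expect_true(all(lengths(man1$accessions) > 0))
  expect_true(all(vapply(man1$refgene_groups, function(g)
    any(g %in% c("TSS1500", "TSS200", "5'UTR", "1stExon")), TRUE)))
  expect_true(all(man1$island_relation == "Island"))
})

test_that("planted loci satisfy all four annotation predicates by construction", {
  cfg <- sim_config(n_loci = 500, n_planted = 10, seed = 8,
                    annotation_fractions = list(is_cpg = 0.5, accession = 0.2,
                                                promoter = 0.2, island = 0.05))
  man <- generate_manifest(cfg)
  planted <- man[1:10, ]
  expect_true(all(planted$is_cpg))
  expect_true(all(lengths(planted$accessions) > 0))
  expect_true(all(vapply(planted$refgene_groups, function(g)
    any(g %in% c("TSS1500", "TSS200", "5'UTR", "1stExon")), TRUE)))
  expect_true(all(planted$island_relation == "Island"))
})

test_that("zero-noise planted profile reproduces group means exactly", {
  cfg <- sim_config(group_sizes = c(3, 3, 3), n_loci = 5, n_planted = 1,
                    effect_profile = c(0.8, 0.6, 0.4), noise_sd = 0,
                    covariate_model = list(enabled = FALSE), seed = 2)
  co <- generate_cohort(cfg)
  man <- generate_manifest(cfg)
  gb <- generate_beta(co, man, cfg)
  planted <- gb$beta[1, ]
  expect_equal(unname(planted[co$group == "NC"]), rep(0.8, 3))
  expect_equal(unname(planted[co$group == "aMCI"]), rep(0.6, 3))
  expect_equal(unname(planted[co$group == "AD"]), rep(0.4, 3))
  expect_equal(gb$truth$direction, "decreasing")
  expect_error(sim_config(effect_profile = c(1.2, 0.5, 0.4)), "in \\(0, 1\\)")
})

test_that("betas stay in [0,1] and planted group means are recovered", {
  cfg <- sim_config(group_sizes = c(20, 20, 20), n_loci = 50, n_planted = 5,
                    seed = 31, covariate_model = list(enabled = FALSE))
  co <- generate_cohort(cfg)
  gb <- generate_beta(co, generate_manifest(cfg), cfg)
  expect_true(all(gb$beta >= 0 & gb$beta <= 1))
  # beta-scale sd ~ noise_sd * b(1-b); group means within 3 sd/sqrt(n)
  for (g in c("NC", "aMCI", "AD")) {
    truth <- gb$truth[[paste0("mean_", tolower(sub("aMCI", "amci", g)))]][1]
    got <- mean(gb$beta[1, co$group == g])
    tol <- 3 * 0.2 * truth * (1 - truth) / sqrt(20)
    expect_lt(abs(got - truth), tol + 0.01)
  }
})

test_that("null beta matrix gives calibrated pairwise t-tests", {
  cfg <- sim_config(group_sizes = c(4, 4, 4), n_loci = 10000, n_planted = 0,
                    seed = 13, covariate_model = list(enabled = FALSE))
  co <- generate_cohort(cfg)
  gb <- generate_beta(co, generate_manifest(cfg), cfg)
  screen <- pairwise_screen(gb$beta, co, alpha = 0.05)
  for (nm in names(screen$sets)) {
    rate <- length(screen$sets[[nm]]) / 10000
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
  }
})

test_that("pyro generation honours orientation and noise", {
  cfg0 <- sim_config(platform = list(pyro_sd = 0, orientation = "same",
                                     n_cpgs = 2), seed = 4)
  b <- c(S1 = 0.25, S2 = 0.75)
  p <- generate_pyro(b, cfg0)
  expect_equal(p$percent_methylation[p$sample_id == "S1"], c(25, 25))
  cfg1 <- sim_config(platform = list(pyro_sd = 0, orientation = "inverted",
                                     n_cpgs = 2), seed = 4)
  p1 <- generate_pyro(b, cfg1)
  expect_equal(p1$percent_methylation[p1$sample_id == "S1"], c(75, 75))

  # inverted orientation with noise: negative correlation with the betas
  set.seed(21)
  bb <- setNames(runif(30, 0.2, 0.8), sprintf("S%02d", 1:30))
  cfg2 <- sim_config(platform = list(pyro_sd = 3, orientation = "inverted",
                                     n_cpgs = 1), seed = 5)
  p2 <- generate_pyro(bb, cfg2)
  expect_lt(cor(bb[p2$sample_id], p2$percent_methylation), 0)
  expect_true(all(p2$percent_methylation >= 0 & p2$percent_methylation <= 100))
})

test_that("intensity-to-beta conversion follows the platform definition", {
  expect_equal(intensities_to_beta(500, 500, offset = 0), 0.5)
  expect_equal(intensities_to_beta(1000, 0, offset = 100), 1000 / 1100)
  expect_equal(intensities_to_beta(0, 800), 0)
  expect_error(intensities_to_beta(0, 0, offset = 0), "undefined")
  expect_error(intensities_to_beta(-1, 5), "non-negative")
})

test_that("discovery subset takes the k youngest per group", {
  co <- generate_cohort(sim_config(seed = 17))
  d <- discovery_subset(co, k = 4)
  expect_equal(nrow(d), 12)
  expect_equal(as.integer(table(d$group)[c("NC", "aMCI", "AD")]), c(4L, 4L, 4L))
  for (g in c("NC", "aMCI", "AD")) {
    ages_all <- sort(co$age[co$group == g])
    expect_equal(sort(d$age[d$group == g]), ages_all[1:4])
  }
  expect_error(discovery_subset(co[co$group != "NC", ], k = 4), "group NC")
})

test_that("covariate model links scores to the candidate locus", {
  cfg <- sim_config(seed = 23, n_loci = 100)
  st <- simulate_study(cfg)
  sc <- st$cohort[st$cohort$group %in% c("aMCI", "AD"), ]
  b <- st$beta[st$candidate_locus, sc$sample_id]
  r <- cor(b, sc$mmse, method = "spearman")
  expect_gt(abs(r), 0.5)
  # group marginals survive the re-generation
  expect_lt(abs(mean(sc$mmse[sc$group == "aMCI"]) - 27.2), 2)
  expect_true(all(is.na(st$cohort$mmse[st$cohort$group == "NC"])))
})
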