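test_that("maximally separated locus is significant in all three pairs", {
  set.seed(201)
  co <- make_cohort(rep(c("NC", "aMCI", "AD"), each = 4))
  vals <- c(rep(0.8, 4), rep(0.5, 4), rep(0.2, 4)) + rnorm(12, 0, 1e-4)
  beta <- matrix(c(vals, runif(12, 0.4, 0.6)), 2, 12, byrow = TRUE,
                 dimnames = list(c("cgSEP", "cgNULL"), co$sample_id))
  sc <- pairwise_screen(beta, co, alpha = 0.05)
  expect_true(all(vapply(sc$sets, function(s) "cgSEP" %in% s, TRUE)))
  expect_equal(intersect_common(sc), "cgSEP")
  expect_equal(sum(sc$venn_counts), length(unique(unlist(sc$sets))))
})

test_that("pairwise screen equals a per-locus t.test loop, with missing handling", {
  set.seed(202)
  co <- make_cohort(rep(c("NC", "aMCI", "AD"), each = 4))
  beta <- matrix(runif(50 * 12), 50, 12,
                 dimnames = list(sprintf("cg%03d", 1:50), co$sample_id))
  beta[2, 1] <- NA                      # NC value missing: skip NC pairs
  beta[sample(length(beta), 10)] <- NA
  sc <- pairwise_screen(beta, co, alpha = 0.2)
  bf <- brute_force_funnel(beta, co, make_manifest(rownames(beta)), alpha = 0.2)
  for (nm in names(sc$sets))
    expect_setequal(sc$sets[[nm]], bf$sets[[nm]])
  expect_true(sc$skipped["cg002", "NC-aMCI"])
  expect_error(pairwise_screen(beta[, 1:5], co[1:5, ], alpha = 0.05), ">= 2")
})

test_that("set intersection matches brute-force membership", {
  sets_to_screen <- function(sets) {
    structure(list(sets = setNames(sets, c("NC-aMCI", "NC-AD", "aMCI-AD"))),
              class = "mf_pairwise_screen")
  }
  expect_equal(intersect_common(sets_to_screen(list(c("a", "b"), c("b", "c"), "b"))),
               "b")
  expect_equal(length(intersect_common(
    sets_to_screen(list(character(0), c("b"), c("b"))))), 0)
  set.seed(203)
  for (i in 1:20) {
    u <- sprintf("cg%02d", 1:30)
    sets <- lapply(1:3, function(k) sample(u, sample(0:30, 1)))
    got <- intersect_common(sets_to_screen(sets))
    exp <- u[u %in% sets[[1]] & u %in% sets[[2]] & u %in% sets[[3]]]
    expect_setequal(got, exp)
  }
})

test_that("monotone filter keeps strictly ordered means only, with direction", {
  co <- make_cohort(rep(c("NC", "aMCI", "AD"), each = 2))
  beta <- rbind(cgDEC = c(0.8, 0.8, 0.6, 0.6, 0.4, 0.4),
                cgNON = c(0.8, 0.8, 0.4, 0.4, 0.6, 0.6),
                cgINC = c(0.2, 0.2, 0.5, 0.5, 0.9, 0.9),
                cgTIE = c(0.5, 0.5, 0.5, 0.5, 0.4, 0.4))
  colnames(beta) <- co$sample_id
  out <- monotone_filter(beta, co, rownames(beta))
  expect_equal(out$locus_id, c("cgDEC", "cgINC"))
  expect_equal(out$direction, c("decreasing", "increasing"))
})

test_that("monotone filter is symmetric under group-order reversal", {
  set.seed(204)
  co <- make_cohort(rep(c("NC", "aMCI", "AD"), each = 3))
  rev_co <- co
  rev_co$group <- factor(rev(as.character(co$group)),
                         levels = c("NC", "aMCI", "AD"))
  beta <- matrix(runif(300 * 9), 300, 9,
                 dimnames = list(sprintf("cg%03d", 1:300), co$sample_id))
  fwd <- monotone_filter(beta, co, rownames(beta))
  bwd <- monotone_filter(beta, rev_co, rownames(beta))
  expect_setequal(fwd$locus_id, bwd$locus_id)
  m <- merge(fwd, bwd, by = "locus_id")
  expect_true(all(m$direction.x != m$direction.y))
})

test_that("annotation filters implement ANY-transcript promoter semantics", {
  man <- make_manifest(c("cgA", "cgB", "cgC", "cgD"))
  # cgA: the five-transcript promoter/island annotation pattern
  man$refgene_groups[[1]] <- c("1stExon", "TSS1500", "5'UTR", "5'UTR", "1stExon")
  man$accessions[[1]] <- sprintf("NM_%06d", 1:5)
  man$gene_names[[1]] <- rep("GENEA", 5)
  # cgB: gene body only -> dropped at the promoter stage
  man$refgene_groups[[2]] <- c("Body", "Body")
  man$accessions[[2]] <- sprintf("NM_%06d", 6:7)
  man$gene_names[[2]] <- rep("GENEB", 2)
  # cgC: promoter + Body mixture -> kept (any transcript qualifies)
  man$refgene_groups[[3]] <- c("Body", "1stExon")
  man$accessions[[3]] <- sprintf("NM_%06d", 8:9)
  man$gene_names[[3]] <- rep("GENEC", 2)
  # cgD: promoter but on a shore, not an island
  man$island_relation[4] <- "N_Shore"
  out <- annotation_filters(c("cgA", "cgB", "cgC", "cgD"), man)
  expect_setequal(out$stage3_accession, c("cgA", "cgB", "cgC", "cgD"))
  expect_setequal(out$stage4_promoter, c("cgA", "cgC", "cgD"))
  expect_setequal(out$stage5_island, c("cgA", "cgC"))
  expect_error(annotation_filters("cgZZ", man), "cgZZ")
})

test_that("funnel equals brute force and its stages nest, over random inputs", {
  set.seed(205)
  for (i in 1:8) {
    n_loci <- sample(c(40, 120, 200), 1)
    co <- make_cohort(rep(c("NC", "aMCI", "AD"), each = 4))
    ids <- sprintf("cg%04d", seq_len(n_loci))
    man <- make_manifest(ids,
                         is_cpg = runif(n_loci) < 0.9,
                         accession = runif(n_loci) < 0.7,
                         promoter = runif(n_loci) < 0.6,
                         island = runif(n_loci) < 0.5)
    beta <- matrix(runif(n_loci * 12), n_loci, 12,
                   dimnames = list(ids, co$sample_id))
    # plant a few separated loci so late stages are non-trivial
    strong <- sample(n_loci, 5)
    beta[strong, ] <- rep(c(0.8, 0.6, 0.4), each = 4)[col(beta[strong, ])] +
      rnorm(5 * 12, 0, 0.02)
    fr <- run_funnel(beta, co, man, alpha = 0.1)
    bf <- brute_force_funnel(beta, co, man, alpha = 0.1)
    expect_setequal(fr$stage1_common, bf$stage1)
    expect_setequal(fr$stage2_monotone$locus_id, bf$stage2)
    expect_setequal(fr$stage3_accession, bf$stage3)
    expect_setequal(fr$stage4_promoter, bf$stage4)
    expect_setequal(fr$stage5_island, bf$stage5)
    expect_true(all(fr$stage5_island %in% fr$stage4_promoter))
    expect_true(all(fr$stage4_promoter %in% fr$stage3_accession))
    expect_true(all(fr$stage3_accession %in% fr$stage2_monotone$locus_id))
    expect_true(all(fr$stage2_monotone$locus_id %in% fr$stage1_common))
    expect_true(all(fr$stage1_common %in% fr$cpg_set))
  }
})

test_that("funnel output is invariant to sample and locus permutations", {
  set.seed(206)
  co <- make_cohort(rep(c("NC", "aMCI", "AD"), each = 4))
  ids <- sprintf("cg%03d", 1:60)
  man <- make_manifest(ids, island = runif(60) < 0.5)
  beta <- matrix(runif(60 * 12), 60, 12, dimnames = list(ids, co$sample_id))
  beta[1, ] <- rep(c(0.8, 0.6, 0.4), each = 4) + rnorm(12, 0, 0.02)
  base <- run_funnel(beta, co, man, alpha = 0.1)
  perm_s <- sample(12); perm_l <- sample(60)
  shuf <- run_funnel(beta[perm_l, perm_s], co[sample(12), ], man, alpha = 0.1)
  expect_setequal(base$stage5_island, shuf$stage5_island)
  expect_setequal(base$stage1_common, shuf$stage1_common)
  expect_equal(sort(unname(base$counts)), sort(unname(shuf$counts)))
})
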