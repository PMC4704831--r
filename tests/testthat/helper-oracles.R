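# Independent oracles: textbook-formula implementations kept deliberately
# separate from the package's code paths, plus small fixture builders.

oracle_t_student <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  s2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(s2 * (1 / n1 + 1 / n2))
  list(t = tt, df = n1 + n2 - 2, p = 2 * pt(-abs(tt), n1 + n2 - 2),
       estimate = mean(x) - mean(y))
}

oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x) / n1; v2 <- var(y) / n2
  tt <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

oracle_anova <- function(samples) {
  y <- unlist(samples)
  k <- length(samples)
  n <- length(y)
  gm <- mean(y)
  ss_between <- sum(vapply(samples, function(s) length(s) * (mean(s) - gm)^2, 0))
  ss_within <- sum(vapply(samples, function(s) sum((s - mean(s))^2), 0))
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(F = f, df1 = k - 1, df2 = n - k, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), n - 2))
}

oracle_spearman_rho <- function(x, y) {
  oracle_pearson(rank(x), rank(y))$r
}

oracle_spearman_p_approx <- function(x, y) {
  n <- length(x)
  rho <- oracle_spearman_rho(x, y)
  if (abs(rho) >= 1) return(0)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tt), n - 2)
}

# exhaustive permutation p for |rho|, built on its own recursive
# enumeration and plain cor() calls
oracle_spearman_exact <- function(x, y) {
  all_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(all_perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  ps <- vapply(all_perms(ry), function(p) cor(rx, p), 0)
  mean(abs(ps) >= obs - 1e-9)
}

oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(x2 = x2, df = df, p = pchisq(x2, df, lower.tail = FALSE))
}

# ANCOVA by explicit normal equations on a hand-built design matrix
oracle_ancova <- function(y, g, age) {
  g <- factor(g)
  lv <- levels(g)
  X0 <- cbind(1, age)
  X1 <- cbind(1, age, vapply(lv[-1], function(l) as.numeric(g == l),
                             numeric(length(y))))
  bhat <- function(X) solve(t(X) %*% X, t(X) %*% y)
  rss <- function(X) { b <- bhat(X); sum((y - X %*% b)^2) }
  rss0 <- rss(X0); rss1 <- rss(X1)
  df1 <- length(lv) - 1
  df2 <- length(y) - ncol(X1)
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  b <- drop(bhat(X1))
  sigma2 <- rss1 / df2
  V <- sigma2 * solve(t(X1) %*% X1)
  adj <- vapply(seq_along(lv), function(i) {
    b[1] + b[2] * mean(age) + if (i == 1) 0 else b[i + 1]
  }, 0)
  names(adj) <- lv
  contrast_p <- function(i, j) {
    v <- numeric(length(b))
    if (i > 1) v[i + 1] <- 1
    if (j > 1) v[j + 1] <- -1
    d <- sum(v * b)
    tt <- d / sqrt(drop(t(v) %*% V %*% v))
    2 * pt(-abs(tt), df2)
  }
  list(F = f, p = pf(f, df1, df2, lower.tail = FALSE), adj = adj,
       slope = b[2], contrast_p = contrast_p, df2 = df2)
}

# quadratic brute-force funnel: per-locus loops over t.test() and
# explicit set logic, no shared code with the package implementation
brute_force_funnel <- function(beta, cohort, manifest, alpha = 0.05) {
  grp <- cohort$group[match(colnames(beta), cohort$sample_id)]
  cpg <- manifest$target_id[manifest$is_cpg]
  loci <- rownames(beta)[rownames(beta) %in% cpg]
  pairs <- list(c("NC", "aMCI"), c("NC", "AD"), c("aMCI", "AD"))
  sets <- lapply(pairs, function(pr) {
    keep <- character(0)
    for (l in loci) {
      x <- beta[l, grp == pr[1]]; y <- beta[l, grp == pr[2]]
      if (anyNA(x) || anyNA(y)) next
      p <- if (sd(x) == 0 && sd(y) == 0) {
        if (mean(x) == mean(y)) 1 else 0
      } else t.test(x, y, var.equal = TRUE)$p.value
      if (p < alpha) keep <- c(keep, l)
    }
    keep
  })
  stage1 <- sets[[1]][sets[[1]] %in% sets[[2]] & sets[[1]] %in% sets[[3]]]
  stage2 <- character(0)
  dir <- character(0)
  for (l in stage1) {
    m <- vapply(c("NC", "aMCI", "AD"),
                function(g) mean(beta[l, grp == g], na.rm = TRUE), 0)
    if (m[1] > m[2] && m[2] > m[3]) { stage2 <- c(stage2, l); dir <- c(dir, "decreasing") }
    else if (m[1] < m[2] && m[2] < m[3]) { stage2 <- c(stage2, l); dir <- c(dir, "increasing") }
  }
  idx <- match(stage2, manifest$target_id)
  acc <- lengths(manifest$accessions[idx]) > 0
  prom <- vapply(manifest$refgene_groups[idx], function(gr)
    any(gr %in% c("TSS1500", "TSS200", "5'UTR", "1stExon")), TRUE)
  isl <- manifest$island_relation[idx] == "Island"
  list(sets = setNames(sets, c("NC-aMCI", "NC-AD", "aMCI-AD")),
       stage1 = stage1, stage2 = stage2, direction = dir,
       stage3 = stage2[acc], stage4 = stage2[acc & prom],
       stage5 = stage2[acc & prom & isl])
}

# small hand-built fixtures -------------------------------------------------

make_cohort <- function(groups, ages = NULL, mmse = NULL, fab = NULL) {
  n <- length(groups)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = factor(groups, levels = c("NC", "aMCI", "AD")),
    age = ages %||% seq(65, 80, length.out = n),
    sex = factor(rep(c("F", "M"), length.out = n), levels = c("F", "M")),
    mmse = if (is.null(mmse)) rep(NA_integer_, n) else as.integer(mmse),
    fab = if (is.null(fab)) rep(NA_integer_, n) else as.integer(fab),
    apoe_a1 = rep("e3", n), apoe_a2 = rep("e3", n),
    duration_months = rep(NA_real_, n), onset_age = rep(NA_real_, n),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_manifest <- function(ids, is_cpg = TRUE, accession = TRUE,
                          promoter = TRUE, island = TRUE) {
  n <- length(ids)
  rec <- function(x) rep_len(x, n)
  is_cpg <- rec(is_cpg); accession <- rec(accession)
  promoter <- rec(promoter); island <- rec(island)
  out <- data.frame(target_id = ids, is_cpg = is_cpg,
                    island_relation = factor(ifelse(island, "Island", "N_Shore"),
                                             levels = c("Island", "N_Shore", "S_Shore",
                                                        "N_Shelf", "S_Shelf", "OpenSea")),
                    chromosome = rep("chr1", n), position = seq_len(n) * 100L,
                    stringsAsFactors = FALSE)
  out$gene_names <- lapply(seq_len(n), function(i) if (accession[i]) "GENE1" else character(0))
  out$accessions <- lapply(seq_len(n), function(i) if (accession[i]) "NM_000001" else character(0))
  out$refgene_groups <- lapply(seq_len(n), function(i) {
    if (!accession[i]) character(0) else if (promoter[i]) "TSS200" else "Body"
  })
  out
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
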