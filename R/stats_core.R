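# Statistical procedures used by the two-stage analysis, each behind a
# small uniform result type so the screening / validation modules can be
# checked against independent oracles in the test suite.  The fitting
# itself is delegated to base R (t.test, oneway.test, lm, cor.test,
# chisq.test); this module owns the contracts: input validation,
# degenerate-case conventions, and the derived quantities (adjusted
# means, contrasts, exact Spearman permutation p).

new_test_result <- function(statistic, df, p_value, estimate, method, n) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), estimate = unname(estimate),
                 method = method, n = n),
            class = "mf_test")
}

#' @export
print.mf_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g, estimate = %.4g (n = %s)\n",
              x$method, x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value, x$estimate, paste(x$n, collapse = "+")))
  invisible(x)
}

#' Unpaired two-sample t-test
#'
#' Student's pooled-variance t-test by default (the convention for the
#' two-group methylation comparisons here), or Welch's test when
#' `equal_variance = FALSE`.  Missing values are dropped per sample.
#'
#' @param x,y Numeric samples (>= 2 non-missing values each).
#' @param equal_variance Pool the variances (Student) or not (Welch).
#' @return An `mf_test` with `statistic` (t), `df`, two-sided `p_value`
#'   and `estimate` = mean(x) - mean(y).
#' @export
#' @examples
#' t_test_unpaired(c(1, 2, 3, 4), c(5, 6, 7, 8))
t_test_unpaired <- function(x, y, equal_variance = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop_mf("t test needs >= 2 non-missing values per sample (got %d and %d)",
            length(x), length(y))
  if (sd(x) == 0 && sd(y) == 0) {
    # degenerate zero-variance conventions: identical constants carry no
    # evidence (t = 0, p = 1); distinct constants are infinitely separated
    d <- mean(x) - mean(y)
    return(new_test_result(if (d == 0) 0 else sign(d) * Inf,
                           length(x) + length(y) - 2,
                           if (d == 0) 1 else 0, d,
                           "unpaired t test", c(length(x), length(y))))
  }
  tt <- t.test(x, y, var.equal = equal_variance)
  new_test_result(tt$statistic, tt$parameter, tt$p.value,
                  mean(x) - mean(y),
                  if (equal_variance) "unpaired t test" else "Welch t test",
                  c(length(x), length(y)))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA.  When every observation is
#' identical the F ratio is 0/0; the documented convention is `F = 0,
#' p = 1` (no evidence of group differences) so that pipelines stay
#' robust on degenerate simulated loci.
#'
#' @param samples List of numeric vectors, one per group (>= 2 groups,
#'   >= 2 non-missing values each).
#' @return An `mf_test` with `statistic` (F), `df` = c(numerator,
#'   denominator), `p_value`, and `estimate` = F.
#' @export
one_way_anova <- function(samples) {
  stopifnot(is.list(samples))
  samples <- lapply(samples, function(s) s[!is.na(s)])
  if (length(samples) < 2) stop_mf("ANOVA needs >= 2 groups")
  if (any(lengths(samples) < 2))
    stop_mf("ANOVA needs >= 2 non-missing values per group")
  y <- unlist(samples, use.names = FALSE)
  g <- factor(rep(seq_along(samples), lengths(samples)))
  df1 <- length(samples) - 1
  df2 <- length(y) - length(samples)
  if (all(y == y[1]))
    return(new_test_result(0, c(df1, df2), 1, 0, "one-way ANOVA", lengths(samples)))
  ow <- oneway.test(y ~ g, var.equal = TRUE)
  new_test_result(ow$statistic, unname(ow$parameter), ow$p.value,
                  unname(ow$statistic), "one-way ANOVA", lengths(samples))
}

#' ANCOVA: one factor, one continuous covariate
#'
#' Fits `value ~ age + group` by least squares and reports the
#' extra-sum-of-squares F for the group factor over the age-only model,
#' group means adjusted to the grand mean of the covariate, and pairwise
#' contrasts of adjusted means using the model residual variance.  This
#' is the age-adjusted three-group comparison used at the validation
#' stage.
#'
#' @param values Numeric response, one per subject.
#' @param groups Group labels, one per subject (>= 3 subjects per group).
#' @param ages Covariate, one per subject; must have no missing values
#'   (the covariate is mandatory) and must vary.
#' @param p_adjust Multiplicity adjustment for the contrasts, as in
#'   [stats::p.adjust()]; `"none"` (default) mirrors per-pair reporting
#'   without correction.
#' @return An `mf_ancova` list: `adjusted_group_means`, `covariate_slope`,
#'   `group_F`, `group_df` (numerator, denominator), `group_p`,
#'   `contrasts` (data frame: pair, difference of adjusted means, t, p),
#'   `n`, `residual_df`.
#' @export
#' @examples
#' g <- rep(c("NC", "aMCI", "AD"), each = 10)
#' age <- rnorm(30, 70, 5)
#' y <- c(NC = 60, aMCI = 40, AD = 45)[g] + 0.1 * age + rnorm(30, 0, 5)
#' ancova_group_age(y, g, age)
ancova_group_age <- function(values, groups, ages, p_adjust = "none") {
  if (anyNA(ages))
    stop_mf("ANCOVA covariate (age) has missing values; the covariate is mandatory")
  keep <- !is.na(values)
  values <- values[keep]; ages <- ages[keep]
  g <- factor(as.character(groups)[keep],
              levels = intersect(GROUP_LEVELS, as.character(groups)))
  if (nlevels(g) == 0 || any(is.na(g))) g <- factor(as.character(groups)[keep])
  g <- droplevels(g)
  if (nlevels(g) < 2) stop_mf("ANCOVA needs >= 2 groups")
  tab <- table(g)
  if (any(tab < 3))
    stop_mf("ANCOVA needs >= 3 subjects per group (group '%s' has %d)",
            names(tab)[which.min(tab)], min(tab))
  if (var(ages) == 0)
    stop_mf("singular design: covariate 'age' is constant")

  d <- data.frame(y = values, g = g, age = ages)
  fit0 <- lm(y ~ age, data = d)
  fit1 <- lm(y ~ age + g, data = d)
  if (any(is.na(coef(fit1))))
    stop_mf("singular design: term '%s' is collinear",
            names(coef(fit1))[is.na(coef(fit1))][1])
  an <- anova(fit0, fit1)
  group_F <- an$F[2]
  group_p <- an$`Pr(>F)`[2]
  # perfect covariate fit: both the extra group sum of squares and the
  # residual sum of squares vanish to round-off, so the F ratio is 0/0
  # noise; taken as no group evidence by convention
  scale <- max(1, sum(values^2))
  if (sum(fit1$residuals^2) < 1e-10 * scale &&
      abs(an$`Sum of Sq`[2]) < 1e-10 * scale) {
    group_F <- 0; group_p <- 1
  }
  if (!is.finite(group_F)) { group_F <- NaN; group_p <- NaN }
  grand_age <- mean(ages)
  lv <- levels(g)
  adj <- predict(fit1, newdata = data.frame(g = factor(lv, levels = lv),
                                            age = grand_age))
  names(adj) <- lv

  # contrasts: difference of adjusted means = difference of group coefs
  # (suppress the perfect-fit note; the zero-residual case is handled above)
  V <- suppressWarnings(vcov(fit1))
  cf <- coef(fit1)
  coef_of <- function(lev) {         # group coefficient vector in coef space
    v <- numeric(length(cf)); names(v) <- names(cf)
    nm <- paste0("g", lev)
    if (nm %in% names(cf)) v[nm] <- 1
    v
  }
  rdf <- fit1$df.residual
  pairs <- utils::combn(lv, 2)
  contrasts <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    difference = NA_real_, t = NA_real_, p = NA_real_,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(ncol(pairs))) {
    v <- coef_of(pairs[1, k]) - coef_of(pairs[2, k])
    diff <- sum(v * cf)
    se <- sqrt(drop(t(v) %*% V %*% v))
    tval <- diff / se
    contrasts$difference[k] <- diff
    contrasts$t[k] <- tval
    contrasts$p[k] <- 2 * pt(-abs(tval), rdf)
  }
  contrasts$p <- p.adjust(contrasts$p, method = p_adjust)

  structure(list(
    adjusted_group_means = adj,
    covariate_slope = unname(cf["age"]),
    group_F = group_F,
    group_df = c(numerator = an$Df[2], denominator = rdf),
    group_p = group_p,
    contrasts = contrasts,
    n = length(values),
    residual_df = rdf
  ), class = "mf_ancova")
}

#' @export
print.mf_ancova <- function(x, ...) {
  cat(sprintf("ANCOVA (age-adjusted): F(%d, %d) = %.4g, p = %.4g; slope = %.4g\n",
              x$group_df[1], x$group_df[2], x$group_F, x$group_p,
              x$covariate_slope))
  cat("adjusted means:",
      paste(sprintf("%s = %.3f", names(x$adjusted_group_means),
                    x$adjusted_group_means), collapse = ", "), "\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

# All permutations of 1..n as an n! x n integer matrix (n <= 9).
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- perm_matrix(n - 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    q <- p + (p >= i)           # remap 1..n-1 to 1..n skipping i
    out[[i]] <- cbind(rep(i, nrow(q)), q, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Spearman rank correlation
#'
#' Rank correlation with ties handled by average ranks.  The two-sided
#' p-value uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` by
#' default; for small samples (n <= 9) `exact = TRUE` computes the exact
#' permutation p-value by full enumeration of the n! rank assignments —
#' relevant at the discovery-stage sample sizes (n = 8 scored subjects,
#' n = 6 with both scores).
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @param exact Use the exact permutation p-value (requires n <= 9).
#' @return An `mf_test` with `estimate` = rho.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop_mf("Spearman correlation needs >= 3 complete pairs (got %d)", n)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop_mf("Spearman correlation undefined: zero variance in ranks")
  rho <- cor(rx, ry)
  rho <- clamp(rho, -1, 1)
  if (exact) {
    if (n > 9) stop_mf("exact Spearman p only available for n <= 9 (got %d)", n)
    perms <- perm_matrix(n)
    ry_perm <- matrix(ry[perms], nrow(perms))
    s <- as.vector(ry_perm %*% rx)
    # rho is an increasing affine function of s given the fixed rank
    # multisets, so compare on s-scale distances from its null mean
    s_obs <- sum(rx * ry)
    mu <- mean(s)
    p <- mean(abs(s - mu) >= abs(s_obs - mu) - 1e-9)
    return(new_test_result(s_obs, n - 2, p, rho,
                           "Spearman rank correlation (exact)", n))
  }
  if (abs(rho) == 1) {
    tstat <- sign(rho) * Inf
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  new_test_result(tstat, n - 2, p, rho, "Spearman rank correlation", n)
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r with a two-sided p-value from the t approximation,
#' used for cross-platform (array vs pyrosequencing) concordance.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @return An `mf_test` with `estimate` = r.
#' @export
pearson_cor <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop_mf("Pearson correlation needs >= 3 complete pairs (got %d)", n)
  if (sd(x) == 0 || sd(y) == 0)
    stop_mf("Pearson correlation undefined: zero variance")
  ct <- cor.test(x, y, method = "pearson")
  new_test_result(ct$statistic, ct$parameter, ct$p.value, ct$estimate,
                  "Pearson correlation", n)
}

#' Chi-square test of independence
#'
#' Pearson's chi-square on a contingency table of counts, expected counts
#' from the marginal products; no continuity correction by default.
#'
#' @param tab Matrix of non-negative integer counts (>= 2x2); all row and
#'   column marginals must be positive.
#' @param correct Apply Yates continuity correction (2x2 only).
#' @return An `mf_test` with `statistic` (chi-square), `df` =
#'   (rows-1)(cols-1).
#' @export
chi_square_independence <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop_mf("chi-square table needs >= 2 rows and >= 2 columns")
  if (any(tab < 0) || any(tab != round(tab)))
    stop_mf("chi-square table must hold non-negative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_mf("chi-square table has a zero marginal")
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  new_test_result(ct$statistic, ct$parameter, ct$p.value, ct$statistic,
                  "chi-square test of independence", sum(tab))
}
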