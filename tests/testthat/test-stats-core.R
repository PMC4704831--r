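test_that("t-test matches the pooled-variance formula oracle", {
  set.seed(101)
  for (i in 1:50) {
    x <- rnorm(4); y <- rnorm(4, 0.5)
    got <- t_test_unpaired(x, y)
    exp <- oracle_t_student(x, y)
    expect_equal(got$statistic, exp$t, tolerance = 1e-10)
    expect_equal(got$p_value, exp$p, tolerance = 1e-10)
    expect_equal(got$estimate, exp$estimate, tolerance = 1e-12)
    w <- t_test_unpaired(x, y, equal_variance = FALSE)
    ew <- oracle_welch(x, y)
    expect_equal(w$statistic, ew$t, tolerance = 1e-10)
    expect_equal(w$df, ew$df, tolerance = 1e-10)
  }
})

test_that("t-test degenerate and shift cases behave as documented", {
  x <- c(1, 2, 3)
  same <- t_test_unpaired(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  shifted <- t_test_unpaired(x, x + 10)
  expect_lt(shifted$p_value, 0.001)
  expect_equal(shifted$estimate, -10)
  expect_error(t_test_unpaired(1, c(1, 2)), ">= 2")
  expect_equal(t_test_unpaired(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(t_test_unpaired(c(3, 3), c(2, 2))$p_value, 0)
})

test_that("one-way ANOVA matches sums-of-squares oracle; F = t^2 with 2 groups", {
  set.seed(102)
  for (i in 1:30) {
    samples <- lapply(1:3, function(k) rnorm(sample(3:8, 1), mean = k / 4))
    got <- one_way_anova(samples)
    exp <- oracle_anova(samples)
    expect_equal(got$statistic, exp$F, tolerance = 1e-10)
    expect_equal(got$p_value, exp$p, tolerance = 1e-10)
    expect_equal(unname(got$df), c(exp$df1, exp$df2))
  }
  x <- rnorm(6); y <- rnorm(5, 1)
  aov2 <- one_way_anova(list(x, y))
  tt <- t_test_unpaired(x, y)
  expect_equal(aov2$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(aov2$p_value, tt$p_value, tolerance = 1e-10)
  # all-constant convention
  const <- one_way_anova(list(c(2, 2), c(2, 2, 2)))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
})

test_that("ANCOVA matches the normal-equations oracle", {
  set.seed(103)
  for (i in 1:20) {
    n <- c(8, 7, 9)
    g <- rep(c("NC", "aMCI", "AD"), n)
    age <- rnorm(sum(n), 70, 5)
    y <- c(NC = 0, aMCI = -0.2, AD = -0.18)[g] - 0.002 * age + rnorm(sum(n), 0, 0.1)
    got <- ancova_group_age(y, g, age)
    exp <- oracle_ancova(y, factor(g, levels = c("NC", "aMCI", "AD")), age)
    expect_equal(got$group_F, exp$F, tolerance = 1e-8)
    expect_equal(got$group_p, exp$p, tolerance = 1e-8)
    expect_equal(got$covariate_slope, unname(exp$slope), tolerance = 1e-8)
    expect_equal(unname(got$adjusted_group_means), unname(exp$adj), tolerance = 1e-8)
    expect_equal(got$contrasts$p[got$contrasts$group1 == "NC" &
                                   got$contrasts$group2 == "AD"],
                 exp$contrast_p(1, 3), tolerance = 1e-8)
  }
})

test_that("ANCOVA recovers a pure covariate signal and validates its design", {
  set.seed(104)
  age <- rnorm(30, 70, 5)
  g <- sample(c("NC", "aMCI", "AD"), 30, replace = TRUE, prob = c(1, 1, 1))
  while (min(table(g)) < 3) g <- sample(c("NC", "aMCI", "AD"), 30, replace = TRUE)
  y <- 2 * age
  fit <- ancova_group_age(y, g, age)
  expect_equal(fit$covariate_slope, 2.0, tolerance = 1e-10)
  expect_gt(fit$group_p, 0.99)
  expect_equal(unname(fit$group_df),
               c(length(unique(g)) - 1, 30 - length(unique(g)) - 1))
  expect_error(ancova_group_age(y, g, rep(70, 30)), "constant")
  expect_error(ancova_group_age(y, g, replace(age, 1, NA)), "missing")
  expect_error(ancova_group_age(y[1:7], rep(c("NC", "AD"), c(2, 5))[1:7],
                                age[1:7]), ">= 3 subjects")
})

test_that("ANCOVA group F tracks one-way ANOVA when the covariate is null", {
  set.seed(105)
  diffs <- replicate(100, {
    g <- rep(c("NC", "aMCI", "AD"), each = 8)
    age <- rnorm(24, 70, 5)           # independent of y
    y <- rnorm(24) + c(NC = 0, aMCI = 0.5, AD = 1)[g]
    a1 <- ancova_group_age(y, g, age)$group_F
    a0 <- one_way_anova(split(y, g))$statistic
    (a1 - a0) / a0
  })
  expect_lt(abs(mean(diffs)), 0.15)   # agree up to Monte-Carlo noise
})

test_that("Spearman matches rank-formula and exhaustive-permutation oracles", {
  set.seed(106)
  for (i in 1:40) {
    x <- rnorm(8); y <- rnorm(8)
    got <- spearman_cor(x, y)
    expect_equal(got$estimate, oracle_spearman_rho(x, y), tolerance = 1e-10)
    expect_equal(got$p_value, oracle_spearman_p_approx(x, y), tolerance = 1e-10)
  }
  expect_equal(spearman_cor(1:6, c(2, 4, 5, 7, 8, 9))$estimate, 1)
  expect_equal(spearman_cor(1:6, -(1:6))$estimate, -1)
  expect_error(spearman_cor(1:5, rep(1, 5)), "zero variance")

  # exact permutation p, n = 7 with a tie, vs brute-force enumeration
  x <- c(1, 2, 3, 4, 5, 6, 7)
  y <- c(2, 1, 4, 4, 6, 5, 7)
  got <- spearman_cor(x, y, exact = TRUE)
  expect_equal(got$p_value, oracle_spearman_exact(x, y), tolerance = 1e-12)
  expect_equal(got$estimate, oracle_spearman_rho(x, y), tolerance = 1e-12)
  expect_error(spearman_cor(rnorm(10), rnorm(10), exact = TRUE), "n <= 9")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(107)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    base <- spearman_cor(x, y)$estimate
    expect_equal(spearman_cor(exp(x), y)$estimate, base)
    expect_equal(spearman_cor(x, y^3 + 5 * y)$estimate, base)
    expect_equal(spearman_cor(-1 / (1 + exp(-x)), y)$estimate, -base)
  }
})

test_that("Pearson matches the covariance-formula oracle", {
  set.seed(108)
  for (i in 1:30) {
    x <- rnorm(12); y <- rnorm(12)
    got <- pearson_cor(x, y)
    exp <- oracle_pearson(x, y)
    expect_equal(got$estimate, exp$r, tolerance = 1e-12)
    expect_equal(got$p_value, exp$p, tolerance = 1e-12)
  }
  expect_equal(pearson_cor(1:5, 3 * (1:5) + 1)$estimate, 1)
  expect_equal(pearson_cor(1:5, -(1:5))$estimate, -1)
  expect_error(pearson_cor(1:5, rep(2, 5)), "zero variance")
})

test_that("chi-square matches the direct formula, including the hand case", {
  flat <- chi_square_independence(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  hand <- chi_square_independence(rbind(c(20, 10), c(10, 20)))
  expect_equal(hand$statistic, 20 / 3, tolerance = 1e-10)   # E = 15 everywhere
  expect_equal(unname(hand$df), 1)
  set.seed(109)
  for (i in 1:30) {
    tab <- matrix(sample(1:30, 6), 2, 3)
    got <- chi_square_independence(tab)
    exp <- oracle_chisq(tab)
    expect_equal(got$statistic, exp$x2, tolerance = 1e-12)
    expect_equal(got$p_value, exp$p, tolerance = 1e-12)
  }
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "zero marginal")
})

test_that("test statistics are invariant to sample reordering", {
  set.seed(110)
  x <- rnorm(9); y <- rnorm(7)
  perm <- sample(9)
  expect_equal(t_test_unpaired(x, y)$statistic,
               t_test_unpaired(x[perm], y)$statistic)
  expect_equal(spearman_cor(x[1:7], y)$estimate,
               spearman_cor(x[1:7][order(y)], y[order(y)])$estimate)
})
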