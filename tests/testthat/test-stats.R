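test_that("a perfect linear relation gives r = 1 and the boundary p = 0", {
  x <- 1:10
  res <- pearsonRP(x, 2 * x + 1)
  expect_equal(statistic(res), 1)
  expect_equal(pValue(res), 0)
  expect_error(pearsonRP(x, rep(2, 10)), "constant")
  expect_error(pearsonRP(1:5, 1:4), "equal length")
})

test_that("the r-to-p transform is symmetric in sign and null at r = 0", {
  expect_equal(pValue(pFromRN(0, 30)), 1)
  for (r in c(0.2, 0.5, 0.8))
    expect_equal(pValue(pFromRN(r, 25)), pValue(pFromRN(-r, 25)))
  expect_error(pFromRN(0.5, 2), "n >= 3")
  ## boundary |r| >= 1 flagged, not an error
  b <- pFromRN(1, 10)
  expect_equal(pValue(b), 0)
  expect_match(paste(b@methodNotes, collapse = " "), "boundary")
})

test_that("pearsonRP agrees with cor.test and with its permutation oracle", {
  set.seed(23)
  x <- rnorm(20); y <- 0.4 * x + rnorm(20)
  res <- pearsonRP(x, y)
  ct <- cor.test(x, y)
  expect_equal(statistic(res), unname(ct$estimate))
  expect_equal(pValue(res), ct$p.value, tolerance = 1e-10)
  perm <- permutationPearsonP(x, y, nPerm = 10000, seed = 1)
  mcSe <- sqrt(pValue(perm) * (1 - pValue(perm)) / 10000)
  expect_lt(abs(pValue(res) - pValue(perm)), 3 * mcSe)
})

test_that("raw-data and summary-statistics t tests coincide", {
  set.seed(8)
  a <- rnorm(14, 10, 2); b <- rnorm(13, 8, 3)
  for (mode in c("pooled", "welch")) {
    raw <- tTestIndependent(a, b, mode = mode)
    summ <- tTestFromSummary(mean(a), sd(a), 14, mean(b), sd(b), 13,
                             mode = mode)
    expect_equal(statistic(summ), statistic(raw), tolerance = 1e-12)
    expect_equal(pValue(summ), pValue(raw), tolerance = 1e-12)
    expect_equal(summ@df, raw@df, tolerance = 1e-12)
  }
})

test_that("degenerate and trivial t-test cases behave", {
  g <- c(1, 2, 3)
  same <- tTestIndependent(g, g)
  expect_equal(statistic(same), 0)
  expect_equal(pValue(same), 1)
  const <- tTestIndependent(c(2, 2), c(2, 2))
  expect_equal(pValue(const), 1)
  expect_match(paste(const@methodNotes, collapse = " "), "degenerate")
  expect_equal(statistic(tTestFromSummary(5, 1, 10, 5, 3, 12)), 0)
  ## consistency: a real shift at large n is detected at any fixed level
  set.seed(1)
  expect_lt(pValue(tTestIndependent(rnorm(500), rnorm(500) + 0.5)), 1e-6)
  expect_error(tTestIndependent(1, c(1, 2)), "n >= 2")
})

test_that("2x2 chi-square matches the closed-form expected-count oracle", {
  set.seed(33)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 12) + 1, 2)
    res <- chi2Test2x2(tab)
    n <- sum(tab)
    oracle <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
      prod(rowSums(tab)) / prod(colSums(tab))
    expect_equal(statistic(res), oracle, tolerance = 1e-12)
    expect_equal(pValue(res), pchisq(oracle, 1, lower.tail = FALSE))
  }
  prop <- matrix(c(10, 20, 5, 10), 2)     # proportional rows
  expect_equal(statistic(chi2Test2x2(prop)), 0)
  expect_equal(pValue(chi2Test2x2(prop)), 1)
  expect_error(chi2Test2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "marginal")
})

test_that("two-group ANOVA F equals the squared pooled t", {
  set.seed(3)
  a <- rnorm(15); b <- rnorm(12, 0.8)
  f <- anovaOneway(list(a = a, b = b))
  t <- tTestIndependent(a, b, mode = "pooled")
  expect_equal(statistic(f), statistic(t)^2, tolerance = 1e-10)
  expect_equal(pValue(f), pValue(t), tolerance = 1e-10)
})

test_that("identical groups give F = 0, p = 1 and unit post hoc p-values", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  f <- anovaOneway(g)
  expect_equal(statistic(f), 0)
  expect_equal(pValue(f), 1)
  for (meth in c("games_howell", "bonferroni"))
    expect_true(all(posthocPairwise(g, method = meth)$p == 1))
  expect_error(anovaOneway(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("Levene's test detects a 4-fold SD ratio with high power", {
  set.seed(6)
  rejections <- vapply(1:300, function(i) {
    g <- list(a = rnorm(50, 0, 1), b = rnorm(50, 0, 4), c = rnorm(50, 0, 1))
    pValue(leveneHomogeneity(g)) < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.9)
  ## equal spreads: p roughly uniform, so usually not significant
  g0 <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  expect_true(pValue(leveneHomogeneity(g0)) >= 0)
})

test_that("Games-Howell matches Tukey HSD under equal variances and n", {
  set.seed(44)
  g <- list(a = rnorm(40, 0), b = rnorm(40, 0.5), c = rnorm(40, 1))
  gh <- posthocPairwise(g, method = "games_howell")
  df <- data.frame(y = unlist(g), grp = factor(rep(names(g), each = 40)))
  tk <- TukeyHSD(aov(y ~ grp, data = df))$grp
  ## same pair order: b-a, c-a, c-b
  ## GH uses Welch df, Tukey pooled df: agreement is approximate
  expect_lt(max(abs(gh$p - unname(tk[, "p adj"]))), 0.03)
})

test_that("the auto post hoc gate follows Levene's verdict", {
  set.seed(10)
  het <- list(a = rnorm(60, 0, 1), b = rnorm(60, 0, 5), c = rnorm(60, 0.2, 1))
  expect_identical(unique(posthocPairwise(het, method = "auto")$method),
                   "games_howell")
  hom <- list(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  ## equal variances: overwhelmingly routed to Bonferroni
  expect_identical(unique(posthocPairwise(hom, method = "auto")$method),
                   "bonferroni")
})

test_that("Bonferroni post hoc p-values are the pairwise p times the pair count", {
  set.seed(2)
  g <- list(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10, 2))
  bp <- posthocPairwise(g, method = "bonferroni")
  pw <- pValue(tTestIndependent(g$a, g$b, mode = "pooled"))
  expect_equal(bp$p[bp$group1 == "a" & bp$group2 == "b"], min(1, pw * 3))
})
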