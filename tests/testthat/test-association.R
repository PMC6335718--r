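test_that("Pearson chi-square reproduces published values and the base oracle", {
  # brachydactylia by grade and ATR by grade, as printed
  expect_equal(pearson_chi2(contingency_2x2(3, 27, 49, 1))$chi2, 63.82,
               tolerance = 0.02 / 63.82)
  expect_equal(pearson_chi2(contingency_2x2(3, 27, 33, 17))$chi2, 23.76,
               tolerance = 0.02 / 23.76)
  expect_equal(pearson_chi2(contingency_2x2(5, 5, 5, 5))$chi2, 0)
  # cross-check formula and p against stats::chisq.test on random tables
  set.seed(17)
  for (i in 1:25) {
    cells <- stats::rpois(4, 12) + 1
    tab <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    ref <- suppressWarnings(stats::chisq.test(as.matrix(tab), correct = FALSE))
    got <- pearson_chi2(tab)
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    refy <- suppressWarnings(stats::chisq.test(as.matrix(tab), correct = TRUE))
    expect_equal(pearson_chi2(tab, correct = TRUE)$chi2,
                 unname(refy$statistic), tolerance = 1e-12)
  }
})

test_that("chi-square validity tracks margins, not cells", {
  # zero cell, positive margins: still computed (printed CSGALNACT row)
  tab <- contingency_2x2(18, 0, 52, 10)
  got <- pearson_chi2(tab)
  expect_true(got$valid)
  expect_equal(got$chi2, 3.31, tolerance = 0.02 / 3.31)
  # zero cell with positive margins is still valid (the dash in the published
  # astriction row reflects an exact-test choice, not a zero margin)
  expect_true(pearson_chi2(contingency_2x2(2, 28, 0, 50))$valid)
  # zero margin: invalid, statistic omitted
  expect_false(pearson_chi2(contingency_2x2(0, 28, 0, 50))$valid)
})

test_that("chi-square is invariant under transposition and row+column swaps", {
  set.seed(23)
  for (i in 1:10) {
    cells <- stats::rpois(4, 9) + 1
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    base <- pearson_chi2(contingency_2x2(a, b, c, d))$chi2
    expect_equal(pearson_chi2(contingency_2x2(a, c, b, d))$chi2, base)
    expect_equal(pearson_chi2(contingency_2x2(d, c, b, a))$chi2, base)
  }
})

test_that("Fisher exact agrees with brute-force enumeration and fisher.test", {
  set.seed(29)
  cases <- list(c(2, 28, 0, 50), c(0, 30, 4, 46), c(3, 27, 49, 1),
                c(10, 10, 10, 10))
  for (i in 1:15) cases[[length(cases) + 1]] <- stats::rpois(4, 10)
  for (cl in cases) {
    if (sum(cl) == 0) next
    tab <- contingency_2x2(cl[1], cl[2], cl[3], cl[4])
    got <- fisher_exact(tab)
    m <- table_margins(tab)
    if (any(m$row == 0) || any(m$col == 0)) {
      expect_equal(got$p_one_sided, 1)
      next
    }
    ora <- fisher_enumerate(cl[1], cl[2], cl[3], cl[4])
    expect_equal(got$p_one_sided, ora$one_sided, tolerance = 1e-12)
    expect_equal(got$p_two_sided_doubling, ora$doubling, tolerance = 1e-12)
    expect_equal(got$p_two_sided_sum_small, ora$sum_small, tolerance = 1e-12)
    # the sum-of-small-probabilities variant is fisher.test's convention
    ref <- stats::fisher.test(as.matrix(tab))
    expect_equal(got$p_two_sided_sum_small, ref$p.value, tolerance = 1e-9)
  }
})

test_that("published dash-row Fisher p-values are reproduced", {
  # one-sided tail: C(30,2)C(50,0)/C(80,2) + ... frozen from enumeration
  astriction <- fisher_exact(contingency_2x2(2, 28, 0, 50))
  expect_equal(astriction$p_one_sided, 0.1376582, tolerance = 1e-6)
  expect_equal(round(astriction$p_one_sided, 3), 0.138)
  alcohol <- fisher_exact(contingency_2x2(0, 30, 4, 46))
  expect_equal(alcohol$p_two_sided_doubling, 0.2912278, tolerance = 1e-6)
  expect_equal(round(alcohol$p_two_sided_doubling, 3), 0.291)
  # degenerate margin: only one table possible
  degenerate <- fisher_exact(contingency_2x2(0, 0, 5, 7))
  expect_equal(degenerate$p_two_sided_doubling, 1)
})

test_that("Woolf odds ratios and intervals match printed precision", {
  # grade-oriented brachydactylia row: OR 441.0 (43.7 - 4449)
  tab <- contingency_2x2(3, 27, 49, 1, or_numerator = "row2")
  orw <- odds_ratio_woolf(tab)
  expect_equal(orw$or, 441.0, tolerance = 1e-6)
  expect_equal(orw$ci_low, 43.7, tolerance = 0.1 / 43.7)
  expect_equal(orw$ci_high, 4449, tolerance = 1.5 / 4449)
  # gene-oriented FZD1 row: OR 16.0
  fzd <- odds_ratio_woolf(contingency_2x2(56, 2, 14, 8,
                                          or_numerator = "row1"))
  expect_equal(fzd$or, 16.0, tolerance = 1e-12)
  expect_equal(fzd$ci_low, 3.05, tolerance = 0.015 / 3.05)
  expect_equal(fzd$ci_high, 83.85, tolerance = 0.2 / 83.85)
  # balanced table: OR 1, CI symmetric on the log scale
  bal <- odds_ratio_woolf(contingency_2x2(10, 10, 10, 10))
  expect_equal(bal$or, 1)
  expect_equal(log(bal$ci_high), -log(bal$ci_low), tolerance = 1e-12)
})

test_that("a zero cell renders the OR undefined unless Haldane is requested", {
  tab <- contingency_2x2(18, 0, 52, 10, or_numerator = "row1")
  expect_false(odds_ratio_woolf(tab)$defined)
  hal <- odds_ratio_woolf(tab, haldane = TRUE)
  expect_true(hal$defined)
  expect_gt(hal$or, 1)
})

test_that("a row swap inverts the OR and mirrors the CI", {
  set.seed(31)
  for (i in 1:10) {
    cells <- stats::rpois(4, 10) + 1
    tab <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    a <- odds_ratio_woolf(tab)
    b <- odds_ratio_woolf(swap_rows(tab))
    expect_equal(b$or, 1 / a$or, tolerance = 1e-12)
    expect_equal(b$ci_low, 1 / a$ci_high, tolerance = 1e-12)
    expect_equal(b$ci_high, 1 / a$ci_low, tolerance = 1e-12)
  }
})

test_that("Woolf intervals cover a known true odds ratio at near-nominal rate", {
  set.seed(37)
  n_rep <- 10000
  p1 <- 0.30
  true_or <- 3
  odds2 <- true_or * p1 / (1 - p1)
  p2 <- odds2 / (1 + odds2)
  a <- stats::rbinom(n_rep, 100, p2); b <- 100 - a
  c <- stats::rbinom(n_rep, 100, p1); d <- 100 - c
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  z <- stats::qnorm(0.975)
  lo <- exp(log(a * d / (b * c)) - z * sqrt(1 / a + 1 / b + 1 / c + 1 / d))
  hi <- exp(log(a * d / (b * c)) + z * sqrt(1 / a + 1 / b + 1 / c + 1 / d))
  coverage <- mean(lo[ok] <= true_or & hi[ok] >= true_or)
  expect_gte(coverage, 0.93)
  expect_lte(coverage, 0.97)
  # spot-check the vectorised simulation against the package function
  tab <- contingency_2x2(a[1], b[1], c[1], d[1], or_numerator = "row1")
  orw <- odds_ratio_woolf(tab)
  expect_equal(orw$ci_low, lo[1], tolerance = 1e-9)
  expect_equal(orw$ci_high, hi[1], tolerance = 1e-9)
})

test_that("Mann-Whitney U handles symmetry, separation and ties", {
  x <- c(1, 2, 3, 4)
  same <- mann_whitney_u(x, x)
  expect_equal(same$U, length(x)^2 / 2)
  expect_equal(same$Z, 0)
  expect_equal(same$p, 1)
  sep <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(sep$U, 0)
  expect_lt(sep$Z, 0)
  # tie-corrected normal p matches wilcox.test's approximation
  set.seed(43)
  for (i in 1:10) {
    a <- sample(1:6, 15, replace = TRUE)
    b <- sample(2:8, 12, replace = TRUE)
    got <- mann_whitney_u(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = FALSE))
    expect_equal(got$U, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  ident <- mann_whitney_u(rep(2, 5), rep(2, 7))
  expect_equal(ident$Z, 0); expect_equal(ident$p, 1)
})

test_that("rank test holds its nominal level under the null", {
  set.seed(47)
  n_rep <- 2000
  rej <- mean(replicate(n_rep, {
    mann_whitney_u(stats::rnorm(20), stats::rnorm(20))$p < 0.05
  }))
  expect_gt(rej, 0.033)
  expect_lt(rej, 0.068)
})

test_that("Pearson correlation matches hand computation and rejects degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  # frozen from covariance/SD arithmetic: cov = 4/3, sd^2 = 5/3 each
  got <- pearson_correlation(x, c(1, 3, 2, 4))
  expect_equal(got$r, 0.8, tolerance = 1e-12)
  expect_equal(got$p, stats::cor.test(x, c(1, 3, 2, 4))$p.value)
  expect_error(pearson_correlation(x, rep(2, 4)), "variance")
  expect_error(pearson_correlation(c(1, 2), c(3, 4)), "3 complete pairs")
  # pairwise deletion
  expect_equal(pearson_correlation(c(x, NA), c(2 * x + 1, 5))$n, 4)
})

test_that("correlation test holds its nominal level under independence", {
  set.seed(53)
  rej <- mean(replicate(2000, {
    pearson_correlation(stats::rnorm(30), stats::rnorm(30))$p < 0.05
  }))
  expect_gt(rej, 0.033)
  expect_lt(rej, 0.068)
})

test_that("group comparison battery: identities and the normality gate", {
  g1 <- c(5.1, 4.9, 5.3, 5.0, 5.2)
  same <- compare_groups(c(g1, g1), rep(c("a", "b"), each = 5))
  expect_equal(same$parametric$statistic, 0)
  expect_equal(same$nonparametric$Z, 0)
  # two-group ANOVA F equals the squared pooled t
  set.seed(59)
  v <- stats::rnorm(24); g <- rep(c("a", "b"), each = 12)
  cg <- compare_groups(v, g)
  f <- summary(stats::aov(v ~ factor(g)))[[1]][["F value"]][1]
  expect_equal(f, cg$parametric$statistic^2, tolerance = 1e-10)
  # heavy-tailed data trip the gate
  set.seed(61)
  skewed <- c(exp(stats::rnorm(30, 0, 1.5)), exp(stats::rnorm(30, 0.2, 1.5)))
  cg2 <- compare_groups(skewed, rep(c("a", "b"), each = 30))
  expect_equal(cg2$recommended, "nonparametric")
  expect_error(compare_groups(c(1, 2, 3), c("a", "a", "b")), "size < 2")
})

test_that("one-way ANOVA holds its nominal level across three groups", {
  set.seed(67)
  rej <- mean(replicate(2000, {
    v <- stats::rnorm(30)
    compare_groups(v, rep(c("a", "b", "c"), each = 10))$parametric$p < 0.05
  }))
  expect_gt(rej, 0.033)
  expect_lt(rej, 0.068)
})
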