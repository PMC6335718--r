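test_that("error-function p-value matches independent quadrature", {
  grid <- seq(0, 6, by = 0.1)
  oracle <- 1 - erf_quadrature(grid / sqrt(2))
  expect_lt(max(abs(erf_logratio_p(grid) - oracle)), 1e-10)
  expect_equal(erf_logratio_p(0), 1)
  expect_equal(erf_logratio_p(-3), erf_logratio_p(3))
  expect_true(all(diff(erf_logratio_p(grid)) <= 0))
  expect_error(erf_logratio_p(Inf), "finite")
})

test_that("the 0.05 threshold sits at |xdev| = 1.959964", {
  # independent root-find on the quadrature oracle
  crit <- stats::uniroot(function(x) (1 - erf_quadrature(x / sqrt(2))) - 0.05,
                         c(1, 3), tol = 1e-10)$root
  expect_equal(crit, 1.959964, tolerance = 1e-6)
  expect_lt(erf_logratio_p(crit + 1e-6), 0.05)
  expect_gt(erf_logratio_p(crit - 1e-6), 0.05)
})

test_that("standardization is zero for unit ratios and base-invariant", {
  expr <- make_expr(matrix(1, 6, 4))
  std <- standardize_logratio(expr, sigma_source = "fixed", sigma = 1)
  expect_equal(std$xdev, rep(0, 6))
  expect_equal(std$p_value, rep(1, 6))

  set.seed(11)
  ratios <- matrix(exp(stats::rnorm(40, 0, 0.4)), 8, 5)
  expr <- make_expr(ratios, housekeeping = c(rep(TRUE, 4), rep(FALSE, 4)))
  std <- standardize_logratio(expr, "housekeeping")
  # same statistic computed in log2 throughout: base cancels
  m2 <- rowMeans(log2(ratios))
  x2 <- m2 / stats::sd(m2[1:4])
  expect_equal(std$xdev, x2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("degenerate sigma estimates are refused", {
  expr <- make_expr(matrix(1, 6, 3), housekeeping = c(TRUE, TRUE, rep(FALSE, 4)))
  expect_error(standardize_logratio(expr, "housekeeping"), "sigma")
  expect_error(standardize_logratio(expr, "fixed"), "sigma")
})

test_that("null standardized p-values are uniform under a fixed true sigma", {
  set.seed(2024)
  n <- 5000
  sigma <- 0.3
  expr <- make_expr(matrix(exp(stats::rnorm(n, 0, sigma)), ncol = 1))
  std <- standardize_logratio(expr, sigma_source = "fixed", sigma = sigma)
  ks <- suppressWarnings(stats::ks.test(std$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("doubling one array shifts its log ratios by exactly ln 2", {
  set.seed(3)
  ratios <- matrix(exp(stats::rnorm(12, 0, 0.3)), 4, 3)
  expr1 <- make_expr(ratios)
  ratios2 <- ratios; ratios2[, 2] <- 2 * ratios2[, 2]
  expr2 <- make_expr(ratios2)
  expect_equal(log(expr2$ratios[, 2]) - log(expr1$ratios[, 2]),
               rep(log(2), 4), ignore_attr = TRUE)
  s1 <- standardize_logratio(expr1, sigma_source = "fixed", sigma = 1)
  s2 <- standardize_logratio(expr2, sigma_source = "fixed", sigma = 1)
  expect_equal(s2$mean_ln - s1$mean_ln, rep(log(2) / 3, 4))
})

test_that("fold-change summary gives the mean and SEM of per-array ratios", {
  expect_equal(fold_change_summary(c(2, 4))[c("mean_fc", "sem_fc")],
               list(mean_fc = 3, sem_fc = 1))
  const <- fold_change_summary(rep(0.47, 5))
  expect_equal(const$mean_fc, 0.47)
  expect_equal(const$sem_fc, 0)
  single <- fold_change_summary(1.3)
  expect_false(single$sem_defined)
  expect_true(is.na(single$sem_fc))
  expect_error(fold_change_summary(c(1, -2)), "positive")
  # rendering in the published "mean ± SEM" layout
  expect_equal(format_mean_sem(0.42, 0), "0.42 ± 0.00")
  expect_equal(format_mean_sem(2.84, 0.27), "2.84 ± 0.27")
})

test_that("DE calls use strict thresholds and the p-value gate", {
  up <- call_de(2.84, 0.01)
  expect_equal(up$direction, "up"); expect_true(up$is_de)
  flat <- call_de(1.0, 0.001)
  expect_equal(flat$direction, "unchanged"); expect_false(flat$is_de)
  # boundary: exactly 2-fold is not called
  expect_false(call_de(2.0, 1e-6)$is_de)
  expect_false(call_de(0.5, 1e-6)$is_de)
  # fold change alone is not enough
  expect_false(call_de(3.0, 0.5)$is_de)
  expect_error(call_de(-1, 0.05), "positive")
})

test_that("screen census counts up/down genes and always partitions", {
  expect_equal(screen_table(c(3.0, 0.4, 1.5)),
               list(n_de = 2, n_up = 1, n_down = 1))
  expect_equal(screen_table(rep(1, 10)), list(n_de = 0, n_up = 0, n_down = 0))
  expect_error(screen_table(numeric(0)), "empty")
  expect_error(screen_table(c(1, 0)), "positive")
  set.seed(5)
  for (i in 1:20) {
    fc <- exp(stats::rnorm(50, 0, 1))
    st <- screen_table(fc)
    expect_identical(st$n_de, st$n_up + st$n_down)
  }
})

test_that("null DE rate under the fold-change rule shrinks with noise", {
  set.seed(9)
  rate <- vapply(c(0.5, 0.25, 0.1), function(s) {
    ratios <- matrix(exp(stats::rnorm(500 * 4, 0, s)), 500, 4)
    st <- screen_table(rowMeans(ratios))
    st$n_de / 500
  }, numeric(1))
  expect_true(all(diff(rate) <= 0))
  ratios0 <- matrix(1, 200, 4)
  expect_equal(screen_table(rowMeans(ratios0))$n_de, 0)
})

test_that("expression matrices round-trip through the TSV dialect", {
  set.seed(21)
  expr <- make_expr(matrix(exp(stats::rnorm(20, 0, 0.3)), 5, 4),
                    housekeeping = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(expr, path)
  back <- read_expression(path)
  expect_equal(back$genes, expr$genes)
  expect_equal(back$ratios, expr$ratios, tolerance = 1e-12)
  expect_error(expression_matrix(matrix(c(1, -1), 1, 2),
                                 symbols = "g"), "positive")
  expect_error(make_expr(matrix(1, 2, 2), symbols = c("g", "g")), "duplicate")
})

test_that("housekeeping normalization centres arrays on their probes", {
  set.seed(13)
  ratios <- matrix(exp(stats::rnorm(30, 0, 0.2)), 6, 5)
  ratios[, 3] <- ratios[, 3] * 1.7  # array-wide scale distortion
  expr <- make_expr(ratios, housekeeping = c(rep(TRUE, 3), rep(FALSE, 3)))
  norm <- normalize_housekeeping(expr)
  med <- apply(log(norm$ratios[1:3, ]), 2, stats::median)
  expect_equal(med, rep(0, 5), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("per-subject DE status applies the same strict band", {
  expr <- make_expr(matrix(c(2.5, 2.0, 1.0, 0.4, 0.5, 1.9), 2, 3))
  st <- de_status(expr)
  expect_equal(dim(st), c(3, 2))
  expect_equal(as.vector(st), c(1L, 0L, 0L, 0L, 1L, 0L))
})
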