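#' Pearson product-moment correlation with t-based p-value
#'
#' Pairwise-deletes missing values, requires at least 3 complete pairs and
#' non-degenerate variance in both vectors, and returns the correlation with
#' the usual p-value from \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on `n - 2` df
#' (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' U is computed from midrank sums for the first sample,
#' \eqn{U = R_1 - n_1(n_1+1)/2}, and referred to the normal approximation
#' \eqn{Z = (U - n_1 n_2/2)/\sigma_U} with the tie-corrected variance
#' \deqn{\sigma_U^2 = \frac{n_1 n_2}{12}\Big(N + 1 -
#'   \frac{\sum_j (t_j^3 - t_j)}{N(N-1)}\Big).}
#' The Z statistic (which published tables report alongside the p-value) is
#' negative when the first group tends to have smaller values. Two identical
#' groups give Z = 0, p = 1.
#'
#' @param x,y Numeric vectors (group 1 and group 2), both non-empty.
#' @return List with `U`, `Z`, `p` (two-sided), `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, Z = 0, p = 1, n1 = n1, n2 = n2))
  Z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  list(U = U, Z = Z, p = 2 * stats::pnorm(-abs(Z)), n1 = n1, n2 = n2)
}

#' Group comparisons with a normality gate
#'
#' The standard comparison battery for continuous variables: Shapiro-Wilk
#' normality per group (at `alpha_normal`), then either the parametric test
#' (pooled-variance t for 2 groups, one-way ANOVA F for more) or its rank
#' analogue (Mann-Whitney U, Kruskal-Wallis H) as the recommended test; both
#' families are always reported. Parametric tests are delegated to
#' [stats::t.test()] / [stats::aov()]; Kruskal-Wallis (tie-corrected) to
#' [stats::kruskal.test()].
#'
#' @param values Numeric vector.
#' @param groups Factor-like vector of the same length.
#' @param alpha_normal Level of the normality gate (default 0.05).
#' @param var_equal Pooled-variance t-test (default TRUE, the conventional
#'   choice here); FALSE gives Welch.
#' @return List with `normal` (logical gate result), `shapiro_p` (per
#'   group), `parametric` (t or F test result), `nonparametric` (rank test
#'   result), and `recommended` (`"parametric"` or `"nonparametric"`).
#' @export
compare_groups <- function(values, groups, alpha_normal = 0.05,
                           var_equal = TRUE) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2)) stop("group(s) of size < 2: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  shapiro_p <- vapply(levels(groups), function(g) {
    v <- values[groups == g]
    if (length(v) < 3 || stats::sd(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  normal <- all(is.na(shapiro_p) | shapiro_p >= alpha_normal)
  if (k == 2) {
    tt <- stats::t.test(values ~ groups, var.equal = var_equal)
    parametric <- list(test = "t", statistic = unname(tt$statistic),
                       df = unname(tt$parameter), p = tt$p.value)
    mw <- mann_whitney_u(values[groups == levels(groups)[1]],
                         values[groups == levels(groups)[2]])
    nonparametric <- list(test = "mann_whitney", statistic = mw$U, Z = mw$Z,
                          p = mw$p)
  } else {
    fit <- stats::aov(values ~ groups)
    s <- summary(fit)[[1]]
    parametric <- list(test = "anova_F", statistic = s[["F value"]][1],
                       df = c(s[["Df"]][1], s[["Df"]][2]),
                       p = s[["Pr(>F)"]][1])
    kw <- stats::kruskal.test(values ~ groups)
    nonparametric <- list(test = "kruskal_wallis",
                          statistic = unname(kw$statistic),
                          df = unname(kw$parameter), p = kw$p.value)
  }
  list(normal = normal, shapiro_p = shapiro_p, parametric = parametric,
       nonparametric = nonparametric,
       recommended = if (normal) "parametric" else "nonparametric")
}
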