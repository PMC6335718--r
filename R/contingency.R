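#' Labelled 2x2 contingency table
#'
#' The unit of all univariate association analysis in the package: four cell
#' counts with explicit row/column labels and an orientation flag recording
#' which row's odds go in the numerator of the odds ratio. Published KBD
#' tables use both orientations: grade tables report the odds of a sign in
#' grade II relative to grade I (`or_numerator = "row2"` in the printed
#' layout), while gene-by-sign tables report the odds of the sign in
#' gene-positive relative to gene-negative subjects (`"row1"`).
#'
#' @param a,b,c,d Non-negative integer cell counts. `a` and `b` are row 1
#'   (column "present" then "absent"); `c` and `d` are row 2.
#' @param row_labels,col_labels Length-2 character labels for the factors.
#' @param or_numerator Which row's odds form the numerator of the odds ratio.
#' @return An object of class `"contingency_2x2"`.
#' @examples
#' tab <- contingency_2x2(3, 27, 49, 1,
#'                        row_labels = c("grade I", "grade II"),
#'                        col_labels = c("sign+", "sign-"),
#'                        or_numerator = "row2")
#' pearson_chi2(tab)$chi2
#' odds_ratio_woolf(tab)$or
#' @export
contingency_2x2 <- function(a, b, c, d,
                            row_labels = c("row1", "row2"),
                            col_labels = c("present", "absent"),
                            or_numerator = c("row1", "row2")) {
  or_numerator <- match.arg(or_numerator)
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    stop("cell counts must be finite non-negative integers")
  }
  if (sum(counts) <= 0) stop("table total must be positive")
  structure(
    list(a = a, b = b, c = c, d = d,
         row_labels = as.character(row_labels),
         col_labels = as.character(col_labels),
         or_numerator = or_numerator),
    class = "contingency_2x2"
  )
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
              dimnames = list(x$row_labels, x$col_labels))
  m
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat("2x2 contingency table (OR numerator:", x$or_numerator, "odds)\n")
  print(as.matrix(x))
  invisible(x)
}

#' Margins of a 2x2 table
#' @param tab A [contingency_2x2()] object.
#' @return Named list with `row` and `col` sums and total `n`.
#' @export
table_margins <- function(tab) {
  stopifnot(inherits(tab, "contingency_2x2"))
  list(row = c(tab$a + tab$b, tab$c + tab$d),
       col = c(tab$a + tab$c, tab$b + tab$d),
       n   = tab$a + tab$b + tab$c + tab$d)
}

#' Swap the rows of a 2x2 table
#'
#' Utility used in invariance checks: a single row swap inverts the odds
#' ratio while leaving the chi-square statistic unchanged.
#' @param tab A [contingency_2x2()] object.
#' @return A `contingency_2x2` with rows exchanged (the OR-numerator flag is
#'   carried over unchanged, so the reported OR inverts).
#' @export
swap_rows <- function(tab) {
  contingency_2x2(tab$c, tab$d, tab$a, tab$b,
                  row_labels = rev(tab$row_labels),
                  col_labels = tab$col_labels,
                  or_numerator = tab$or_numerator)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Computes the 1-df Pearson statistic
#' \deqn{\chi^2 = n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}
#' with no continuity correction by default. The statistic is still computed
#' in the presence of zero cells as long as all four margins are positive; a
#' zero margin renders it invalid (`valid = FALSE`, statistic `NA`), matching
#' the dash convention of the published tables.
#'
#' @param tab A [contingency_2x2()] object.
#' @param correct Apply the Yates continuity correction
#'   (`|ad-bc|` shrunk by `n/2`, floored at 0). Off by default.
#' @return List with `chi2`, `df` (always 1), `p`, and `valid`.
#' @export
pearson_chi2 <- function(tab, correct = FALSE) {
  stopifnot(inherits(tab, "contingency_2x2"))
  m <- table_margins(tab)
  if (any(m$row == 0) || any(m$col == 0)) {
    return(list(chi2 = NA_real_, df = 1L, p = NA_real_, valid = FALSE))
  }
  num <- abs(tab$a * tab$d - tab$b * tab$c)
  if (correct) num <- max(0, num - m$n / 2)
  chi2 <- m$n * num^2 / (prod(m$row) * prod(m$col))
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       valid = TRUE)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric tail probabilities with fixed margins. Three
#' p-values are returned because published case-control tables are not
#' consistent about two-sidedness: the one-sided tail in the observed
#' direction, the doubled smaller tail (capped at 1), and the sum of all
#' tables with point probability no larger than the observed one (the
#' convention of `stats::fisher.test`).
#'
#' @param tab A [contingency_2x2()] object.
#' @return List with `p_one_sided`, `p_two_sided_doubling`,
#'   `p_two_sided_sum_small`, and `direction` (`"upper"`/`"lower"`/`"none"`).
#'   Degenerate margins (only one table possible) give all p = 1.
#' @export
fisher_exact <- function(tab) {
  stopifnot(inherits(tab, "contingency_2x2"))
  m <- table_margins(tab)
  if (any(m$row == 0) || any(m$col == 0)) {
    return(list(p_one_sided = 1, p_two_sided_doubling = 1,
                p_two_sided_sum_small = 1, direction = "none"))
  }
  r1 <- m$row[1]; r2 <- m$row[2]; k <- m$col[1]
  lo <- max(0L, k - r2); hi <- min(r1, k)
  support <- lo:hi
  dens <- stats::dhyper(support, r1, r2, k)
  a <- tab$a
  expected <- r1 * k / m$n
  p_upper <- sum(dens[support >= a])
  p_lower <- sum(dens[support <= a])
  if (a >= expected) {
    p_one <- p_upper
    direction <- "upper"
  } else {
    p_one <- p_lower
    direction <- "lower"
  }
  p_doubling <- min(1, 2 * min(p_upper, p_lower))
  p_obs <- stats::dhyper(a, r1, r2, k)
  p_sum <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  list(p_one_sided = min(1, p_one),
       p_two_sided_doubling = p_doubling,
       p_two_sided_sum_small = min(1, p_sum),
       direction = direction)
}

#' Odds ratio with Woolf (logit) confidence interval
#'
#' The odds ratio in the table's recorded orientation, with the Woolf
#' interval \eqn{\exp(\ln OR \pm z_{1-\alpha/2}\sqrt{1/a+1/b+1/c+1/d})}.
#' With any zero cell the OR is reported undefined (`defined = FALSE`,
#' rendered as a dash in reports) unless the Haldane-Anscombe 0.5 correction
#' is requested.
#'
#' @param tab A [contingency_2x2()] object; its `or_numerator` decides the
#'   orientation (`"row1"`: \eqn{ad/bc}; `"row2"`: \eqn{bc/ad}).
#' @param conf_level Confidence level, default 0.95.
#' @param haldane Add 0.5 to every cell when any cell is zero.
#' @return List with `or`, `ci_low`, `ci_high`, `log_or`, `se_log_or`,
#'   `defined`.
#' @export
odds_ratio_woolf <- function(tab, conf_level = 0.95, haldane = FALSE) {
  stopifnot(inherits(tab, "contingency_2x2"))
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  if (any(cells == 0)) {
    if (!haldane) {
      return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  log_or = NA_real_, se_log_or = NA_real_, defined = FALSE))
    }
    cells <- cells + 0.5
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  log_or <- if (tab$or_numerator == "row1") log(a * d / (b * c)) else
    log(b * c / (a * d))
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(log_or),
       ci_low = exp(log_or - z * se),
       ci_high = exp(log_or + z * se),
       log_or = log_or, se_log_or = se, defined = TRUE)
}

#' Full univariate association summary for a 2x2 table
#'
#' Bundles [pearson_chi2()], [fisher_exact()] and [odds_ratio_woolf()] into
#' one record, the row unit of the univariate report tables.
#'
#' @inheritParams odds_ratio_woolf
#' @param correct Continuity correction for the chi-square component.
#' @return A one-row `data.frame` with counts, margins total `n`, chi-square,
#'   Fisher p-values, OR and CI columns.
#' @export
associate_2x2 <- function(tab, conf_level = 0.95, correct = FALSE,
                          haldane = FALSE) {
  chi <- pearson_chi2(tab, correct = correct)
  fis <- fisher_exact(tab)
  orw <- odds_ratio_woolf(tab, conf_level = conf_level, haldane = haldane)
  data.frame(
    a = tab$a, b = tab$b, c = tab$c, d = tab$d,
    n = tab$a + tab$b + tab$c + tab$d,
    chi2 = chi$chi2, chi2_valid = chi$valid, p_chi2 = chi$p,
    p_fisher_one_sided = fis$p_one_sided,
    p_fisher_two_sided = fis$p_two_sided_doubling,
    p_fisher_sum_small = fis$p_two_sided_sum_small,
    odds_ratio = orw$or, or_ci_low = orw$ci_low, or_ci_high = orw$ci_high,
    or_defined = orw$defined,
    stringsAsFactors = FALSE
  )
}

#' Cross-tabulate two binary columns of a cohort into a 2x2 table
#'
#' Subjects missing either variable are dropped (pairwise deletion), which is
#' how blank questionnaire items are excluded from a sign's table.
#'
#' @param data A data.frame (a cohort or report table).
#' @param row_var,col_var Column names. `row_var` may be a factor-like column
#'   with exactly the two `row_levels`, or a binary 0/1 column (levels then
#'   default to `c(1, 0)`).
#' @param row_levels Length-2 vector giving the order of rows.
#' @param col_levels Length-2 vector giving the column order; default `c(1, 0)`
#'   ("present" first).
#' @param or_numerator Orientation passed to [contingency_2x2()].
#' @return A `contingency_2x2`.
#' @export
tabulate_2x2 <- function(data, row_var, col_var,
                         row_levels = c(1, 0), col_levels = c(1, 0),
                         or_numerator = c("row1", "row2")) {
  or_numerator <- match.arg(or_numerator)
  for (v in c(row_var, col_var)) {
    if (!v %in% names(data)) stop("column not found in data: ", v)
  }
  r <- data[[row_var]]; k <- data[[col_var]]
  keep <- !is.na(r) & !is.na(k)
  r <- r[keep]; k <- k[keep]
  if (!all(r %in% row_levels)) {
    bad <- setdiff(unique(r), row_levels)
    stop("unexpected level(s) in ", row_var, ": ", paste(bad, collapse = ", "))
  }
  if (!all(k %in% col_levels)) {
    bad <- setdiff(unique(k), col_levels)
    stop("unexpected level(s) in ", col_var, ": ", paste(bad, collapse = ", "))
  }
  contingency_2x2(
    sum(r == row_levels[1] & k == col_levels[1]),
    sum(r == row_levels[1] & k == col_levels[2]),
    sum(r == row_levels[2] & k == col_levels[1]),
    sum(r == row_levels[2] & k == col_levels[2]),
    row_labels = paste0(row_var, "=", row_levels),
    col_labels = paste0(col_var, "=", col_levels),
    or_numerator = or_numerator
  )
}
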