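#' Built-in published contingency-table fixtures
#'
#' The four univariate association tables of the source study, encoded as
#' counts plus the printed chi-square, p, odds ratio and Woolf CI values:
#' clinical signs by KBD grade (`grade_signs`), differential-expression rate
#' of nine genes by grade (`grade_genes`), and gene status by phalanges
#' tuberositas (`tuberositas_genes`) and by brachydactylia
#' (`brachydactylia_genes`). Each row records which chi-square convention its
#' printed statistic matches (`pearson` = uncorrected, `yates` =
#' continuity-corrected, `none` = printed as a dash, `inconsistent` = matches
#' neither its own counts' value) and whether the printed OR/CI are
#' reproducible (`or_ok`, `ci_ok`); typo rows are flagged in `note` and
#' excluded from value comparisons, their counts remaining available.
#'
#' @return data.frame with one row per printed table row; printed values are
#'   kept as character to preserve their decimal precision.
#' @export
kbd_printed_tables <- function() {
  path <- system.file("extdata", "printed_tables.tsv", package = "kbdassoc",
                      mustWork = TRUE)
  utils::read.delim(path, colClasses = "character", stringsAsFactors = FALSE)
}

#' Published differential-expression gene list
#'
#' The 39 genes of the published screen with their printed mean fold change
#' and SEM (21 downregulated, 18 upregulated).
#' @return data.frame: `symbol`, `public_id`, `direction`, `mean_fc`,
#'   `sem_fc`.
#' @export
kbd_de_foldchanges <- function() {
  path <- system.file("extdata", "de_genes.tsv", package = "kbdassoc",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Build a contingency table from a fixture row
#' @param row One row of [kbd_printed_tables()].
#' @return A [contingency_2x2()].
#' @export
fixture_table <- function(row) {
  contingency_2x2(as.integer(row$a), as.integer(row$b),
                  as.integer(row$c), as.integer(row$d),
                  row_labels = c("row1", "row2"),
                  col_labels = c("present", "absent"),
                  or_numerator = row$or_numerator)
}

# decimal places of a printed number, from its text form
printed_decimals <- function(txt) {
  ifelse(grepl("\\.", txt), nchar(sub("^[^.]*\\.", "", txt)), 0L)
}

# printed-precision agreement: within 1.5 units of the last printed digit
# (covers both rounding and the truncation seen in wide ORs), or within 0.2%
# relative for large values whose last digit is coarse
matches_printed <- function(computed, printed_txt) {
  printed <- as.numeric(printed_txt)
  d <- printed_decimals(printed_txt)
  abs(computed - printed) <= 1.5 * 10^(-d) |
    abs(computed - printed) / pmax(abs(printed), 1e-12) <= 0.002
}

#' Recompute and check every built-in printed table row
#'
#' For each fixture row, recomputes the chi-square under the convention the
#' printed value follows (uncorrected Pearson, the package default, or
#' Yates-corrected where the source printed that variant), the Fisher exact
#' p for the dash rows, and the Woolf OR/CI, and compares against the
#' printed values: chi-square to `tol_chi2`, OR and CI bounds to printed
#' precision. Rows whose printed statistics are internally inconsistent are
#' reported as `skipped`, never compared.
#'
#' @param tables Fixture data.frame, by default [kbd_printed_tables()];
#'   passing a modified copy is how the harness's sensitivity is exercised.
#' @param tol_chi2 Absolute tolerance on chi-square, default 0.02.
#' @return data.frame with one row per checked quantity: `table`, `row`,
#'   `quantity`, `convention`, `expected`, `computed`, `status`
#'   (pass/fail/skipped), `note`; summary counts in attribute `"summary"`.
#' @export
verify_printed_tables <- function(tables = kbd_printed_tables(),
                                  tol_chi2 = 0.02) {
  out <- list()
  add <- function(tbl, row, quantity, convention, expected, computed,
                  status, note = "") {
    out[[length(out) + 1L]] <<- data.frame(
      table = tbl, row = row, quantity = quantity, convention = convention,
      expected = expected, computed = computed, status = status, note = note,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(tables))) {
    r <- tables[i, ]
    tab <- fixture_table(r)
    # chi-square
    if (r$chi2_convention == "pearson") {
      comp <- pearson_chi2(tab)$chi2
      ok <- is.finite(comp) && abs(comp - as.numeric(r$chi2_printed)) <= tol_chi2
      add(r$table, r$row, "chi2", "pearson", as.numeric(r$chi2_printed),
          comp, if (ok) "pass" else "fail")
    } else if (r$chi2_convention == "yates") {
      comp <- pearson_chi2(tab, correct = TRUE)$chi2
      ok <- is.finite(comp) && abs(comp - as.numeric(r$chi2_printed)) <= tol_chi2
      add(r$table, r$row, "chi2", "yates", as.numeric(r$chi2_printed),
          comp, if (ok) "pass" else "fail",
          "printed value follows the continuity-corrected convention")
    } else if (r$chi2_convention == "none") {
      add(r$table, r$row, "chi2", "none", NA_real_, NA_real_, "skipped",
          "printed as dash (zero margin or exact test used)")
    } else {
      add(r$table, r$row, "chi2", r$chi2_convention, NA_real_, NA_real_,
          "skipped", paste0("paper-inconsistent: ", r$note))
    }
    # Fisher p for the dash rows
    if (r$p_method %in% c("fisher_one_sided", "fisher_doubling")) {
      fe <- fisher_exact(tab)
      comp <- if (r$p_method == "fisher_one_sided") fe$p_one_sided else
        fe$p_two_sided_doubling
      ok <- matches_printed(comp, r$p_printed)
      add(r$table, r$row, "fisher_p", r$p_method, as.numeric(r$p_printed),
          comp, if (ok) "pass" else "fail")
    }
    # OR and CI
    orw <- odds_ratio_woolf(tab)
    if (identical(r$or_ok, "TRUE")) {
      ok <- orw$defined && matches_printed(orw$or, r$or_printed)
      add(r$table, r$row, "odds_ratio", r$or_numerator,
          as.numeric(r$or_printed), orw$or, if (ok) "pass" else "fail")
    } else {
      add(r$table, r$row, "odds_ratio", r$or_numerator,
          suppressWarnings(as.numeric(r$or_printed)), orw$or, "skipped",
          paste0("not comparable: ", r$note))
    }
    if (identical(r$ci_ok, "TRUE")) {
      ok_lo <- orw$defined && matches_printed(orw$ci_low, r$ci_low_printed)
      ok_hi <- orw$defined && matches_printed(orw$ci_high, r$ci_high_printed)
      add(r$table, r$row, "ci_low", r$or_numerator,
          as.numeric(r$ci_low_printed), orw$ci_low,
          if (ok_lo) "pass" else "fail")
      add(r$table, r$row, "ci_high", r$or_numerator,
          as.numeric(r$ci_high_printed), orw$ci_high,
          if (ok_hi) "pass" else "fail")
    }
  }
  res <- do.call(rbind, out)
  attr(res, "summary") <- c(pass = sum(res$status == "pass"),
                            fail = sum(res$status == "fail"),
                            skipped = sum(res$status == "skipped"))
  res
}
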