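#' Two-channel expression ratio matrix
#'
#' Container for a gene-by-subject grid of linear-scale two-channel ratios
#' (case signal over common reference), as produced by a custom spotted
#' array. Ratios must be strictly positive; gene symbols must be unique.
#' Housekeeping probes are flagged: they are assumed non-differential and
#' calibrate the null scale of log ratios.
#'
#' @param ratios Numeric matrix, genes in rows, subjects in columns, all
#'   entries > 0. Row/column names are taken from `symbols`/`subjects` when
#'   given.
#' @param symbols Character vector of gene symbols (unique).
#' @param public_ids Accession ids, optional.
#' @param housekeeping Logical vector flagging housekeeping probes.
#' @param subjects Subject ids; defaults to existing column names.
#' @return Object of class `"kbd_expression"`: list with `genes` (data.frame
#'   `symbol`, `public_id`, `housekeeping`) and `ratios` (named matrix).
#' @export
expression_matrix <- function(ratios, symbols = rownames(ratios),
                              public_ids = NA_character_,
                              housekeeping = FALSE,
                              subjects = colnames(ratios)) {
  ratios <- as.matrix(ratios)
  if (!is.numeric(ratios) || any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop("ratios must be a finite, strictly positive numeric matrix")
  }
  if (is.null(symbols)) stop("gene symbols are required")
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols)) {
    stop("duplicate gene symbol(s): ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
  }
  if (length(symbols) != nrow(ratios)) stop("symbols/ratios length mismatch")
  if (is.null(subjects)) subjects <- paste0("S", seq_len(ncol(ratios)))
  genes <- data.frame(
    symbol = symbols,
    public_id = rep_len(as.character(public_ids), length(symbols)),
    housekeeping = rep_len(as.logical(housekeeping), length(symbols)),
    stringsAsFactors = FALSE
  )
  dimnames(ratios) <- list(symbols, as.character(subjects))
  structure(list(genes = genes, ratios = ratios), class = "kbd_expression")
}

#' @export
print.kbd_expression <- function(x, ...) {
  cat("Expression ratio matrix:", nrow(x$ratios), "genes x",
      ncol(x$ratios), "subjects (", sum(x$genes$housekeeping),
      "housekeeping )\n")
  invisible(x)
}

#' Read / write an expression ratio matrix
#'
#' TSV dialect: columns `symbol`, `public_id`, `housekeeping` (0/1), then one
#' column of linear ratios per subject.
#' @param path File path.
#' @return [read_expression()]: a `kbd_expression`; [write_expression()]:
#'   `path` invisibly.
#' @export
read_expression <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("symbol", "public_id", "housekeeping")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("expression file missing column(s): ",
                         paste(miss, collapse = ", "))
  subj <- setdiff(names(x), need)
  if (!length(subj)) stop("expression file has no subject columns")
  mat <- as.matrix(x[subj])
  storage.mode(mat) <- "double"
  expression_matrix(mat, symbols = x$symbol, public_ids = x$public_id,
                    housekeeping = x$housekeeping == 1, subjects = subj)
}

#' @rdname read_expression
#' @param expr A `kbd_expression`.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "kbd_expression"))
  out <- cbind(
    data.frame(symbol = expr$genes$symbol, public_id = expr$genes$public_id,
               housekeeping = as.integer(expr$genes$housekeeping),
               stringsAsFactors = FALSE),
    as.data.frame(expr$ratios)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-sided error-function p-value for a standardized log ratio
#'
#' The screen's p-value is the two-sided Gaussian tail of the standardized
#' log-ratio deviation:
#' \deqn{P = 1 - \mathrm{Erf}(|xdev|/\sqrt{2}) = \mathrm{Erfc}(|xdev|/\sqrt 2),}
#' with \eqn{\mathrm{Erf}(x) = (2/\sqrt\pi)\int_0^x e^{-t^2}dt}. Equivalently
#' twice the upper standard-normal tail at `|xdev|`. Symmetric in the sign of
#' `xdev` and non-increasing in its magnitude; `xdev = 0` gives P = 1.
#'
#' @param xdev Standardized deviation(s) of the mean log ratio from 0.
#' @return Two-sided p-value(s) in \[0, 1\].
#' @examples
#' erf_logratio_p(0)        # 1
#' erf_logratio_p(1.959964) # 0.05
#' @export
erf_logratio_p <- function(xdev) {
  if (any(!is.finite(xdev))) stop("xdev must be finite")
  2 * stats::pnorm(-abs(xdev))
}

#' Standardize per-gene mean log ratios
#'
#' For each gene, the mean natural-log ratio across the selected arrays is
#' divided by an estimate of the null standard deviation of that mean,
#' giving the `xdev` fed to [erf_logratio_p()]. The null scale can come from
#' the housekeeping probes (standard deviation of their per-gene mean log
#' ratios; the default, since those probes are on the array for exactly this
#' purpose), from all genes robustly (1.4826 x MAD of per-gene means), or be
#' supplied directly (`sigma` is then the null SD of a per-gene mean log
#' ratio). Results are invariant to the logarithm base because numerator and
#' denominator share it.
#'
#' @param expr A `kbd_expression`.
#' @param sigma_source One of `"housekeeping"`, `"all_genes"`, `"fixed"`.
#' @param sigma Null SD of the per-gene mean log ratio, for
#'   `sigma_source = "fixed"`.
#' @param subjects Optional subject ids (columns) to use, e.g. the case
#'   arrays only.
#' @return data.frame with `symbol`, `mean_ln`, `sigma` (the estimate used,
#'   recorded for audit), `xdev`, `p_value`.
#' @export
standardize_logratio <- function(expr,
                                 sigma_source = c("housekeeping", "all_genes",
                                                  "fixed"),
                                 sigma = NULL, subjects = NULL) {
  stopifnot(inherits(expr, "kbd_expression"))
  sigma_source <- match.arg(sigma_source)
  mat <- expr$ratios
  if (!is.null(subjects)) {
    miss <- setdiff(subjects, colnames(mat))
    if (length(miss)) stop("unknown subject id(s): ",
                           paste(utils::head(miss, 5), collapse = ", "))
    mat <- mat[, subjects, drop = FALSE]
  }
  mean_ln <- rowMeans(log(mat))
  sig <- switch(sigma_source,
    housekeeping = {
      hk <- expr$genes$housekeeping
      if (sum(hk) < 2) stop("need >= 2 housekeeping genes for sigma_source = 'housekeeping'")
      stats::sd(mean_ln[hk])
    },
    all_genes = stats::mad(mean_ln, constant = 1.4826),
    fixed = {
      if (is.null(sigma)) stop("sigma must be given for sigma_source = 'fixed'")
      sigma
    })
  if (!is.finite(sig) || sig <= 0) stop("estimated null sigma is zero or non-finite")
  xdev <- mean_ln / sig
  data.frame(symbol = expr$genes$symbol, mean_ln = mean_ln, sigma = sig,
             xdev = xdev, p_value = erf_logratio_p(xdev),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Median-centre arrays on their housekeeping probes
#'
#' Optional normalization: subtracts from each array's log ratios the median
#' housekeeping log ratio of that array. Off by default throughout the
#' pipeline; published fold changes are reproduced without it.
#' @param expr A `kbd_expression`.
#' @return A normalized `kbd_expression`.
#' @export
normalize_housekeeping <- function(expr) {
  stopifnot(inherits(expr, "kbd_expression"))
  hk <- expr$genes$housekeeping
  if (!any(hk)) stop("no housekeeping genes flagged; cannot normalize")
  med <- apply(log(expr$ratios[hk, , drop = FALSE]), 2, stats::median)
  out <- expr
  out$ratios <- exp(sweep(log(expr$ratios), 2, med))
  out
}

#' Fold-change mean and standard error
#'
#' Arithmetic mean of the per-array linear ratios and the standard error of
#' that mean (sample SD / sqrt(n)). With fewer than two arrays the SEM is
#' undefined and flagged.
#'
#' @param ratios Numeric vector of per-array linear ratios for one gene.
#' @return List with `mean_fc`, `sem_fc`, `n`, `sem_defined`.
#' @examples
#' fold_change_summary(c(2, 4)) # mean 3, SEM 1
#' @export
fold_change_summary <- function(ratios) {
  ratios <- ratios[!is.na(ratios)]
  if (!length(ratios)) stop("no ratios supplied")
  if (any(ratios <= 0)) stop("ratios must be positive")
  n <- length(ratios)
  if (n < 2) {
    return(list(mean_fc = mean(ratios), sem_fc = NA_real_, n = n,
                sem_defined = FALSE))
  }
  list(mean_fc = mean(ratios), sem_fc = stats::sd(ratios) / sqrt(n), n = n,
       sem_defined = TRUE)
}

#' Render "mean +/- SEM" the way published screen tables do
#' @param mean_fc,sem_fc Numeric scalars/vectors.
#' @param digits Decimal places (default 2).
#' @return Character vector like `"0.42 ± 0.00"`.
#' @export
format_mean_sem <- function(mean_fc, sem_fc, digits = 2) {
  sem_txt <- ifelse(is.na(sem_fc), "NA",
                    formatC(sem_fc, format = "f", digits = digits))
  paste0(formatC(mean_fc, format = "f", digits = digits), " ± ", sem_txt)
}

#' Differential-expression call from fold change and p-value
#'
#' The screen's decision rule, with strict thresholds: direction is "up" iff
#' `mean_fc > up` (default 2), "down" iff `mean_fc < down` (default 0.5),
#' otherwise "unchanged"; a gene is called differentially expressed iff it is
#' up or down *and* `p_value < alpha` (default 0.05). A fold change of
#' exactly 2 (or 0.5) is not called.
#'
#' @param mean_fc Positive fold change(s).
#' @param p_value P-value(s) from [erf_logratio_p()].
#' @param up,down Fold-change thresholds (`down < 1 < up`).
#' @param alpha Significance level.
#' @return data.frame with `direction` (up/down/unchanged) and `is_de`.
#' @export
call_de <- function(mean_fc, p_value, up = 2, down = 0.5, alpha = 0.05) {
  if (any(!is.finite(mean_fc)) || any(mean_fc <= 0)) {
    stop("mean_fc must be positive")
  }
  if (!(down < 1 && up > 1)) stop("need down < 1 < up")
  direction <- ifelse(mean_fc > up, "up",
                      ifelse(mean_fc < down, "down", "unchanged"))
  data.frame(direction = direction,
             is_de = direction != "unchanged" & p_value < alpha,
             stringsAsFactors = FALSE)
}

#' Census of a fold-change list under the 2-fold rule
#'
#' Counts up- (`mean_fc > up`) and downregulated (`mean_fc < down`) genes;
#' used to re-derive the published census of 39 = 18 up + 21 down from the
#' printed fold-change column.
#'
#' @param fold_changes Numeric vector of positive mean fold changes (may be
#'   named by gene symbol).
#' @param up,down Strict thresholds, defaults 2 and 0.5.
#' @return Named list `n_de`, `n_up`, `n_down`; always `n_de = n_up + n_down`.
#' @export
screen_table <- function(fold_changes, up = 2, down = 0.5) {
  if (!length(fold_changes)) stop("empty fold-change list")
  if (any(!is.finite(fold_changes)) || any(fold_changes <= 0)) {
    stop("fold changes must be positive")
  }
  n_up <- sum(fold_changes > up)
  n_down <- sum(fold_changes < down)
  list(n_de = n_up + n_down, n_up = n_up, n_down = n_down)
}

#' Per-gene differential-expression screen
#'
#' Runs the whole screen on an expression matrix: per-gene fold-change mean
#' and SEM over the case arrays, standardized log-ratio deviation and its
#' error-function p-value, and the strict fold-change/p-value call.
#'
#' @param expr A `kbd_expression`.
#' @param case_ids Subject ids of the case arrays; default all columns.
#' @param sigma_source,sigma Passed to [standardize_logratio()].
#' @param normalize Median-centre arrays by housekeeping probes first
#'   (default `FALSE`).
#' @param up,down,alpha Passed to [call_de()].
#' @return data.frame, one row per gene: `symbol`, `public_id`,
#'   `housekeeping`, `mean_fc`, `sem_fc`, `xdev`, `sigma`, `p_value`,
#'   `direction`, `is_de`.
#' @export
screen_expression <- function(expr, case_ids = NULL,
                              sigma_source = "housekeeping", sigma = NULL,
                              normalize = FALSE,
                              up = 2, down = 0.5, alpha = 0.05) {
  stopifnot(inherits(expr, "kbd_expression"))
  if (normalize) expr <- normalize_housekeeping(expr)
  if (is.null(case_ids)) case_ids <- colnames(expr$ratios)
  std <- standardize_logratio(expr, sigma_source = sigma_source,
                              sigma = sigma, subjects = case_ids)
  mat <- expr$ratios[, case_ids, drop = FALSE]
  n <- ncol(mat)
  mean_fc <- rowMeans(mat)
  sem_fc <- if (n >= 2) apply(mat, 1, stats::sd) / sqrt(n) else
    rep(NA_real_, nrow(mat))
  calls <- call_de(mean_fc, std$p_value, up = up, down = down, alpha = alpha)
  data.frame(symbol = expr$genes$symbol, public_id = expr$genes$public_id,
             housekeeping = expr$genes$housekeeping,
             mean_fc = mean_fc, sem_fc = sem_fc,
             xdev = std$xdev, sigma = std$sigma, p_value = std$p_value,
             direction = calls$direction, is_de = calls$is_de,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-subject differential-expression status
#'
#' A subject is scored positive for a gene when that subject's ratio falls
#' outside the (down, up) band, i.e. the subject-level analogue of the
#' fold-change rule. These binary statuses are the "+/-" entries of the
#' univariate gene-by-sign tables and the predictors of the multivariable
#' logistic stage.
#'
#' @param expr A `kbd_expression`.
#' @param up,down Strict thresholds, defaults 2 and 0.5.
#' @return Integer matrix subjects x genes of 0/1 statuses.
#' @export
de_status <- function(expr, up = 2, down = 0.5) {
  stopifnot(inherits(expr, "kbd_expression"))
  status <- t(expr$ratios > up | expr$ratios < down)
  storage.mode(status) <- "integer"
  status
}
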