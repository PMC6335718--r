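#' Default gene panel for simulated arrays
#'
#' The 39 published differentially expressed genes (log-ratio shifts equal to
#' the log of their printed mean fold change), 11 housekeeping probes and
#' enough null filler probes to reach the array's 169 spots. Housekeeping and
#' filler probes carry zero shift.
#'
#' @param n_probes Total probes on the array (default 169).
#' @param n_housekeeping Housekeeping probes (default 11).
#' @param sigma Per-array log-ratio noise SD shared by all probes
#'   (default 0.25).
#' @return data.frame: `symbol`, `public_id`, `housekeeping`, `lnfc` (full
#'   log-ratio shift reached at the top of the severity scale), `sigma`.
#' @export
default_gene_panel <- function(n_probes = 169, n_housekeeping = 11,
                               sigma = 0.25) {
  de <- kbd_de_foldchanges()
  n_filler <- n_probes - nrow(de) - n_housekeeping
  if (n_filler < 0) stop("n_probes too small for the panel")
  panel <- rbind(
    data.frame(symbol = de$symbol, public_id = de$public_id,
               housekeeping = FALSE, lnfc = log(de$mean_fc),
               stringsAsFactors = FALSE),
    data.frame(symbol = sprintf("HK%02d", seq_len(n_housekeeping)),
               public_id = NA_character_, housekeeping = TRUE, lnfc = 0,
               stringsAsFactors = FALSE),
    if (n_filler > 0) data.frame(
      symbol = sprintf("NULL%03d", seq_len(n_filler)),
      public_id = NA_character_, housekeeping = FALSE, lnfc = 0,
      stringsAsFactors = FALSE)
  )
  panel$sigma <- sigma
  panel
}

#' Per-sign logistic coefficients calibrated to the published grade tables
#'
#' For each questionnaire item, solves the two-point logistic system so that
#' a subject at the grade-I mean severity has the grade-I prevalence and one
#' at the grade-II mean severity the grade-II prevalence, both taken from
#' the published counts (shrunk by 0.5/1 to keep the logits finite).
#'
#' @param severity_mean Named vector of stratum severity means with entries
#'   `I` and `II`.
#' @return data.frame: `sign`, `intercept`, `slope`.
#' @export
default_sign_coef <- function(severity_mean = c(control = 0, I = 1.5, II = 3)) {
  tabs <- kbd_printed_tables()
  tabs <- tabs[tabs$table == "grade_signs", ]
  a <- as.numeric(tabs$a); b <- as.numeric(tabs$b)
  c_ <- as.numeric(tabs$c); d <- as.numeric(tabs$d)
  p1 <- (a + 0.5) / (a + b + 1)
  p2 <- (c_ + 0.5) / (c_ + d + 1)
  m1 <- severity_mean[["I"]]; m2 <- severity_mean[["II"]]
  slope <- (stats::qlogis(p2) - stats::qlogis(p1)) / (m2 - m1)
  data.frame(sign = tabs$row, intercept = stats::qlogis(p1) - slope * m1,
             slope = slope, stringsAsFactors = FALSE)
}

#' Configuration of the latent-severity cohort model
#'
#' One latent severity scalar per subject, drawn by stratum, drives the
#' clinical signs (per-sign logistic links), the gene expression log ratios
#' (per-gene shift proportional to severity, reaching the published fold
#' change at the grade-II mean) and nothing else; anthropometry is Gaussian
#' by stratum with grade means echoing the published continuous-variable
#' table (metacarpal length 16.7 vs 15.8 cm). Cohort sizes default to the
#' study design: 100 controls, 50 grade I, 50 grade II.
#'
#' @param n_control,n_grade1,n_grade2 Stratum sizes.
#' @param severity_mean,severity_sd Named numeric vectors (`control`, `I`,
#'   `II`) for the latent severity distribution.
#' @param sign_coef data.frame `sign`/`intercept`/`slope`; default calibrated
#'   by [default_sign_coef()].
#' @param gene_panel data.frame as from [default_gene_panel()].
#' @param anthropometry Named list of per-stratum `c(mean, sd)` pairs; see
#'   defaults in the source.
#' @param missing_rate Probability a questionnaire cell is blanked
#'   (default 0).
#' @return Validated list of class `"kbd_severity_config"`.
#' @export
severity_config <- function(n_control = 100, n_grade1 = 50, n_grade2 = 50,
                            severity_mean = c(control = 0, I = 1.5, II = 3),
                            severity_sd = c(control = 1, I = 1, II = 1),
                            sign_coef = NULL,
                            gene_panel = NULL,
                            anthropometry = NULL,
                            missing_rate = 0) {
  if (is.null(sign_coef)) sign_coef <- default_sign_coef(severity_mean)
  if (is.null(gene_panel)) gene_panel <- default_gene_panel()
  if (is.null(anthropometry)) {
    anthropometry <- list(
      age = list(control = c(53.4, 8.0), I = c(55.3, 9.2), II = c(58.0, 5.7)),
      bmi = list(control = c(21.7, 2.5), I = c(21.7, 2.1), II = c(21.5, 2.8)),
      height = list(control = c(160, 7), I = c(160, 7), II = c(160, 7)),
      metacarpal_length = list(control = c(16.7, 1.2), I = c(16.7, 1.2),
                               II = c(15.8, 1.1)),
      metacarpal_breadth = list(control = c(8.01, 0.6), I = c(8.01, 0.6),
                                II = c(8.22, 0.5))
    )
  }
  cfg <- list(n_control = n_control, n_grade1 = n_grade1, n_grade2 = n_grade2,
              severity_mean = severity_mean, severity_sd = severity_sd,
              sign_coef = sign_coef, gene_panel = gene_panel,
              anthropometry = anthropometry, missing_rate = missing_rate,
              p_male = 0.44, sitting_ratio = c(0.53, 0.01))
  validate_severity_config(cfg)
  structure(cfg, class = "kbd_severity_config")
}

validate_severity_config <- function(cfg) {
  for (f in c("n_control", "n_grade1", "n_grade2")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v)) {
      stop("invalid config field: ", f, " must be a non-negative integer")
    }
  }
  if (cfg$n_control + cfg$n_grade1 + cfg$n_grade2 == 0) {
    stop("invalid config: empty cohort")
  }
  for (f in c("severity_mean", "severity_sd")) {
    if (!all(c("control", "I", "II") %in% names(cfg[[f]]))) {
      stop("invalid config field: ", f, " needs entries control, I, II")
    }
  }
  if (any(cfg$severity_sd <= 0)) stop("invalid config field: severity_sd must be > 0")
  if (!all(c("sign", "intercept", "slope") %in% names(cfg$sign_coef))) {
    stop("invalid config field: sign_coef needs sign/intercept/slope columns")
  }
  if (any(cfg$gene_panel$sigma <= 0)) {
    stop("invalid config field: gene_panel sigma must be > 0")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("invalid config field: missing_rate must be in [0, 1)")
  }
  invisible(cfg)
}

draw_stratum <- function(spec, stratum, n) {
  p <- spec[[stratum]]
  stats::rnorm(n, p[1], p[2])
}

#' Generate a cohort and expression matrix from the latent-severity model
#'
#' Draws, per subject: a stratum severity, tri-state signs from the per-sign
#' logistic links, Gaussian anthropometry by stratum (sitting height as a
#' fraction of height, leg length derived as their difference), and a
#' two-channel ratio per probe, `exp(lnfc * s / mean(severity II) + noise)`,
#' so a grade-II subject's expected ratio is the published fold change and a
#' control's is 1. Housekeeping and filler probes stay null. Everything is
#' reproducible from the seed; the truth record carries all parameters and
#' the per-subject latents for recovery tests.
#'
#' @param config A [severity_config()].
#' @param seed Integer seed (mandatory; every stochastic call flows from it).
#' @return List of class `"kbd_sim"`: `cohort` (data.frame), `expression`
#'   (`kbd_expression`), `truth` (config, per-subject severity, panel).
#' @export
generate_model_cohort <- function(config = severity_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  validate_severity_config(config)
  set.seed(seed)
  strata <- rep(c("control", "I", "II"),
                c(config$n_control, config$n_grade1, config$n_grade2))
  n <- length(strata)
  s <- stats::rnorm(n, config$severity_mean[strata], config$severity_sd[strata])

  cohort <- data.frame(
    id = sprintf("S%04d", seq_len(n)),
    group = ifelse(strata == "control", "control", "KBD"),
    grade = ifelse(strata == "control", "none", strata),
    gender = ifelse(stats::runif(n) < config$p_male, "male", "female"),
    stringsAsFactors = FALSE
  )
  for (f in c("age", "bmi", "height", "metacarpal_length",
              "metacarpal_breadth")) {
    spec <- config$anthropometry[[f]]
    v <- numeric(n)
    for (st in unique(strata)) {
      idx <- strata == st
      v[idx] <- draw_stratum(spec, st, sum(idx))
    }
    cohort[[f]] <- round(pmax(v, 0.2 * spec[["control"]][1]), 1)
  }
  ratio <- pmin(pmax(stats::rnorm(n, config$sitting_ratio[1],
                                  config$sitting_ratio[2]), 0.45), 0.62)
  cohort$sitting_height <- round(cohort$height * ratio, 1)
  cohort$leg_length <- round(cohort$height - cohort$sitting_height, 1)

  for (i in seq_len(nrow(config$sign_coef))) {
    sc <- config$sign_coef[i, ]
    p <- stats::plogis(sc$intercept + sc$slope * s)
    v <- stats::rbinom(n, 1, p)
    if (config$missing_rate > 0) {
      v[stats::runif(n) < config$missing_rate] <- NA_integer_
    }
    cohort[[sc$sign]] <- v
  }

  panel <- config$gene_panel
  s_top <- config$severity_mean[["II"]]
  loading <- panel$lnfc / s_top
  ln_ratio <- outer(loading, s) +
    matrix(stats::rnorm(nrow(panel) * n, 0, panel$sigma),
           nrow = nrow(panel))
  expr <- expression_matrix(exp(ln_ratio), symbols = panel$symbol,
                            public_ids = panel$public_id,
                            housekeeping = panel$housekeeping,
                            subjects = cohort$id)
  cohort <- validate_cohort(cohort)
  structure(list(cohort = cohort, expression = expr,
                 truth = list(config = config, seed = seed, severity = s,
                              loading = loading, strata = strata)),
            class = "kbd_sim")
}

#' Replay specification for exact table reconstruction
#'
#' Describes a cohort whose cross-tabulation on two factors reproduces a
#' target 2x2 table cell-for-cell; used to rebuild any published table by
#' construction.
#'
#' @param table A [contingency_2x2()] with the target counts and OR
#'   orientation.
#' @param row_var Name of the row factor: `"grade"` or a gene symbol.
#' @param col_var Name of the column factor (a sign name, or `"grade"` style
#'   factor for gene-by-grade tables).
#' @param row_levels Values taken by the row factor, row 1 first. Defaults:
#'   `c("I", "II")` when the factor is `grade`, else `c(1, 0)`.
#' @param col_levels Values taken by the column factor, column 1 first;
#'   default `c(1, 0)`.
#' @param n_total Optional expected cohort size; an error if it disagrees
#'   with the cell sum.
#' @param seed Seed controlling the (deterministic) row shuffle.
#' @return List of class `"kbd_replay_spec"`.
#' @export
replay_spec <- function(table, row_var, col_var, row_levels = NULL,
                        col_levels = NULL, n_total = NULL, seed = 1) {
  stopifnot(inherits(table, "contingency_2x2"))
  n <- table$a + table$b + table$c + table$d
  if (!is.null(n_total) && n_total != n) {
    stop("inconsistent spec: counts sum to ", n, " but n_total = ", n_total)
  }
  if (is.null(row_levels)) {
    row_levels <- if (identical(row_var, "grade")) c("I", "II") else c(1, 0)
  }
  if (is.null(col_levels)) {
    col_levels <- if (identical(col_var, "grade")) c("I", "II") else c(1, 0)
  }
  structure(list(table = table, row_var = row_var, col_var = col_var,
                 row_levels = row_levels, col_levels = col_levels,
                 seed = seed),
            class = "kbd_replay_spec")
}

#' Generate a cohort that reproduces a 2x2 table exactly
#'
#' Deterministic given the spec's seed (which only shuffles subject order):
#' cross-tabulating the generated cohort on the spec's two factors returns
#' the target counts with integer equality. Unconstrained subject fields are
#' filled with neutral defaults so the cohort passes validation.
#'
#' @param spec A [replay_spec()].
#' @return A cohort data.frame carrying the two factor columns.
#' @export
generate_replay <- function(spec) {
  stopifnot(inherits(spec, "kbd_replay_spec"))
  tab <- spec$table
  n <- tab$a + tab$b + tab$c + tab$d
  rows <- rep(spec$row_levels, c(tab$a + tab$b, tab$c + tab$d))
  cols <- c(rep(spec$col_levels, c(tab$a, tab$b)),
            rep(spec$col_levels, c(tab$c, tab$d)))
  cohort <- data.frame(
    id = sprintf("R%04d", seq_len(n)),
    group = "KBD", grade = "I", gender = "female",
    age = 57, bmi = 21.7, height = 165, sitting_height = 87,
    leg_length = 78, metacarpal_length = 16.2, metacarpal_breadth = 8.1,
    stringsAsFactors = FALSE
  )
  if (identical(spec$row_var, "grade")) cohort$grade <- rows else
    cohort[[spec$row_var]] <- rows
  if (identical(spec$col_var, "grade")) cohort$grade <- cols else
    cohort[[spec$col_var]] <- cols
  set.seed(spec$seed)
  cohort <- cohort[sample.int(n), , drop = FALSE]
  rownames(cohort) <- NULL
  validate_cohort(cohort)
}
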