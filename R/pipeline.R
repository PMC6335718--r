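#' Pipeline configuration
#'
#' Collects and validates everything a pipeline run depends on. Inputs are
#' either a cohort plus expression matrix (objects or file paths) or a
#' simulation config; all randomness flows from the single `seed`.
#'
#' @param cohort Cohort data.frame or path for [read_cohort()].
#' @param expression `kbd_expression` or path for [read_expression()].
#' @param simulate A [severity_config()] to generate inputs instead.
#' @param seed Root seed for the run.
#' @param alpha_de Significance level of the expression screen.
#' @param alpha_screen Stage-1 level of the multivariable procedure.
#' @param fc_up,fc_down Strict fold-change thresholds (`fc_down < 1 < fc_up`).
#' @param sigma_source,sigma,normalize Passed to [screen_expression()].
#' @param outdir Optional directory for the TSV report bundle.
#' @param verbose Log stage progress to standard error.
#' @return List of class `"kbd_run_config"`.
#' @export
run_config <- function(cohort = NULL, expression = NULL, simulate = NULL,
                       seed = 1, alpha_de = 0.05, alpha_screen = 0.05,
                       fc_up = 2, fc_down = 0.5,
                       sigma_source = "housekeeping", sigma = NULL,
                       normalize = FALSE, outdir = NULL, verbose = FALSE) {
  if (is.null(simulate) && (is.null(cohort) || is.null(expression))) {
    stop("either both cohort and expression, or a simulation config, required")
  }
  if (!(fc_down > 0 && fc_down < 1 && fc_up > 1)) {
    stop("need 0 < fc_down < 1 < fc_up")
  }
  for (a in c(alpha_de, alpha_screen)) {
    if (!(a > 0 && a < 1)) stop("alpha levels must be in (0, 1)")
  }
  structure(list(cohort = cohort, expression = expression,
                 simulate = simulate, seed = seed, alpha_de = alpha_de,
                 alpha_screen = alpha_screen, fc_up = fc_up,
                 fc_down = fc_down, sigma_source = sigma_source,
                 sigma = sigma, normalize = normalize, outdir = outdir,
                 verbose = verbose),
            class = "kbd_run_config")
}

run_stage <- function(name, verbose, expr) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S"), " stage: ", name)
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full clinical-variable/expression association pipeline
#'
#' Stage order mirrors the study's analysis: expression screen, clinical
#' indexes, gene-index correlations, univariate 2x2 associations (signs by
#' grade, gene status by grade and by the two modelled signs), and one
#' multivariable logistic model per modelled sign. The bundle is a pure
#' function of (inputs, config, seed); with `outdir` set, one TSV per report
#' plus a manifest are written.
#'
#' @param config A [run_config()].
#' @return List of class `"kbd_run"` with elements `screen`, `indexes`,
#'   `correlation`, `grade_signs`, `grade_genes`, `sign_genes` (list by
#'   sign), `models` (list by sign), `de_genes`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "kbd_run_config"))
  v <- isTRUE(config$verbose)

  inputs <- run_stage("inputs", v, {
    if (!is.null(config$simulate)) {
      sim <- generate_model_cohort(config$simulate, seed = config$seed)
      list(cohort = sim$cohort, expr = sim$expression)
    } else {
      cohort <- if (is.character(config$cohort)) read_cohort(config$cohort)
        else validate_cohort(config$cohort)
      expr <- if (is.character(config$expression))
        read_expression(config$expression) else config$expression
      if (!inherits(expr, "kbd_expression")) stop("expression input invalid")
      miss <- setdiff(cohort$id, colnames(expr$ratios))
      if (length(miss)) stop("cohort subject(s) missing from expression: ",
                             paste(utils::head(miss, 5), collapse = ", "))
      list(cohort = cohort, expr = expr)
    }
  })
  cohort <- inputs$cohort
  expr <- inputs$expr
  kbd_ids <- cohort$id[cohort$group == "KBD"]
  if (!length(kbd_ids)) stop("stage 'inputs' failed: no KBD subjects")

  screen <- run_stage("screen", v, {
    s <- screen_expression(expr, case_ids = kbd_ids,
                           sigma_source = config$sigma_source,
                           sigma = config$sigma,
                           normalize = config$normalize,
                           up = config$fc_up, down = config$fc_down,
                           alpha = config$alpha_de)
    s$fold_change <- format_mean_sem(s$mean_fc, s$sem_fc)
    s
  })
  de_genes <- screen$symbol[screen$is_de & !screen$housekeeping]

  indexes <- run_stage("indexes", v, {
    cbind(data.frame(id = cohort$id, stringsAsFactors = FALSE),
          compute_indexes(cohort))
  })

  correlation <- run_stage("correlation", v, {
    if (!length(de_genes)) {
      data.frame(gene = character(), index = character(), r = numeric(),
                 p = numeric(), n = integer(), stringsAsFactors = FALSE)
    } else {
      kbd_idx <- indexes[match(kbd_ids, indexes$id), ]
      rows <- list()
      for (g in de_genes) {
        lnr <- log(expr$ratios[g, kbd_ids])
        for (ix in c("skelic", "mc_length_breadth", "mc_length_height")) {
          res <- tryCatch(pearson_correlation(lnr, kbd_idx[[ix]]),
                          error = function(e) list(r = NA_real_,
                                                   p = NA_real_, n = NA))
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, index = ix, r = res$r, p = res$p, n = res$n,
            stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    }
  })

  kbd <- cohort[cohort$group == "KBD", , drop = FALSE]
  status <- de_status(expr, up = config$fc_up, down = config$fc_down)
  status_kbd <- status[kbd$id, , drop = FALSE]

  grade_signs <- run_stage("univariate_grade_signs", v, {
    if (!any(kbd$grade == "I") || !any(kbd$grade == "II")) {
      stop("grade contrast needs subjects in both grade I and grade II")
    }
    items <- intersect(kbd_all_items, names(kbd))
    do.call(rbind, lapply(items, function(it) {
      tab <- tabulate_2x2(kbd, "grade", it, row_levels = c("I", "II"),
                          or_numerator = "row2")
      cbind(data.frame(variable = it, stringsAsFactors = FALSE),
            associate_2x2(tab))
    }))
  })

  grade_genes <- run_stage("univariate_grade_genes", v, {
    if (!length(de_genes)) grade_signs[0, ] else
      do.call(rbind, lapply(de_genes, function(g) {
        dat <- data.frame(grade = kbd$grade, st = status_kbd[, g])
        tab <- tabulate_2x2(dat, "grade", "st", row_levels = c("I", "II"),
                            or_numerator = "row2")
        cbind(data.frame(variable = g, stringsAsFactors = FALSE),
              associate_2x2(tab))
      }))
  })

  model_signs <- intersect(c("phalanges_tuberositas", "brachydactylia"),
                           names(kbd))
  sign_genes <- run_stage("univariate_sign_genes", v, {
    out <- list()
    for (sg in model_signs) {
      out[[sg]] <- if (!length(de_genes)) grade_signs[0, ] else
        do.call(rbind, lapply(de_genes, function(g) {
          dat <- data.frame(st = status_kbd[, g], s = kbd[[sg]])
          tab <- tabulate_2x2(dat, "st", "s", or_numerator = "row1")
          cbind(data.frame(variable = g, stringsAsFactors = FALSE),
                associate_2x2(tab))
        }))
    }
    out
  })

  models <- run_stage("models", v, {
    out <- list()
    for (sg in model_signs) {
      out[[sg]] <- if (!length(de_genes)) NULL else
        suppressWarnings(univariate_screen_then_model(
          kbd[[sg]], status_kbd[, de_genes, drop = FALSE],
          alpha = config$alpha_screen))
    }
    out
  })

  manifest <- c(
    paste0("package_version\t", as.character(utils::packageVersion("kbdassoc"))),
    paste0("seed\t", config$seed),
    paste0("alpha_de\t", config$alpha_de),
    paste0("alpha_screen\t", config$alpha_screen),
    paste0("fc_up\t", config$fc_up),
    paste0("fc_down\t", config$fc_down),
    paste0("sigma_source\t", config$sigma_source),
    paste0("normalize\t", config$normalize),
    paste0("simulated\t", !is.null(config$simulate)),
    paste0("n_subjects\t", nrow(cohort)),
    paste0("n_genes\t", nrow(expr$ratios)),
    paste0("n_de_genes\t", length(de_genes))
  )

  bundle <- structure(
    list(screen = screen, indexes = indexes, correlation = correlation,
         grade_signs = grade_signs, grade_genes = grade_genes,
         sign_genes = sign_genes, models = models, de_genes = de_genes,
         manifest = manifest, cohort = cohort),
    class = "kbd_run")

  if (!is.null(config$outdir)) {
    run_stage("write_reports", v, write_run_bundle(bundle, config$outdir))
  }
  invisible(bundle)
}

#' Write a pipeline report bundle as TSV files
#' @param bundle A `kbd_run` object.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run_bundle <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "kbd_run"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE,
    na = "—")
  screen_cols <- c("symbol", "public_id", "fold_change", "direction",
                   "p_value", "is_de")
  wt(bundle$screen[screen_cols], "screen.tsv")
  wt(bundle$indexes, "indexes.tsv")
  wt(bundle$correlation, "correlation.tsv")
  wt(bundle$grade_signs, "univariate_grade_signs.tsv")
  wt(bundle$grade_genes, "univariate_grade_genes.tsv")
  for (sg in names(bundle$sign_genes)) {
    wt(bundle$sign_genes[[sg]], paste0("univariate_", sg, "_genes.tsv"))
  }
  for (sg in names(bundle$models)) {
    m <- bundle$models[[sg]]
    wt(sign_model_table(m), paste0("model_", sg, ".tsv"))
  }
  writeLines(bundle$manifest, file.path(outdir, "manifest.tsv"))
  invisible(outdir)
}

#' @export
print.kbd_run <- function(x, ...) {
  cat("KBD association pipeline run\n")
  cat("  subjects:", nrow(x$cohort), " genes screened:", nrow(x$screen), "\n")
  cat("  DE genes:", length(x$de_genes), "\n")
  for (sg in names(x$models)) {
    m <- x$models[[sg]]
    k <- if (is.null(m) || is.null(m$fit)) 0 else
      nrow(m$fit$coefficients) - 1
    cat("  model[", sg, "]: ", k, " gene term(s)\n", sep = "")
  }
  invisible(x)
}
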