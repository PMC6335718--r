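#' Logistic regression by iteratively reweighted least squares
#'
#' Maximizes the Bernoulli log-likelihood of a logit model by Newton-Raphson
#' (IRLS), implemented in-package so the multivariable stage is fully
#' auditable: convergence is declared when the maximum absolute score drops
#' below `tol` or the relative deviance change does, standard errors come
#' from the inverse observed information, and each coefficient's "Sig" is
#' the Wald p-value \eqn{(B/SE)^2} on \eqn{\chi^2_1}. Complete or
#' quasi-separation (a predictor perfectly splitting the outcome) drives
#' coefficients to infinity; diverging coefficients are capped at `cap` and
#' flagged via `separation_detected` rather than reported silently.
#'
#' @param x Predictor matrix or data.frame (no intercept column; one is
#'   added). Columns must be named and jointly full rank.
#' @param y Binary 0/1 outcome with both classes present.
#' @param tol Convergence tolerance on score and relative deviance change.
#' @param max_iter Maximum IRLS iterations.
#' @param cap Absolute bound on coefficients used to contain separation.
#' @param lr_tests Also compute per-term likelihood-ratio p-values by
#'   refitting without each term (audit companion to the Wald "Sig").
#' @return Object of class `"kbd_logistic"`: list with `coefficients` (a
#'   data.frame: `term`, `B`, `SE`, `wald_chi2`, `p_wald`, `OR`,
#'   `or_ci_low`, `or_ci_high`, and `p_lr` when requested), `converged`,
#'   `n_iter`, `log_likelihood`, `deviance_trace`, `separation_detected`,
#'   `n`, `vcov`.
#' @examples
#' set.seed(1)
#' x <- matrix(rbinom(200, 1, 0.5), ncol = 1, dimnames = list(NULL, "gene"))
#' y <- rbinom(200, 1, plogis(-0.5 + 1.2 * x[, 1]))
#' fit_logistic_irls(x, y)$coefficients
#' @export
fit_logistic_irls <- function(x, y, tol = 1e-8, max_iter = 50, cap = 15,
                              lr_tests = FALSE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  if (any(is.na(x)) || any(is.na(y))) stop("missing values in design; drop them first")
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2) stop("outcome has a single class")
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  X <- cbind("(Intercept)" = 1, x)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }

  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    sum(y * eta - log1p(exp(eta)))
  }
  beta <- rep(0, ncol(X))
  dev_trace <- -2 * loglik(beta)
  converged <- FALSE
  iter <- 0L
  capped <- FALSE
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X, w * X)
    step <- tryCatch(solve(info, score),
                     error = function(e) stop("information matrix singular: ",
                                              conditionMessage(e)))
    new_beta <- beta + step
    # step-halve if the deviance would increase (guards early overshoot)
    halvings <- 0L
    while (-2 * loglik(new_beta) > dev_trace[length(dev_trace)] + 1e-12 &&
           halvings < 20L) {
      step <- step / 2
      new_beta <- beta + step
      halvings <- halvings + 1L
    }
    if (any(abs(new_beta) > cap)) {
      capped <- TRUE
      new_beta <- pmin(pmax(new_beta, -cap), cap)
    }
    dev_new <- -2 * loglik(new_beta)
    rel_change <- abs(dev_new - dev_trace[length(dev_trace)]) /
      (abs(dev_new) + 0.1)
    beta <- new_beta
    dev_trace <- c(dev_trace, dev_new)
    if (max(abs(score)) < tol || rel_change < tol) {
      converged <- max(abs(drop(crossprod(X, y - stats::plogis(drop(X %*% beta)))))) <
        max(tol, 1e-6) || rel_change < tol
      break
    }
    if (iter >= max_iter) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  pinned <- mu < 1e-8 | mu > 1 - 1e-8
  separation <- capped || (any(pinned) && max(abs(beta)) > 10)
  if (separation) converged <- FALSE

  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(X, w * X)
  vcov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  })
  se <- sqrt(diag(vcov))
  wald <- (beta / se)^2
  z <- stats::qnorm(0.975)
  coefs <- data.frame(
    term = colnames(X), B = unname(beta), SE = unname(se),
    wald_chi2 = unname(wald),
    p_wald = stats::pchisq(unname(wald), df = 1, lower.tail = FALSE),
    OR = exp(unname(beta)),
    or_ci_low = exp(unname(beta) - z * unname(se)),
    or_ci_high = exp(unname(beta) + z * unname(se)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  ll <- loglik(beta)
  if (lr_tests && ncol(x) >= 1) {
    p_lr <- rep(NA_real_, nrow(coefs))
    for (j in seq_len(ncol(x))) {
      sub <- x[, -j, drop = FALSE]
      ll0 <- if (ncol(sub)) {
        fit_logistic_irls(sub, y, tol = tol, max_iter = max_iter, cap = cap,
                          lr_tests = FALSE)$log_likelihood
      } else {
        p0 <- mean(y)
        sum(y * log(p0) + (1 - y) * log(1 - p0))
      }
      p_lr[j + 1L] <- stats::pchisq(2 * (ll - ll0), df = 1, lower.tail = FALSE)
    }
    coefs$p_lr <- p_lr
  }
  structure(list(coefficients = coefs, converged = converged, n_iter = iter,
                 log_likelihood = ll, deviance_trace = dev_trace,
                 separation_detected = separation, n = length(y),
                 vcov = vcov),
            class = "kbd_logistic")
}

#' @export
print.kbd_logistic <- function(x, ...) {
  cat("Logistic fit (IRLS): n =", x$n, ", iterations =", x$n_iter,
      ", converged =", x$converged, "\n")
  if (x$separation_detected) {
    cat("WARNING: separation detected; capped coefficients are not MLEs\n")
  }
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Univariate gene screen followed by a joint multivariable model
#'
#' The two-stage clinical-sign modelling procedure: stage 1 cross-tabulates
#' each gene's subject-level differential-expression status against the sign
#' and keeps genes whose uncorrected Pearson chi-square p is below `alpha`
#' (Fisher doubled p substitutes when a zero margin invalidates the
#' chi-square); stage 2 fits one joint logistic regression of the sign on
#' all retained genes, with no stepwise selection. Subjects missing the sign
#' or any retained gene's status are dropped listwise from stage 2.
#'
#' @param sign Binary 0/1 outcome vector (the clinical sign), NA allowed.
#' @param genes Matrix or data.frame of binary per-gene statuses, columns
#'   named by gene symbol.
#' @param alpha Stage-1 retention level, default 0.05.
#' @param ... Passed to [fit_logistic_irls()].
#' @return List of class `"kbd_sign_model"`: `stage1` (per-gene chi2, p,
#'   kept flag), `fit` (a `kbd_logistic`, or NULL when no gene survives —
#'   with a warning, not an error), `n_used`.
#' @export
univariate_screen_then_model <- function(sign, genes, alpha = 0.05, ...) {
  genes <- as.matrix(genes)
  if (is.null(colnames(genes))) stop("gene status columns must be named")
  if (nrow(genes) != length(sign)) stop("sign and genes sizes differ")
  stage1 <- do.call(rbind, lapply(colnames(genes), function(g) {
    keep <- !is.na(sign) & !is.na(genes[, g])
    tab <- tabulate_2x2(data.frame(g = genes[keep, g], s = sign[keep]),
                        "g", "s", or_numerator = "row1")
    chi <- pearson_chi2(tab)
    p <- if (chi$valid) chi$p else fisher_exact(tab)$p_two_sided_doubling
    data.frame(gene = g, chi2 = chi$chi2, chi2_valid = chi$valid, p = p,
               n = tab$a + tab$b + tab$c + tab$d, stringsAsFactors = FALSE)
  }))
  stage1$kept <- !is.na(stage1$p) & stage1$p < alpha
  kept <- stage1$gene[stage1$kept]
  if (!length(kept)) {
    warning("no gene passed the univariate screen at alpha = ", alpha,
            "; returning an empty model")
    return(structure(list(stage1 = stage1, fit = NULL, n_used = 0L),
                     class = "kbd_sign_model"))
  }
  sub <- genes[, kept, drop = FALSE]
  complete <- !is.na(sign) & stats::complete.cases(sub)
  fit <- fit_logistic_irls(sub[complete, , drop = FALSE], sign[complete], ...)
  structure(list(stage1 = stage1, fit = fit, n_used = sum(complete)),
            class = "kbd_sign_model")
}

#' Render a sign model in the published report layout
#'
#' Columns `Gene`, `B`, `S.E.`, `Sig` (Wald p), `OR`, one row per gene term
#' (intercept omitted).
#' @param model A `kbd_sign_model` or `kbd_logistic`.
#' @return data.frame (zero rows for an empty model).
#' @export
sign_model_table <- function(model) {
  fit <- if (inherits(model, "kbd_sign_model")) model$fit else model
  if (is.null(fit)) {
    return(data.frame(Gene = character(), B = numeric(), S.E. = numeric(),
                      Sig = numeric(), OR = numeric(),
                      stringsAsFactors = FALSE, check.names = FALSE))
  }
  co <- fit$coefficients
  co <- co[co$term != "(Intercept)", , drop = FALSE]
  out <- data.frame(Gene = co$term, B = co$B, S.E. = co$SE, Sig = co$p_wald,
                    OR = co$OR, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}
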