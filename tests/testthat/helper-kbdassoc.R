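# shared fixture builders (everything is generated in code; no stored data)

# cohort of n subjects with valid defaults; fields overridable
make_cohort <- function(n = 5, ...) {
  co <- data.frame(
    id = sprintf("C%03d", seq_len(n)),
    group = "KBD", grade = "I", gender = "female",
    age = 57, bmi = 21.7, height = 165, sitting_height = 87,
    leg_length = 78, metacarpal_length = 16.2, metacarpal_breadth = 8.1,
    stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (f in names(dots)) co[[f]] <- dots[[f]]
  co
}

# 80-subject sign cohort whose per-gene status x sign cross-tabs equal the
# given (a, b, c, d) tables; sign margin must be constant across genes
make_sign_cohort <- function(tables, sign = "phalanges_tuberositas") {
  n_pos <- unique(vapply(tables, function(t) t[1] + t[3], numeric(1)))
  n_neg <- unique(vapply(tables, function(t) t[2] + t[4], numeric(1)))
  stopifnot(length(n_pos) == 1, length(n_neg) == 1)
  out <- data.frame(sign = rep(c(1, 0), c(n_pos, n_neg)))
  names(out) <- sign
  for (g in names(tables)) {
    t <- tables[[g]]
    out[[g]] <- c(rep(c(1, 0), c(t[1], n_pos - t[1])),
                  rep(c(1, 0), c(t[2], n_neg - t[2])))
  }
  out
}

# small expression matrix from an explicit ratio matrix
make_expr <- function(ratios, housekeeping = rep(FALSE, nrow(ratios)),
                      symbols = sprintf("G%03d", seq_len(nrow(ratios)))) {
  expression_matrix(ratios, symbols = symbols, housekeeping = housekeeping,
                    subjects = sprintf("S%02d", seq_len(ncol(ratios))))
}

# independent quadrature of the error function, 2/sqrt(pi) * int_0^x e^{-t^2}
erf_quadrature <- function(x) {
  vapply(x, function(xx) {
    s <- sign(xx)
    v <- stats::integrate(function(t) exp(-t^2), 0, abs(xx),
                          rel.tol = 1e-13, abs.tol = 1e-15)$value
    s * 2 / sqrt(pi) * v
  }, numeric(1))
}

# brute-force Fisher enumeration over all tables with the observed margins
fisher_enumerate <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  support <- max(0, k - r2):min(r1, k)
  prob <- vapply(support, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, k - x) - lchoose(n, k))
  }, numeric(1))
  upper <- sum(prob[support >= a])
  lower <- sum(prob[support <= a])
  expected <- r1 * k / n
  one <- if (a >= expected) upper else lower
  p_obs <- prob[support == a]
  list(one_sided = one,
       doubling = min(1, 2 * min(upper, lower)),
       sum_small = sum(prob[prob <= p_obs * (1 + 1e-7)]))
}
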