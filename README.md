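# kbdassoc

Association analysis between clinical variables and gene expression in
Kashin-Beck disease (KBD), an endemic osteoarthropathy of articular
cartilage. The package is aimed at biostatisticians and epidemiologists
analysing case-control cohorts in which a custom two-channel expression
array (here 169 probes, 11 of them housekeeping) is paired with a clinical
questionnaire (binary signs, anthropometry, severity grade I/II).

## What it computes

* **Differential-expression screen.** Per-gene mean fold change ± SEM over
  case arrays, a standardized log-ratio deviation
  `xdev = mean(ln r) / σ̂` (null scale σ̂ from housekeeping probes by
  default), and the two-sided error-function p-value

  `P = 1 − Erf(|xdev|/√2) = Erfc(|xdev|/√2)`,

  with the strict call rule: DE iff fold change > 2 or < 0.5 **and**
  P < 0.05.
* **Clinical indexes.** Manouvrier's skelic index
  `(height − sitting height)/sitting height × 100`, the metacarpal
  length/breadth index and the metacarpal length/height index.
* **2×2 contingency statistics.** Uncorrected Pearson χ² (Yates variant
  behind a flag), Fisher's exact p in one-sided / doubled / sum-of-small-
  probability variants, odds ratios in an explicit orientation with Woolf
  logit intervals `exp(ln OR ± 1.96 √(1/a+1/b+1/c+1/d))`.
* **Rank and parametric comparisons.** Tie-corrected Mann-Whitney U with
  its Z statistic, Pearson correlation, pooled t / ANOVA / Kruskal-Wallis
  behind a Shapiro-Wilk normality gate.
* **Multivariable stage.** An in-package IRLS logistic regression (Wald
  and likelihood-ratio inference, separation detection) driven by a
  univariate-screen-then-joint-model procedure per clinical sign.
* **Synthetic cohorts.** An exact table-replay generator and a
  latent-severity model (defaults: 100 controls + 50 grade I + 50 grade II,
  gene shifts calibrated to the published fold changes) with a truth record
  for parameter-recovery tests.
* **Verification harness.** All 46 rows of the four published univariate
  tables are built in; `verify_printed_tables()` recomputes every
  comparable χ², Fisher p, OR and CI bound and reports pass/fail/skipped
  (typo rows are skipped with the reason, never compared).

## Worked example

```r
library(kbdassoc)

# the brachydactylia-by-grade table: counts (3, 27 / 49, 1),
# odds of the sign in grade II relative to grade I
tab <- contingency_2x2(3, 27, 49, 1,
                       row_labels = c("grade I", "grade II"),
                       col_labels = c("sign+", "sign-"),
                       or_numerator = "row2")
round(associate_2x2(tab)[c("chi2", "p_chi2", "odds_ratio",
                           "or_ci_low", "or_ci_high")], 3)
#>     chi2 p_chi2 odds_ratio or_ci_low or_ci_high
#> 1 63.824      0        441    43.713   4449.092

# census of the published fold-change list under the 2-fold rule
unlist(screen_table(kbd_de_foldchanges()$mean_fc))
#>   n_de   n_up n_down
#>     39     18     21

# a full synthetic run at study scale
run <- run_pipeline(run_config(simulate = severity_config(), seed = 7))
run
#> KBD association pipeline run
#>   subjects: 200  genes screened: 169
#>   DE genes: 19
#>   model[phalanges_tuberositas]: 19 gene term(s)
#>   model[brachydactylia]: 19 gene term(s)
```

The χ² of 63.824 says the brachydactylia rate differs sharply between
grades; the odds ratio 441 (Woolf 95% CI 43.7-4449) quantifies how much
more likely the sign is in grade II. The census partitions the 39 DE genes
into 18 up- and 21 downregulated. In the synthetic run, 19 of the 39
planted signal genes clear the strict 2-fold/P < 0.05 screen when grades
are pooled (grade I subjects sit at half the grade II log shift, so weaker
genes fall inside the band) and all 19 enter both sign models.

A thin command-line front end is installed at
`inst/scripts/kbd-pipeline.R` with verbs `simulate`, `run`, and `verify`.

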