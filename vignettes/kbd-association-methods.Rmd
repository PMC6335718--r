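---
title: "Methods: clinical-variable and gene-expression association analysis for Kashin-Beck disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clinical-variable and gene-expression association analysis for Kashin-Beck disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbdassoc)
```

## The scientific setting

Kashin-Beck disease (KBD) is an endemic osteoarthropathy driven by necrosis
of deep-zone chondrocytes in articular cartilage, graded clinically I-III by
severity. The analysis this package implements links two layers of data from
a case-control study design — 100 KBD patients (50 grade I, 50 grade II) and
100 matched controls — namely:

* a **clinical layer**: nine binary signs (phalanges tuberositas,
  brachydactylia, deformity and dyskinesia items), ten general-information
  items, and anthropometry from which three severity indexes are computed;
* an **expression layer**: a 169-probe custom two-channel array (including
  11 housekeeping probes) measuring linear-scale expression ratios in
  peripheral blood mononuclear cells.

The pipeline proceeds in the order the study design dictates: screen the
expression matrix for differentially expressed (DE) genes, compute clinical
indexes, correlate gene expression with the indexes, cross-tabulate gene
status against grade and against the two modelled signs, and finally fit a
multivariable logistic regression of each sign on the genes that survive a
univariate screen.

## Clinical indexes

Three dimensionless indexes, all scaled by 100, summarise skeletal
proportions (lengths in centimetres):

$$\mathrm{skelic} = \frac{\mathrm{height} - \mathrm{sitting\ height}}
  {\mathrm{sitting\ height}} \times 100, \qquad
\mathrm{MLB} = \frac{\mathrm{metacarpal\ length}}
  {\mathrm{metacarpal\ breadth}} \times 100, \qquad
\mathrm{MLH} = \frac{\mathrm{metacarpal\ length}}{\mathrm{height}}
  \times 100.$$

The skelic index is implemented in its classical Manouvrier form: leg length
relative to trunk (sitting) height. Questionnaire sources sometimes carry a
redundant leg-length column; `compute_indexes()` validates it against
`height - sitting_height` (warning beyond 0.5 cm) but never uses it in the
formula, which keeps the index dimensionless and scale-invariant. A literal
reading that multiplies by leg length would not be dimensionless, so it was
rejected as a transcription artefact.

## The expression screen

Two-channel ratios are analysed on the natural-log scale. For gene $g$ with
per-array ratios $r_{gj}$, the screen computes the mean fold change
$\bar r_g$ with its SEM, and a standardized deviation of the mean log ratio
from zero,

$$x_{dev,g} = \frac{\overline{\ln r_g}}{\hat\sigma},$$

whose two-sided p-value is the Gaussian tail expressed through the error
function:

$$P = 1 - \mathrm{Erf}\!\left(\frac{|x_{dev}|}{\sqrt 2}\right)
    = \mathrm{Erfc}\!\left(\frac{|x_{dev}|}{\sqrt 2}\right),
\qquad \mathrm{Erf}(x) = \frac{2}{\sqrt\pi}\int_0^x e^{-t^2}\,dt.$$

`erf_logratio_p()` evaluates this as `2 * pnorm(-|xdev|)` and is tested
against direct numeric quadrature of the integral to below 1e-10 across
$x_{dev} \in [0, 6]$.

**The null scale $\hat\sigma$.** The scale of the standardization is a
genuine design choice; three estimators are offered:

* `housekeeping` (default): the SD of the housekeeping probes' mean log
  ratios. Housekeeping probes are on the array precisely because they are
  assumed non-differential, so they estimate the null spread of a per-gene
  mean directly.
* `all_genes`: 1.4826 × MAD of all per-gene means — robust to the minority
  of truly differential genes.
* `fixed`: a user-supplied $\sigma$, interpreted as the null SD of a
  *per-gene mean* log ratio.

Because numerator and denominator share the logarithm base, $x_{dev}$ and
$P$ are invariant to computing in ln or log2 (asserted by a test).

**The call rule.** A gene is called DE iff its mean fold change is strictly
above 2 or strictly below 0.5 *and* $P < 0.05$. Thresholds are strict: a
fold change of exactly 2 is not called. The published 39-gene census
(18 up + 21 down) is re-derived from the printed fold-change column by
`screen_table()`. Per-subject gene status — the "+/−" entries of the
univariate tables and the predictors of the multivariable stage — applies
the same band to the individual subject's ratio (`de_status()`).

Optional housekeeping median-centring of each array is available
(`normalize_housekeeping()`) but off by default; the published fold changes
are reproduced without it.

## Contingency analysis

Every univariate association is a labelled 2×2 table. The package computes:

* the 1-df Pearson chi-square
  $\chi^2 = n(ad-bc)^2 / \big((a+b)(c+d)(a+c)(b+d)\big)$ with **no
  continuity correction by default**; a Yates-corrected variant exists
  behind `correct = TRUE`. The statistic is still computed with zero cells
  as long as margins are positive, and reported invalid (a dash) only on a
  zero margin;
* Fisher's exact hypergeometric p in three flavours — one-sided tail,
  doubled smaller tail, and sum of tables no more probable than the
  observed one — because published case-control tables are not consistent
  about two-sidedness. Both the astriction-style one-sided 0.138 and the
  alcohol-style doubled 0.291 conventions are reproduced and exposed;
* the odds ratio in the table's recorded orientation with the Woolf logit
  interval $\exp(\ln OR \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$. Any zero cell
  makes the OR undefined (rendered as a dash); a Haldane-Anscombe +0.5
  correction is available behind a flag, never silently.

**Orientation is metadata.** Grade tables report the odds of a sign in
grade II relative to grade I ($bc/ad$ in the printed layout); gene tables
report the odds of the sign in gene-positive relative to gene-negative
subjects ($ad/bc$). Each fixture row pins its orientation, and a row swap
provably inverts the OR while leaving $\chi^2$ unchanged.

**The built-in fixture suite.** `kbd_printed_tables()` encodes all 46 rows
of the four published univariate tables; `verify_printed_tables()`
recomputes every comparable value. Recomputation revealed that the
published grade-by-sign table mixes chi-square conventions: nine rows match
the uncorrected Pearson statistic and eight match the Yates-corrected one
(largely the rows with an expected count below 5, the classic software
default for when the correction is displayed). The fixture file records
which convention each printed value follows and the harness checks each row
under its own convention, labelling corrected rows as such. Three rows are
internally inconsistent (two gene rows whose printed statistics belong to
each other's counts, and one OR that is a digit-transposition typo of the
value its own CI implies); these are reported as `skipped`, never compared,
and their counts remain available for structural tests.

## Rank tests, correlations, and the normality gate

Mann-Whitney U is implemented directly (mid-ranks, tie-corrected normal
variance) because the reported tables print the Z statistic alongside the
p-value; the p is cross-checked against `wilcox.test`'s normal
approximation. Pearson correlations between per-gene log ratios and the
clinical indexes use `cor.test`. `compare_groups()` applies the
conventional gate: Shapiro-Wilk per group at 0.05, parametric tests
(pooled t, one-way ANOVA) when all groups pass, rank tests (Mann-Whitney,
Kruskal-Wallis) otherwise — both families always reported.

## The multivariable stage

`fit_logistic_irls()` maximizes the Bernoulli log-likelihood of a logit
model by Newton-Raphson with step-halving, entirely in-package:

* convergence: max |score| < `tol` (1e-8) or relative deviance change <
  `tol`, within `max_iter` = 50 iterations; the deviance trace is exposed
  and is non-increasing;
* inference: SEs from the inverse observed information; per-term "Sig" is
  the Wald $(B/SE)^2$ p on $\chi^2_1$, with per-term likelihood-ratio p
  available for audit (`lr_tests = TRUE`);
* separation: coefficients are capped at ±15 and the fit flagged
  (`separation_detected`) when a predictor perfectly or nearly perfectly
  splits the outcome. Published model tables occasionally show the
  signature of this pathology — a huge negative coefficient with a large SE
  and an OR that is not `exp(B)` — and the flag documents how such a row
  should be read. Capped estimates are never presented as MLEs.

`univariate_screen_then_model()` implements the two-stage procedure: keep
genes whose 2×2 association with the sign has chi-square p < 0.05 (Fisher
doubled p when the chi-square is invalid), then fit all survivors jointly —
no stepwise selection, matching the full rosters of the published model
tables. Predictors are binary per-gene DE statuses by default; continuous
log-ratio predictors work through the same fitting function.

Coefficient-level published values are *not* reproduction targets: they
require the unavailable subject-level data, and the printed tables are
internally inconsistent (one table prints B = 3.95 with OR = 11.54 although
$e^{3.95} \approx 52$). Instead the stage is validated by closed forms (a
single binary predictor's slope equals $\ln(ad/bc)$ with Woolf SE),
equivalence with an independent BFGS optimizer of the same likelihood to
1e-6, nominal Wald type-I error, and 93-97% Wald CI coverage on cohorts
generated with known coefficients.

## The synthetic cohort generator

The generator is first-class, tested code in two modes.

**Replay mode** (`generate_replay()`) reconstructs a cohort whose
cross-tabulation equals any target 2×2 table cell-for-cell — integer
equality, checked over every fixture row — so the full association stack
can be exercised end-to-end on exactly the published margins. The seed only
shuffles subject order; same seed, byte-identical files.

**Latent-severity mode** (`generate_model_cohort()`) draws one latent
severity scalar per subject by stratum (defaults: mean 0/1.5/3, SD 1 for
control/grade I/grade II) and derives everything else from it:

* each questionnaire item is Bernoulli with a logistic link on severity;
  default intercepts/slopes are solved once from the published grade I/II
  prevalences at the default stratum severities, so simulated grade
  contrasts echo the printed tables in expectation;
* each gene's log ratio is `lnfc * s / 3 + N(0, 0.25²)`, where `lnfc` is
  the log of the gene's published mean fold change — a grade-II subject's
  expected ratio is the published fold change, a control's is 1;
  housekeeping and filler probes (to 169 total) carry zero shift;
* anthropometry is Gaussian by stratum with grade means echoing the
  published continuous-variable table (metacarpal length 16.7 vs 15.8 cm,
  breadth 8.01 vs 8.22 cm); sitting height is a fraction (0.53 ± 0.01) of
  height and leg length their difference;
* an optional missing-data rate blanks questionnaire cells to exercise the
  exclusion path;
* the truth record carries the config, the per-subject severities and the
  per-gene loadings for recovery tests.

The single latent scalar is the simplest structure consistent with signs,
indexes and expression co-varying with disease grade; it is a modelling
convenience, not a claim about KBD biology. Real data differ in ways the
generator deliberately omits: sign-specific dependence beyond one factor,
array artefacts (dye bias, spatial effects, background), selenium and
biochemical covariates, and within-stratum correlation between
anthropometry and severity. Passing tests therefore demonstrate the
*statistical machinery* — calibration, recovery, exactness of the
contingency stack — not fidelity of any biological conclusion.

## Numerical choices and degenerate inputs

* Strict inequalities at every threshold (fold change 2/0.5, all alphas).
* Chi-square: invalid only on a zero margin; zero cells allowed.
* Fisher: degenerate margins give p = 1 (one table possible).
* OR: undefined with any zero cell unless Haldane requested.
* Mann-Whitney: all-tied data give Z = 0, p = 1, not NaN.
* Correlations: at least 3 complete pairs and positive variance, else an
  error naming the problem.
* IRLS: weights floored at 1e-10; step-halving guards overshoot;
  coefficient cap 15; rank checked via QR with collinear columns named.
* The severity generator truncates sitting-height fractions to (0.45,
  0.62) and floors lengths at a fifth of the control mean so degenerate
  anthropometry cannot arise at extreme seeds.

## Problem sizes used by the test suite

Simulation-based checks run at sizes chosen to make their acceptance bands
sharp while keeping the suite fast: 10⁴ vectorised tables for Woolf
coverage (band 93-97%), 10³ generator-plus-fit replicates for coefficient
recovery (93-97%), 2×10³ replicates for each type-I error check (band
3-7%), 5×10³ genes for the uniform-p Kolmogorov check (distance < 0.05).
End-to-end runs use the study-scale design, 200 subjects × 169 probes,
which completes in about a second.

## Known limitations

* The per-grade DE census depends on subject-level data that are not
  published; only the overall 39-gene census is a fixture.
* No multiple-testing correction is applied by default, mirroring the
  original analysis; Bonferroni/BH columns can be added downstream via
  `p.adjust` on any report column.
* No stratified (Mantel-Haenszel) analysis, exact OR intervals, or r×c
  tables beyond 2×2 (Kruskal-Wallis excepted).
* The logistic stage offers no penalized fallback; separation is flagged,
  not resolved.
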