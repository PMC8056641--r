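---
title: "Methods: gestational age clocks, robust evaluation and GA acceleration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gestational age clocks, robust evaluation and GA acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the models, the parameters that matter, the simulator that stands in for
restricted cohort data, and the numerical and design choices that were
genuinely open.

## The clock model

An epigenetic gestational age (GA) clock is a sparse linear model on the
beta scale,

$$\widehat{GA}_i = \beta_0 + \sum_{j \in S} \beta_j \, x_{ij},$$

where $x_{ij} \in [0,1]$ is the methylation beta value of CpG $j$ in
newborn $i$ and $S$ is a small set of CpGs selected by the Lasso,

$$\min_{\beta_0, \beta} \; \frac{1}{2n}\sum_i \big(y_i - \beta_0 -
x_i^\top\beta\big)^2 + \lambda \lVert \beta \rVert_1 ,$$

with $y$ the clinical (ultrasound) GA in days. Betas are bounded and the
true CpG–GA relationship is sigmoidal at the extremes; fitting on the beta
scale assumes the active CpGs sit in the quasi-linear middle of their
response, which holds for the moderate slopes seen over the ~85-day
clinical GA range.

Training composes: median imputation of missing betas (per probe, across
samples; a probe with no observed values falls back to a supplied median,
e.g. a clock's stored training medians) → K-fold cross-validated selection
of $\lambda$ → a final fit at the selected $\lambda$ on all training
samples. The trained object stores the training medians of its CpGs so that
prediction on arrays lacking some CpGs can impute them; a CpG that is
absent *and* has no recorded median is excluded from the linear
combination, with a count — the conventional treatment when applying a
published clock to a platform that lacks some of its probes.

### Tuning parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 1 | pure Lasso; elastic-net mixing is out of scope |
| `n_folds` | 10 | CV folds; seeded random near-equal partition, no stratification |
| `lambda_grid` | 100 points, $\lambda_{max}$ down to $10^{-3}\lambda_{max}$, log-spaced | $\lambda_{max}$ is the smallest penalty with an all-zero model |
| `lambda_rule` | `"min"` | `"1se"` picks the largest $\lambda$ within one SE of the CV minimum |
| `train_fraction` | 0.8 | train/test split fraction |
| `standardize` | `TRUE` | predictors scaled to unit $1/n$-variance internally; coefficients reported on the beta scale |

The penalty-selection rule is genuinely underdetermined in practice —
reported $\lambda$ values from real cohorts are data-dependent and cannot
identify the rule — so both rules are exposed and `"min"` is the default
(it optimises prediction error, which is what the evaluation measures).
Fold assignment is seeded, so training is reproducible end to end.

### Numerical choices

The Lasso is solved by cyclic coordinate descent with soft-threshold
updates, warm starts along the decreasing $\lambda$ path, and an active-set
strategy (full sweep; then sweeps over the nonzero set until stable; then a
final full sweep to catch violators). Convergence follows the convention of
the ecosystem's penalised-regression solvers: stop when the largest squared
coordinate update falls below `tol * var(y)` (`tol = 1e-7`); an absolute
threshold is a poor criterion here because the response is in days and the
saturated tail of the path (hundreds of active coordinates when
$\lambda \to 10^{-3}\lambda_{max}$) converges geometrically but slowly.
Each solution's maximum KKT violation is reported; with a tightened `tol`
the objective agrees with an independent solver to better than $10^{-6}$
relative (asserted in the test suite). $\lambda_{max}$ is computed with the
same centring, scaling and accumulation order as the solver's gradient so
that $\lambda \ge \lambda_{max}$ yields the null model *exactly*, not up to
rounding. Constant probes are excluded from penalised fitting (their scale
is undefined); constant responses are an error at cross-validation time.

## Robust evaluation

Predicted GA is regressed on clinical GA with an MM-type estimator:

1. **S-stage** — 500 seeded two-point subsamples propose candidate lines;
   each is scored by the 50%-breakdown M-scale of its residuals (bisquare
   $\rho$, tuning $c = 1.548$, consistency constant $b = 0.5\,c^2/6$),
   solved by fixed-point iteration with an early-rejection test against the
   best scale so far; the winner is refined by reweighted least squares
   with simultaneous scale updates.
2. **M-stage** — IRLS with bisquare weights at $c = 4.685$ (95% Gaussian
   efficiency), the scale held fixed from stage 1, until the maximum
   relative coefficient change is below $10^{-7}$ or 200 iterations;
   non-convergence is flagged in the result, not thrown.

The subsample count is fixed and seeded so the stochastic initialiser is
deterministic. An exact-fit configuration (the majority of points on one
line) drives the M-scale to zero; the code then reports the exact line with
unit weights rather than dividing by a zero scale.

Three metrics summarise a prediction set:

* **R²** — `1 - sum(w r^2) / sum(w (pred - mean_w(pred))^2)` with the final
  bisquare weights `w` and robust residuals `r`; this weighted form is what
  robust-regression summaries report. A plain squared-correlation option is
  available (`r2_method = "cor"`).
* **SE** — the robust residual scale of the MM fit, in days. The quantity
  reported under this name alongside robust fits is not uniquely defined in
  the literature; the residual scale is the natural per-fit dispersion and
  is the interpretation adopted here.
* **MAD** — `median(|pred - obs|)` in days, deliberately *without* the
  1.4826 Gaussian consistency factor: it is a direct accuracy statement,
  not a scale estimate.

The regression direction is DNAm-on-clinical by default; descriptions of
such analyses appear in both directions in the literature, so a
`direction` argument swaps it (MAD is unaffected).

### Paired bootstrap

Two prediction sets on the same individuals are compared by drawing, in
each of `n_boot` replicates, one resample of individuals with replacement
and evaluating *both* sets on it — pairing removes the shared sampling
variability, and no model is refit because all three metrics are functions
of (observed, predicted) pairs only. 95% percentile intervals of the
replicate differences decide significance (interval excludes zero).
Replicates where the robust fit fails (e.g. a degenerate resample with
constant clinical GA) are dropped and counted; more than 5% dropped raises
a recorded warning. Bootstrap index draws and per-replicate MM subsampling
seeds all derive from one seed.

## Probe quality control

`filter_probes()` removes, in a fixed order: cross-reactive probes,
detection failures, SNP-overlapping probes (last three bases), and
non-autosomal probes. The order is fixed so per-stage removal counts are
deterministic and recountable. The detection rule defaults to
*any-sample*: one sample with detection p above the threshold (default
0.01) removes the probe; `detp_fraction = f` switches to the
at-least-a-fraction-`f` dialect (e.g. `f = 0.25`) used by some cohorts.
The published pipelines this mirrors do not state the per-sample rule
precisely, so both dialects are exposed. `restrict_to_platform()` keeps
the intersection with a platform probe list (e.g. the ~397K CpGs shared by
the 450K and EPIC arrays) in matrix order.

## Embryo-transfer-date gestational age

For ART records, whole-day arithmetic with a 14-day convention:

* fresh, retrieval known: `(birth - retrieval) + 14`;
* fresh, retrieval unknown: insertion stands in for retrieval + 2 culture
  days, so `(birth - insertion) + 16`;
* frozen: `(birth - insertion) + 14 + (freeze - retrieval)`, crediting the
  embryo its pre-freezing development; the freeze-retrieval difference is
  required nonnegative by the sheet's date-order invariants.

Whether the 14-day convention applies before or after rounding partial
days is not specified anywhere authoritative; all dates are calendar dates
here, so whole-day arithmetic is assumed throughout. Intrauterine
insemination is classified non-ART and rejected by `compute_etd_ga()`.

## GA acceleration

GAA is the residual from an *ordinary least squares* regression (with
intercept) of DNAm GA on clinical GA — deliberately not the robust fit:
the convention for acceleration residuals is a plain linear regression,
and the package preserves the contrast between the robust evaluation fit
and the plain GAA fit. The association test is a maximum-likelihood
logistic regression of the group label (ART vs non-ART, ICSI vs IVF,
frozen vs fresh — subgroup contrasts just relabel the groups) on GAA, with
a Wald p-value for the GAA coefficient. The fit pools both groups in one
regression; a reference-group-only residualisation would also be
defensible, but pooling matches how such analyses describe their sample
sizes. Perfect separation is detected (via the fitting warnings or an
exploding coefficient) and reported as "not estimable" rather than a
misleadingly tiny p-value.

## The cohort simulator

`simulate_cohort()` draws:

* **GA** from a normal distribution truncated to `[216, 301]` days with
  centre 281 and sd 11 — the range and median reported for the cord-blood
  cohorts such clocks are trained on; only range and median are published,
  so a truncated normal is used rather than an empirical distribution.
* **Active CpGs**: `n_active` probes whose logit-scale methylation is
  `baseline + slope * (GA - 281) + N(0, noise_sd)`; inactive probes are
  baseline plus noise. Baselines are `logit(U(0.05, 0.95))`. The inverse
  logit keeps every beta strictly inside (0, 1) for any configuration.
  Signal is injected on the logit (M-value-like) scale while clocks fit on
  the beta scale — mirroring practice, where betas are regressed directly —
  and the moderate slopes keep that mismatch in the quasi-linear range.
* **Slopes**: `+/- effect_sd` with random signs by default. Equal
  magnitudes make every active probe equally detectable, which is what
  parameter-recovery tests need to be meaningful; `slope_dist = "normal"`
  draws heterogeneous effects instead. Given a target `signal_fraction`
  $f$ — the squared correlation between GA and the best linear combination
  of the active-probe logits — the slope magnitude solves
  $f = (1 + \sigma^2 / (\mathrm{Var}(GA)\, K s^2))^{-1}$ using the
  truncated-normal GA variance in closed form.
* **ART metadata**: a configured fraction of ART samples (default 0.45,
  the make-up of the cohorts emulated), split into ICSI/IVF and
  frozen/fresh; procedure dates are generated so the ETD rules recover the
  true GA exactly (fresh transfers two days after retrieval; frozen
  embryos frozen 2–6 days after retrieval, stored 30–365 days).
* **GA acceleration**: `gaa_shift_days` moves the *methylation-implied* GA
  of ART samples — acceleration is by definition a DNAm-vs-clinical
  discrepancy, so the shift enters the methylation signal, not the
  clinical GA. Zero simulates the null.

The population probe model (which probes are active, slopes, baselines) is
keyed to `cfg$seed` alone; `simulate_cohort(cfg, sample_seed = s)` draws
fresh individuals from the *same* population, so a clock trained on one
simulated cohort is applicable to others — the design the type-I-error and
power simulations rely on.

What the simulator does **not** emulate: probe-type chemistry differences,
batch effects, cell-composition heterogeneity, correlated CpG blocks, or
GA-dependent missingness. Passing tests therefore demonstrate correctness
of the statistical machinery under the stated generative model, not
performance on real arrays.

## Problem sizes in the test suite

The heavier checks run at sizes chosen to make their Monte-Carlo bands
meaningful while keeping the suite quick: support recovery on an
800-train/200-test cohort with 5000 probes and 30 active CpGs at signal
fraction 0.8; bootstrap calibration over 200 outer replications of 300
replicates at n = 200; GAA size over 500 cohorts of n = 300 and power over
50 cohorts of n = 800 against a 500-probe population; the robustness
contrast at n = 500 with a 20% contaminated cluster (placed on the
lowest-GA quintile — contamination uncorrelated with GA would shift only
the intercept, so a slope-level contrast requires structured outliers).
The end-to-end demo and the acceptance script use a 600-sample,
4000-probe cohort.

## Known limitations

* The Lasso path solver is dense (no sparse-matrix input) and single
  threaded; cohorts far beyond ~10⁵ probes per fold will be slow.
* The robust R² can stray marginally outside [0, 1] at non-converged fits;
  convergence is flagged on every result.
* `compute_etd_ga()` trusts calendar dates; it has no plausibility window
  beyond positivity and the sheet's date-order invariants.
* The GAA test is unadjusted (no covariates such as maternal BMI or birth
  weight); multivariable adjustment is out of scope.
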