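---
title: "Placental epigenetic clocks: models, parameters and design choices"
author: "plclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placental epigenetic clocks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plclock)
```

## The problem

The placenta remodels its DNA methylation profile continuously over
gestation, strongly enough that gestational age (GA) can be read back from
an Illumina methylation array of placental tissue. `plclock` implements the
full workflow for building and using such placental epigenetic clocks:
harmonizing and quality-controlling beta matrices, fitting sparse
penalized-regression clocks, quantifying GA acceleration, imputing fetal
sex from autosomal methylation, and running a stratified epigenome-wide
association study (EWAS) of GA that is robust to confounding by pregnancy
conditions such as preeclampsia.

All inputs are assumed to be already-normalized beta values
$\beta \in [0,1]$ (the ratio of methylated to total fluorescence signal).
Array normalization, IDAT parsing and batch correction are out of scope by
design: clocks of this family are deliberately trained across heterogeneous
normalization pipelines so that they transfer between them.

## The clock model

A clock is a sparse linear predictor

$$\widehat{GA}_i \;=\; b_0 + \sum_{j \in S} b_j\,\beta_{ij},$$

with $S$ a small set of CpGs selected by an elastic net. Training minimizes

$$\frac{1}{2n}\sum_i\left(y_i - b_0 - x_i^\top b\right)^2
  + \lambda\left(\alpha\|b\|_1 + \tfrac{1-\alpha}{2}\|b\|_2^2\right)$$

via `glmnet`. Tunable parameters, with defaults:

* `alpha = 0.5` — equal L1/L2 mixing, the conventional choice for
  methylation clocks: the lasso component yields a sparse, portable CpG
  panel while the ridge component stabilizes selection among correlated
  probes.
* `lambda` — chosen as the value minimizing the mean cross-validated MSE
  over a path of 100 log-spaced values from $\lambda_{max}$ (the smallest
  value zeroing every coefficient) down to $10^{-4}\lambda_{max}$.
* `n_folds = 10`, `fold_seed` — cross-validation folds are assigned
  reproducibly from the seed, stratified by GA quartile. Stratification is
  our choice where the convention is silent; it stabilizes the CV curve
  when GA distributions are skewed toward term, as placental cohorts are.
* `standardize = TRUE` — predictors are standardized internally during
  fitting; reported coefficients are always on the original beta scale
  (weeks per unit beta).

Three clock variants differ only in their training data and candidate
probes: a *robust* clock trained on all pregnancies including complicated
ones; a *control* clock trained with
`sample_filter = function(s) s$condition == "control"`; and a *refined*
clock for uncomplicated term pregnancies, trained with
`filter_uncomplicated_term()` (control and `ga_weeks > 36`) and with
`probe_subset` restricted to the parent clock's CpGs — which guarantees the
refined panel nests inside the parent panel.

`predict_ga()` applies any coefficient table, including externally
published clocks read with `read_clock()`, so cross-clock comparisons use
one code path.

### GA acceleration

GA acceleration is the raw residual from the OLS regression of predicted on
observed GA. By least-squares orthogonality it is exactly uncorrelated with
observed GA, which is what makes it usable as an age-adjusted exposure or
outcome. The standardized variant (residual / SD) is provided because
violin-plot style condition comparisons are conventionally drawn on that
scale. We default to raw residuals.

### Fetal sex classifier

`train_sex_classifier()` fits a logistic elastic net (binomial deviance,
same `alpha`/`lambda` machinery) of sex on autosomal beta values. Passing a
probe manifest enforces the autosomal restriction, which is the entire
point of the classifier: it works on datasets whose sex-chromosome probes
were stripped during preprocessing. A predicted probability of exactly 0.5
is resolved deterministically to the negative class.

## Quality control

`detect_outliers()` implements a three-step gold-standard recipe:

1. the gold standard profile is the per-probe median beta across **all**
   samples (prospective outliers included — the profile is computed once,
   never iteratively re-estimated);
2. each sample is Pearson-correlated with the gold standard over probes
   non-missing in both;
3. samples with $r < 0.9$ (`min_correlation`) are excluded. A
   zero-variance sample has no defined correlation and is excluded with
   reason `"constant profile"`.

Medians of even counts average the two central values. `impute_missing()`
replaces each missing cell with the probe's gold-standard median; it is a
pure transform, and the policy of imputing *training data only* belongs to
the calling pipeline, not the operation. Exact-duplicate sample ids are
rejected by the readers; correlation-based replicate detection is out of
scope.

## The EWAS

Within each stratum (by convention the `condition` label, so that a
condition that both shortens gestation and perturbs methylation cannot
induce spurious GA associations), every probe is tested with the biweight
midcorrelation:

$$u_i = \frac{x_i - m_x}{9\,d_x},\qquad
  a_i = (1-u_i^2)^2\,\mathbf{1}[|u_i|<1],\qquad
  \tilde{x}_i = (x_i - m_x)\,a_i,$$

$$\mathrm{bicor}(x,y) =
  \frac{\sum_i \tilde{x}_i\tilde{y}_i}
       {\sqrt{\sum_i \tilde{x}_i^2}\sqrt{\sum_i \tilde{y}_i^2}},$$

with $m_x$ the median and $d_x$ the (unscaled) median absolute deviation.
If $d_x = 0$ the statistic degenerates and we fall back to Pearson,
flagged. We deliberately omit the outlier-proportion cap that some
screening implementations add (`maxPOutliers`); the plain formula above is
the contract. Probes with missing cells are tested on pairwise-complete
observations with the per-probe $n$ recorded.

Per stratum, $t = r\sqrt{(n-2)/(1-r^2)}$ gives a two-sided Student-t
p-value, and $z = \mathrm{sign}(r)\,\Phi^{-1}(1-p/2)$ — derived from the
p-value so each stratum's $(z, p)$ pair is self-consistent by
construction. Strata are combined per probe by weighted Stouffer:

$$Z_{meta} = \frac{\sum_i Z_i \sqrt{n_i}}{\sqrt{\sum_i n_i}},\qquad
  p_{meta} = 2\,(1 - \Phi(|Z_{meta}|)).$$

Numerical choices: tail probabilities are computed on the log scale, so
$|z| \approx 10$ yields $p \approx 10^{-24}$ instead of underflowing to
zero; $|r| = 1$ maps to the smallest representable double with $z$ capped
at $\pm 40$; p-values are floored at the same minimum. Significance is a
fixed genome-wide threshold $p_{meta} < 10^{-7}$, with no further
multiple-testing correction — that is the field's rule for this analysis.
`annotate_and_tabulate()` counts significant probes by CpG-island relation
and per gene (a probe annotated to several genes counts toward each; ties
rank alphabetically).

## The simulator

`simulate_dataset()` generates the statistical structure the analyses
assume, with full ground truth:

* GA $\sim$ Uniform over `ga_range` (default 6–42 weeks). Condition
  assignment happens **before** the GA draw, and affected samples have
  their GA shifted by `ga_shift_weeks` — the arrow "condition → earlier
  delivery" of the selection-bias mechanism, so stratified analyses can be
  shown to remove the induced confounding.
* Clock CpGs drift linearly: $\mu_j(GA) = \mathrm{clip}(a_j + b_j\,GA,\,
  0.02,\,0.98)$ with $a_j \sim U(0.1, 0.9)$ and slopes of random sign and
  magnitude in `slope_range` (default 0.005–0.02 per week). Other probes
  have constant means; sex probes are shifted by `sex_effect` in males;
  condition probes by `dnam_shift` in affected samples.
* Observed betas are Beta-distributed, $\beta \sim
  \mathrm{Beta}(\mu\varphi, (1-\mu)\varphi)$ with concentration
  $\varphi$ = `noise_precision` (default 50, i.e. an SD of ~0.07 at
  $\mu = 0.5$). Beta noise rather than logit-normal keeps values in
  $[0,1]$ with a single dispersion knob and no transform.
* Whole-sample outliers are i.i.d. Uniform(0,1) profiles; missingness is
  uniform at random; everything is reproducible from `seed`.

`standard_scenarios()` fixes five study conditions used across the test
suite: `clock_recovery` (400 samples × 2,000 probes, 50 clock CpGs),
`ewas_twostrata` (831 control + 70 preeclampsia, the stratum sizes of the
motivating analysis, with a −6-week delivery shift and +0.10 methylation
shift at 100 CpGs), `ewas_null` (200 × 5,000, 10 signal CpGs, for type-I
calibration), `sex_sep` (300 samples, 50 sex CpGs at effect 0.2) and
`qc_outliers` (96 clean + 4 planted outliers × 5,000 probes). Probe counts
of 2,000–5,000 are deliberate desk-scale choices — large enough for
calibration statistics, small enough that the whole suite runs in well
under a minute of simulation time.

What the simulator does *not* emulate: probe-chemistry artifacts (type
I/II), batch structure, cell-composition shifts, copy-number effects on
beta, and realistic cohort GA mixtures (GA is uniform unless shifted).
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative model, not performance on real
arrays.

One consequence of the bounded-mean design worth knowing: a clock CpG whose
baseline sits near the boundary can have its linear trend saturate at the
clip limits over much of the GA range, leaving little detectable signal.
This mirrors the real biology of bounded beta values, and it is why
"signal probes dominate the top of the EWAS ranking" is the property we
assert, rather than every planted probe beating every null probe.

## Evaluation

`evaluate_clock()` reports the median absolute error (MAE, weeks) and
Pearson $r$. The MAE interval is a seeded percentile bootstrap over paired
resamples ($B = 1000$ by default); the $r$ interval is Fisher-z. The CI
method for published clock evaluations of this kind is typically
unstated, so these are our documented choices and are not expected to
reproduce any published interval endpoints. `compare_clocks()` applies the
same machinery across models and subgroups (all samples, late gestation,
uncomplicated term, per condition).

## Degenerate inputs and conventions

* Beta readers reject values outside $[0,1]$ and duplicate identifiers,
  naming the offender; `0` and `1` are accepted unchanged.
* Clock coefficient files are CSV `CpG,Coefficient` with the intercept row
  labelled `(Intercept)`; zero coefficients are dropped on write. The
  reader requires an intercept row by default because every clock this
  package trains has one; `require_intercept = FALSE` covers published
  tables that omit it (intercept 0).
* Constant observed GA is an error for acceleration and evaluation;
  constant *predictions* (an intercept-only clock) leave $r$ as `NA` while
  MAE remains defined.
* The packaged coefficient files under `inst/extdata/` are **synthetic**
  stand-ins with the real clocks' structure (558 RPC CpGs, 546 CPC CpGs
  sharing 199 with the RPC, a 395-CpG refined panel nested in the RPC, a
  220-CpG sex classifier); their weights are random and carry no
  biological meaning.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(standard_scenarios()$clock_recovery)
qc <- detect_outliers(sim$beta)
clean <- impute_missing(sim$beta[!rownames(sim$beta) %in%
                                   qc$excluded_samples, ])

test_ids <- sim$sheet$sample_id[301:400]
model <- train_clock(clean[!rownames(clean) %in% test_ids, ], sim$sheet,
                     fold_seed = 7, name = "robust")
pred <- predict_ga(model, clean[test_ids, ])
evaluate_clock(pred, sim$sheet$ga_weeks[match(test_ids,
                                              sim$sheet$sample_id)])
ga_acceleration(pred, sim$truth$ga[test_ids])
```

## Known limitations

* Real-cohort accuracy claims are outside what synthetic data can
  establish; the package validates machinery, not biology.
* The EWAS z-statistics use the Student-t normal-quantile construction;
  alternative screening implementations that post-process bicor
  differently will agree closely but not bit-exactly.
* `train_clock()` requires at least two candidate probes (the underlying
  solver's contract) and does not implement nonlinear age transforms —
  gestational age needs none.
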