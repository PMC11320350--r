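---
title: "Methods: building and validating a mortality-trained proteomic aging clock"
author: "protclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating a mortality-trained proteomic aging clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protclock)
```

## Overview

`protclock` builds a second-generation biological-age measure: instead of
training a predictor of chronological age, it trains a predictor of
all-cause mortality and expresses each person's risk on the age scale.
This vignette records the model, the assumptions, the tunable parameters,
the numerical choices, and what the synthetic-data tests do and do not
establish about real cohorts.

## The Gompertz proportional-hazards backbone

Adult all-cause mortality is well described by a hazard growing
exponentially with time — the Gompertz law. We parameterize

$$h(t \mid x) = \exp(\beta_0 + a\,t + x'\beta),$$

with $t$ in years since baseline, shape $a$ (1/years), log baseline rate
$\beta_0$, and covariate log hazard ratios $\beta$. Chronological age at
baseline enters as a covariate, so the timescale is follow-up time; this
matches a design in which baseline age is an input to the clock. (Using
age itself as the timescale is a coherent alternative; we chose
time-on-study because the clock must map a *baseline* covariate vector to
a risk, and the fitted age coefficient then absorbs the age gradient of
mortality.)

The censored-data log-likelihood has the closed form

$$\ell = \sum_i d_i(\beta_0 + a t_i + x_i'\beta)
        - \sum_i e^{\beta_0 + x_i'\beta}\,\frac{e^{a t_i} - 1}{a},$$

which `fitGompertz()` maximizes by full Newton iterations with analytic
gradient and Hessian, starting from $a = 0.05$, $\beta_0 = \log$(crude
event rate), $\beta = 0$, with step-halving line search. Convergence
requires the per-observation scaled gradient norm below $10^{-9}$; on
failure the start is perturbed deterministically and refitted (at most
three restarts) before erroring with diagnostics. $(e^{at}-1)/a$ and its
derivatives in $a$ are evaluated with series expansions for $|a|$ near
zero, so the exponential limit $a \to 0$ is handled continuously.
Standard errors come from the observed information. The test suite checks
the fit against an independent Gompertz implementation (flexsurv) and
against the generating parameters of simulated cohorts.

## Protein selection

Selection uses an L1-penalized Cox partial likelihood over all proteins
plus chronological age. We standardize the design ourselves (population
sd) and run the penalized fit with standardization disabled, so the
optimized objective is exactly

$$-\tfrac{1}{n}\,\ell_{\text{Breslow}}(\beta_{\text{std}})
  + \lambda \lVert \beta_{\text{std}} \rVert_1 ,$$

with coefficients reported back on the original scale. This makes the
Karush–Kuhn–Tucker conditions directly checkable: `coxKKTResidual()`
recomputes the Breslow score analytically and verifies
$|s_j|/n \le \lambda$ for inactive and $s_j/n = \lambda\,\mathrm{sign}(\beta_j)$
for active coefficients at every path point. Breslow tie handling is used
inside the penalized fit (the standard choice for coordinate-descent
solvers); the unpenalized validation models use the more accurate Efron
approximation.

By default age is penalized together with the proteins, since the
selection step is run on the pooled design; `unpenalizedAge = TRUE`
protects it when the analyst wants age always retained. The penalty is
chosen by 10-fold cross-validated partial-likelihood deviance
(`selectLambda()`), with seed-derived fold assignment for exact
reproducibility; a fixed published value can be supplied instead. Whether
a published penalty was itself cross-validated is usually unstated, so
the fixed mode makes no claim beyond reproducing the number.

## From risk to proteomic age

The clock is a pair of Gompertz models sharing the training rows: a
*full* model on age + selected proteins and an *age-only* reference. Over
a horizon of $k$ years the full model assigns cumulative risk

$$M = 1 - \exp\!\Big\{-e^{\beta_0 + x'\beta}\,\frac{e^{ak}-1}{a}\Big\},$$

and the proteomic age is the age $A$ at which the reference model reaches
the same risk — risk matching, the construction used by established
mortality-trained clocks. Because the reference has a single covariate,
the inversion is closed-form:

$$A = \frac{\log\{-\log(1-M)\,a_0/(e^{a_0 k}-1)\} - \beta_{00}}{\beta_{age,0}}.$$

The tests verify this closed form against a bisection root-finder to
$10^{-8}$ years. Two degeneracies are guarded: $M$ numerically 0 or 1
(no finite age matches; an error, not a clamp), and a non-positive age
coefficient in the reference model (the inversion is undefined; `buildPAC()`
refuses to construct such a clock).

**Horizon.** We default to $k = 10$ years — the horizon used by the
established mortality-trained clock lineage (the PhenoAge-style
construction) that this risk-matching transform derives from — and
expose it as a parameter. The proteomic age is only weakly sensitive to $k$ because
both models are evaluated at the same horizon.

**Identity property.** When the full and reference models share
parameters exactly, $A$ equals chronological age to machine precision;
when protein effects are zero but the models are refitted, $A$ deviates
only by fitting noise. At $n = 20{,}000$ with ten null proteins in the
model the mean absolute deviation is of order $0.7$–$1$ year — the scale
expected from coefficient noise ($\sqrt{p}\,\mathrm{se}/\beta_{age}$) —
and shrinks with larger training sets.

## Validation analyses

*Associations.* The acceleration score is associated with mortality by
Cox regression and with incident diseases by Fine–Gray subdistribution
hazards, the appropriate estimand when death competes with disease onset.
Fine–Gray estimation uses the Geskus weighted risk-set expansion
(`survival::finegray`) followed by a weighted Cox fit; with zero
competing events this reduces *exactly* to the Cox model, a property the
tests assert to $10^{-6}$, and against simulations from a proportional
subdistribution-hazards generator it recovers the true coefficient. An
independent implementation (cmprsk) serves as a cross-check.

*Adjustment tiers.* Three nested covariate sets — age only; age +
sociodemographic and lifestyle covariates; those plus pre-existing
disease indicators (the modelled outcome's own indicator dropped) —
mirror standard epidemiological practice. Participants prevalent for a
disease at baseline are excluded from that disease's models. P-values are
BH-FDR adjusted pooled across all outcomes and tiers of one suite run;
the pooling follows the convention of correcting the full battery
together and is configurable by passing a single tier.

*Concordance.* Harrell's C is computed with explicit pair counting:
comparable pairs have the shorter observed time as an event (tied times
comparable only when exactly one member is an event), risk ties count
one half. For disease outcomes the concordance screen treats competing
deaths as censoring — the standard simplification, since the
subdistribution concordance is computationally heavy and yields similar
rankings. Model comparisons fit one Cox model per candidate score on the
same complete-case rows so the C-statistics are directly comparable.

*Standardization.* For cross-measure comparisons each biological-age
measure is rank-based inverse-normal transformed (`inverseNormal()`,
Blom offset $3/8$, average ranks for ties; the offset is the common
default where the transform is named without one). Measures whose raw
direction is protective (telomere length) are sign-reversed first.
Age-adjusted correlation panels residualize each measure on chronological
age before correlating.

## Functional analysis

Per-protein linear models regress the acceleration score on each
inverse-normal-transformed protein plus covariates; the protein
coefficient's exact OLS t-test is computed via the Frisch–Waugh
projection (algebraically identical to the full regression, one QR of
the covariate block for all proteins). Bonferroni correction over the
protein count defines the significant set, which is mapped (possibly
many-to-many) to gene symbols and tested per gene set by the upper-tail
hypergeometric distribution against a background universe — default
20,260 protein-coding genes, configurable. Sets overlapping the input in
fewer than five genes are excluded regardless of p-value; the Bonferroni
multiplier is the full collection size (50 for a hallmark-style
collection), matching the convention of correcting per collection.

## The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the analysis
assumes, with every generating parameter recorded as ground truth:

* **Ages** Uniform(39, 70) — a middle-aged/older recruitment window.
* **Proteins**: linear age trends plus Gaussian noise,
  $x_j = s_j(\mathrm{age} - 54.5) + \varepsilon$, $\varepsilon \sim
  N(0, 1)$; slopes drawn once per cohort from $N(0, 0.02)$ per year,
  giving protein–age correlations up to $|r| \approx 0.4$ — the range
  seen for strongly age-tracking plasma proteins. Centering at the
  mid-age keeps the Gompertz log-rate interpretable.
* **Mortality**: Gompertz hazard with shape $0.09$/yr (mortality
  doubling time ≈ 8 years), age effect $0.08$ log-hazard per year, and a
  sparse causal protein subset (default log hazard ratio $0.3$ per
  expression unit). The baseline log-rate is calibrated by root-finding
  so marginal cumulative mortality over follow-up equals $10.9\%$.
  Death times are drawn by inverse-CDF sampling of the closed-form
  cumulative hazard.
* **Follow-up**: administrative censoring at 13.3 years. Real cohort
  censoring is registry-date-driven and not reconstructible; a single
  administrative horizon is the honest stand-in.
* **Diseases**: cause-specific exponential hazards (with age and
  optional protein effects) competing with death; status records
  event / death-first / censored and times respect the competing-risks
  ordering by construction.
* **Missingness**: MCAR at 2% of cells by default, plus a mechanism that
  concentrates dropout in designated proteins to exercise the
  high-missingness filter (panels in practice carry a few proteins with
  60–99% dropout, which motivates the 0.5 removal threshold).
* **Reproducibility**: one integer seed per cohort; per-component
  sub-streams are derived from it by a fixed affine map, so adding a
  component never reshuffles the others.

What the generator does *not* emulate: assay plate/batch structure,
consortium-enriched sampling, non-linear protein–age trajectories,
protein–protein correlation beyond the shared age trend, informative
dropout, and registry-driven censoring. Passing the recovery and
calibration tests therefore demonstrates correctness of the estimators
under the model's assumptions — not robustness to these real-data
features, which should be assessed on the target cohort.

## Preprocessing choices

* **Missingness filter**: proteins with missing fraction strictly above
  0.5 are removed before imputation. The threshold reproduces the
  removal of extreme-dropout proteins (63–99% missing) while keeping
  ordinarily-missing ones.
* **k-NN imputation** (`knnImpute()`, default $k = 10$): missing cells
  are replaced by the inverse-distance-weighted mean of the $k$ nearest
  participants observing that protein, with distance the root mean
  squared difference over co-observed proteins — the per-shared-dimension
  scaling keeps participants with different missingness patterns
  comparable. Zero-distance neighbours take over with equal weight;
  fewer than $k$ usable neighbours falls back to all available with a
  warning. Observed cells are never altered, and convex weights bound
  imputed values by each protein's observed range.
* **Degenerate inputs**: constant vectors are rejected by
  `inverseNormal()` (no rank information) and by the correlation panel;
  all-identical rows score identically by construction.

## Problem sizes in the tests

The shipped suite exercises parameter recovery at the sizes where the
asymptotics are informative but a laptop run stays comfortable: Gompertz
recovery over 50 replicates of $n = 20{,}000$; penalized-Cox support
recovery over 20 seeds at $n = 2{,}000$, $p = 100$; Fine–Gray recovery
at $n = 10{,}000$; brute-force oracle comparisons for concordance, BH and
the hypergeometric tail at $n \le 200$, $N \le 30$, and 1,000 random
p-vectors; and bit-reproducibility of the full pipeline on a
$500 \times 50$ cohort. The full suite runs in a few minutes.

## Known limitations

* The Fine–Gray Wald intervals use the model-based variance of the
  weighted Cox fit, not the IPCW-robust sandwich; for large cohorts the
  difference is small, but confidence intervals for heavily weighted
  data are approximate.
* `knnImpute()` materializes an $n \times n$ distance matrix; cohorts
  beyond a few tens of thousands of participants need chunked or
  approximate neighbour search.
* The clock assumes a positive age gradient of mortality in the
  reference model; cohorts where that fails (e.g. very narrow age
  ranges) cannot support the age-scale inversion and are rejected
  rather than extrapolated.
* Harrell's C for disease outcomes censors competing deaths; it is a
  ranking screen, not a subdistribution concordance.
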