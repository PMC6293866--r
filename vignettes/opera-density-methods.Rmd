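---
title: "Methods: multi-threshold density, OPERA, and matched-set model comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-threshold density, OPERA, and matched-set model comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operamd)
```

## The statistical problem

A nested case-control study matches each incident breast cancer case to M
disease-free controls on design variables (here, birth-year stratum).
Mammographic density is measured on the pre-diagnosis film at three
brightness thresholds — conventional, higher, highest — on two scales
(absolute dense area in cm², percent of breast area). The three measures
are nested superlevel sets of the same image and correlate strongly, so
the scientific question is comparative: which measure best discriminates
risk, separately for interval and screen-detected cancers, and do the two
outcomes need different models?

`operamd` treats that question as four composable stages: measurement,
standardization, matched-set regression, and model comparison; plus a
synthetic-cohort generator whose mechanism is exactly the model being
fitted, so every estimator can be validated by parameter recovery.

## Dual-threshold measurement

A `gray_image` is an integer intensity matrix (12-bit by default,
0–4095) with a physical pixel spacing (cm per pixel side; default 0.01 cm —
film digitizer resolutions vary and the value only scales areas, so it is a
configurable parameter rather than a modelling assumption). A
`threshold_pair` holds the two operator-chosen grey levels: the background
threshold separates breast from background; the density threshold marks
dense tissue. Both are applied *inclusively* (pixel counted when intensity
≥ threshold); the convention of the original interactive software is not
documented, so we fixed one and state it. The breast mask is the full
superlevel set with no connected-component filtering: the package's
phantoms control geometry exactly, and real-image artefact exclusion is a
pre-processing concern outside the measurement model. An image in which no
pixel reaches the background threshold is an error, never a silent 0%.

`measure_nested()` applies an ascending ladder of density thresholds over
one background threshold; dense areas are then weakly decreasing by
construction, which is the defining property of the three-measure family.

## Standardization to the adjusted SD scale

Each raw measure `y` is transformed by Box–Cox,
`(y^λ − 1)/λ` (log at λ = 0), with λ estimated by maximizing the profile
log-likelihood (normal likelihood of the transformed values plus the
`(λ − 1) Σ log y` Jacobian) over λ ∈ [−3, 3] by bounded scalar
optimization; the test suite checks the optimizer against an independent
0.001-step grid search and against `MASS::boxcox`. Zeros (possible for
percent density at the highest threshold) are handled by an additive shift
of half the smallest positive value, applied before transforming and
recorded in the report.

The transformed measure is then regressed on age (years) and BMI (kg/m²)
by OLS **among controls only**, both covariates entering linearly (the
functional form is not prescribed by the design; linear is the default and
the adjustment covariates are arguments). Residuals for *all* subjects use
the control-fitted coefficients — adjusting cases with their own
coefficients would leak case status into the scale. The residuals are
divided by the control residual SD (n − 1 denominator), the *adjusted SD*.
Two consequences define the scale: the control subset of the output has SD
exactly 1, and the adjusted SD never exceeds the unadjusted SD (an OLS
identity, enforced as an invariant). λ is likewise estimated on controls
only; estimating it on all subjects would let case enrichment tilt the
transformation. `standardize_cohort()` applies this per outcome mode by
default, since each outcome's analysis uses its own controls.

When several observers measure the same images, `average_measurers()`
averages their standardized values per subject and re-reports the control
SD of the average, which falls below 1 for imperfectly correlated
observers — for k equicorrelated unit-variance observers at pairwise r the
SD is √((1 + (k−1) r)/k).

## Conditional logistic regression

For sets with exactly one case, the conditional likelihood is
`L(β) = Π_sets exp(η_case) / Σ_members exp(η)`, `η = xβ`. The engine uses
Newton–Raphson with the analytic score and observed information,
log-sum-exp stabilization of the within-set denominators, step-halving (up
to 10 halvings) whenever a step would decrease the likelihood, and declares
convergence when the largest score component is below 1e-8 (at most 50
iterations). Standard errors come from the inverse observed information;
95% limits are β ± 1.959964·SE. Any |β| > 10 on the standardized scale
with a non-vanishing gradient is flagged as separation rather than
reported. Missing covariates drop the subject, and the whole set when the
case is dropped, with both counts reported. Only 1:M sets are supported;
sets violating the one-case rule are an error rather than silently
generalized. The implementation is validated three ways: against a direct
enumeration of the likelihood, against a 1e-4 grid search on small
problems, and against `survival::clogit` (coefficients, SEs and
log-likelihood agree to at least 1e-6 in the tests).

The likelihood-ratio test uses `2ΔLL ~ χ²` with df equal to the term-count
difference, for nested fits on identical sets. Unconditional logistic
regression (for contrasts between independent case subgroups, e.g.
interval vs screen-detected) is delegated to `stats::glm`, with the same
convergence/separation contract.

## OPERA and the comparison toolkit

- **OPERA** = exp(β̂) when the covariate is standardized to unit adjusted
  SD; CI endpoints exponentiate the Wald limits.
- **Bivariable rescaling**: when two standardized measures with
  correlation r are fitted jointly, each log OR is multiplied by
  √(1 − r²) before exponentiating, expressing it per residual SD given the
  other measure. For the trivariable model the natural generalization is
  used: each term's multiplier is √(1 − R²) with R the measure's multiple
  correlation with the other two among controls.
- **IQQR** ≈ OPERA^2.5, the top-vs-bottom-quartile risk ratio implied by a
  normally distributed standardized exposure. It is strictly increasing and
  satisfies IQQR(1/x) = 1/IQQR(x).
- **ΔBIC**: for equal parameter counts, ΔBIC = −2ΔLL (model A better when
  negative); otherwise the `(k_a − k_b) log n` complexity term is added.
  Posterior odds in favour of A are reported as exp(−ΔBIC) — the
  convention under which ΔBIC = −6 is ~400:1 and −14 is ~10⁶:1, which is
  internally consistent and is the package default — with
  `convention = "halved"` exposing the textbook exp(−ΔBIC/2). Verbal
  strength bands on |ΔBIC|: < 2 none, 2–6 positive, 6–10 strong, ≥ 10 very
  strong.
- **AUC** is the pooled Mann–Whitney statistic of the standardized measure
  with a DeLong CI (via pROC). A matched-pair AUC variant would condition
  on sets; pooled was chosen because the standardized measure is already
  design-adjusted, and the choice is stated rather than hidden.
- **Quartile ORs** cut the cohort at the control 25/50/75 percentiles of
  the measure residualized on age, BMI and (configurable) live births, and
  fit the three upper-quartile indicators by conditional logistic
  regression.
- **ICC**: one-way random-effects ANOVA estimator
  `(MSB − MSW) / (MSB + (k̄ − 1) MSW)` with an F-distribution CI, for the
  repeat-measurement design (≈10% of images re-measured within batches).

## The synthetic cohort: what it emulates, and what it does not

The generator's defaults are the study conditions the package is
calibrated to: 168 interval and 422 screen-detected matched sets at 1 case
: 3 controls; age N(56.2, 6.8²) years for interval sets and N(58.4, 7.6²)
for screen sets; BMI N(26.5, 4.9²) kg/m² truncated at 15; live births
Poisson(2.7) truncated to 0–8; positive family history at 15% (descriptive
only — it carries no risk in the generator, by design). The 6×6 latent
correlation matrix of the transformed standardized measures has 0.86
(conventional–higher, dense area), 0.88 (same, percent), 0.82 for all
pairs involving the highest threshold and for cross pairs, and 0.87 / 0.92
/ 0.96 between the two scales at each threshold; it is checked to be
positive definite. Raw-scale marginal moments mirror typical control
values (e.g. conventional dense area mean 19, SD 11 cm²; highest-threshold
percent density mean 3, SD 3.5) with a log-normal shape
(`boxcox_lambda_true = 0`).

Three design choices deserve comment:

1. **Exact mechanism.** Within each set of M + 1 candidates sharing the
   matching variable, the case is a single multinomial draw with
   probability exp(η)/Σexp(η), η built from the latent standardized
   measures (plus, in screen-detected sets, a centered
   (BMI − mean)(age − mean) interaction term, default 0.004 per unit —
   small and positive, matching an association that strengthens with age).
   This *is* the conditional-logistic likelihood, so fitting recovers the
   generating β without approximation error; recovery to within
   Monte-Carlo error is an acceptance-grade test, not a hope.
2. **Nesting by margin separation, not fractionation.** Each of the six
   raw measures is a monotone Box–Cox back-transform of its own latent
   trait. This preserves the latent correlation structure exactly on the
   analysis (transformed) scale — which is the scale on which the target
   correlations are defined — at the cost that the raw dense areas are
   only *almost surely* ordered: the configured margins separate the
   thresholds by ≥ 2.3 within-difference SDs, and the ~1–3% of draws that
   would violate nesting are restored by an order-preserving clamp whose
   count is reported. The alternative (generating lower-threshold measures
   as Beta-distributed fractions of the conventional one) guarantees
   nesting algebraically but cannot hold the transformed-scale correlation
   at a prescribed value, which is the quantity the calibration tests
   check.
3. **Confounding that the pipeline must remove.** Age and BMI enter the
   transformed measures linearly (defaults −0.02 per year and −0.02 /
   −0.08 per kg/m² for dense area / percent), then the trait is rescaled
   to unit SD before back-transforming so the raw moments still match.
   Standardization must therefore actually work for recovery tests to
   pass.

What the generator does **not** emulate: screening attendance and masking
mechanisms, tumour growth, family history as a risk factor, the study's
ragged matching ratio (the screen stratum is fixed at 1:3; the fitting
engine itself accepts variable M), country-of-origin matching, menopause
and the other descriptive covariates, and measurement error beyond the
repeat-pair model `y = t + e`. Passing calibration tests on this cohort
shows the estimators are correct under the stated mechanism; it does not
show the mechanism captures real mammograms.

## Numerical notes and known limitations

- Back-transforming a standard-normal trait to a raw mean/SD is exact for
  λ = 0 (log-normal moment matching) and λ = 1 (affine), first-order
  (delta method) otherwise; non-positive Box–Cox bases are clamped at a
  configurable positive floor with a logged count.
- Pearson correlations of *estimated*-λ transformed measures are very
  mildly attenuated relative to the latent values (any monotone
  nonlinearity attenuates a Gaussian-copula correlation); with ~1700
  subjects the effect is under 0.01 and well inside the calibration
  tolerances.
- The λ search interval [−3, 3] and the 1e-8 score tolerance are
  defaults, not guarantees, for pathological data; both are arguments.
- Problem sizes in the shipped tests and acceptance script were chosen for
  Monte-Carlo precision: 200 replicates put the SE of a mean recovered
  OPERA near 0.02 at study sizes; 100 replicates of 180 repeat pairs put
  the SE of the mean ICC near 0.0005; coverage and type-I checks use
  500–1000 replicates at reduced set counts.
- Reported LRT and ΔBIC arithmetic assumes the compared fits used the same
  sets; the functions check set and subject counts, not row identity.
- Exact conditional inference for sparse data, robust variances, m:n
  conditional likelihoods, calibration statistics and absolute-risk
  projection are out of scope.
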