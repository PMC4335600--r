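---
title: "Methods: absolute stroke risk, add-on deltas, and the validation battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: absolute stroke risk, add-on deltas, and the validation battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskometer)
```

## The model

Absolute stroke risk over a horizon $t \in \{5, 10\}$ years follows the
Cox baseline-survival form

$$\mathrm{risk}(t) = 1 - S_0(t)^{\exp(\beta' x - \beta' \bar{x})},$$

with sex-specific coefficients $\beta$, covariate means $\bar x$ and
baseline survival $S_0(t)$ supplied as configuration data
(`coefficient_set()`), never re-estimated by this package. A configuration
with all means zero reproduces the uncentered form. When only $S_0(10)$ is
configured, $S_0(5) = S_0(10)^{1/2}$ is derived — exact if the baseline
hazard is constant over the decade, and a mild approximation otherwise; an
explicitly configured $S_0(5)$ always wins.

The Riskometer score adds terms for factors outside the classic equation.
The published constants mix magnitudes, and the package interprets them by
scale — the interpretation lives in `delta_config()` as data, so alternates
are selectable without touching code:

* values in $(0, 1)$ (0.20 non-Caucasian, 0.20 poor diet, 0.10 high
  alcohol, 0.10 low physical activity, 0.05 family history) are additions
  to the log-hazard linear predictor;
* values $\ge 1$ (1.80 cognitive problems, 1.40 memory problems without
  cognitive problems, 1.20 previous head injury, 1.02 per-cm waist) are
  hazard-ratio multipliers, entering as $\ln(\cdot)$ additions to the
  linear predictor;
* the previous stroke/TIA values 10 and 15 are incompatible with the log
  scale (they would multiply the hazard by $e^{10}$) and are treated as
  absolute percentage-point additions to the final risk, capped at 100.

Anthropometry enters through a fallback chain — waist-to-hip ratio if
measured, else BMI, else waist circumference — with only the first
available measurement contributing. Two documented ambiguities:

* the BMI rule is stated in two places with and without a base term of
  1.02; the variable-definition table (the operational definition of the
  app's inputs) has no base term, so the default is 0.10 per kg/m² above
  the ethnic threshold, with `bmi_rule$include_base_rr = TRUE` adding
  $\ln 1.02$;
* *stress* is listed as a variable but carries no published coefficient
  anywhere; its delta defaults to 0 and is configurable.

The *baseline comparison risk* — "someone of your age and sex with no risk
factors" — is the score of a profile with every flag off, never-smoker,
and SBP at a reference value. No reference SBP is published; the package
uses 120 mmHg (the conventional boundary of normal blood pressure),
configurable via `delta_config(reference_sbp = )`.

### Shipped base coefficients are a stand-in

The add-on constants above are published; the base-equation coefficients
are not printed in the source material available to this package. The
shipped default (`extdata/fsrs_coefficients_synthetic.json`) is therefore a
*synthetic stand-in* with Framingham-like magnitudes, labelled as such in
its filename and provenance string. It produces plausible risks (a
65-year-old male smoker with diabetes lands near 10% at 5 years) and
exercises every code path; it is not suitable for clinical use. Every
exactness property of the add-on layer (the delta table, the
percentage-point addition, the fallback chain) is independent of the base
coefficients, and all exact-value tests use toy coefficient sets.

## Validation statistics

All pair-based statistics give ties 0.5 credit.

**AUROC** uses the Mann–Whitney pair estimator, which equals the
trapezoidal area of the ROC curve (asserted to $10^{-12}$ in the tests).
**DeLong** variance comes from the placement-value structural components,
computed via midranks; confidence intervals are normal-approximation,
truncated to $[0,1]$ (a logit-scale interval is available). The paired test
uses the paired DeLong covariance and reports a two-sided normal p-value;
identical or order-equivalent score vectors short-circuit to $z = 0$,
$p = 1$.

**Harrell's C** treats a pair as comparable when one subject had an event
strictly before the other's observed time; pairs tied on time with two
events are excluded by default (`tied_times = "half"` includes them at
half credit). Somers' D is reported as exactly $2C - 1$. **Pseudo-R²** is
Nagelkerke's rescaling of Cox–Snell computed from the Bernoulli
log-likelihood of the *fixed* predicted risks against the outcomes — no
logistic model is refitted, because the package validates externally
derived algorithms (risks are clipped at $10^{-12}$ for the likelihood).

**Hosmer–Lemeshow** groups subjects by quantiles of predicted risk (ties
to the lower group, so groups can be unequal under heavy ties), takes
expected counts from summed predictions, and sums
$(O-E)^2/E + (O'-E')^2/E'$. The reference distribution is
$\chi^2(g)$ by default: the familiar $g-2$ degrees of freedom are correct
when the model was fitted to the same data, but for a fixed external
algorithm nothing is estimated, the group terms are asymptotically
independent $\chi^2(1)$ variables, and simulation confirms the choice —
drawing outcomes from the predictions themselves at $n = 2000$, the
$\chi^2(g)$ reference holds the 5% level (rejection ≈ 0.05, p-values
uniform), while $g-2$ rejects ≈ 10% of the time. `fitted = TRUE` restores
the development-data convention. This is the one place the package
deviates from its original design sketch, because the recovery experiment
proved the sketch wrong.

**Classification**: a subject is high-risk when its predicted risk is
$\ge$ the threshold (the boundary counts as high; the source tables do not
state the rule, so it is documented here once).
`threshold_for_accuracy()` scans every distinct score and returns the
*lowest* cut-point whose accuracy meets the target — the most sensitive
classification subject to the accuracy constraint, matching the
monotone-threshold structure of the published tables; a "closest accuracy"
mode is available. `default_high_risk_thresholds()` ships the published
high/low cut-points (e.g. base model, male, 5-year: 13.0%) as descriptive
defaults.

## The synthetic cohort generator

The generator emulates the *marginals* of the three published validation
cohorts:

* `russia-like` — n = 1378, ages ≈ 50 (SD 6), SBP 131–136 mmHg, BMI
  ≈ 27.5–27.8, diabetes 4.6%, 3.2% event rate at 5 years;
* `rotterdam-like` — n = 7713, elderly (69–72), SBP ≈ 139–140, BMI
  25.6–26.7, diabetes 6.6%, 8.4% event rate, 10-year horizon;
* `arcos-like` — n = 410, a stroke-register style case-only cohort
  (every row an event within one year), high SBP (≈ 157), WHR 0.9 (0.1),
  waist 97–99 cm, diabetes 20%.

Continuous factors are truncated normals (age 20–100, SBP 70–260 mmHg,
BMI 14–60 kg/m², WHR 0.5–1.4, waist 50–180 cm — physiologic plausibility
bounds; drawn by inverse CDF so one uniform is consumed per value and the
stream is reproducible). Binary factors are independent Bernoullis. Only
the continuous means/SDs, diabetes prevalence and event rates are
published for these cohorts; the remaining prevalences are neutral,
field-plausible defaults chosen once (e.g. antihypertensive treatment 15%
in the middle-aged cohort vs 30% in the elderly one, prior stroke/TIA 1%
vs 3%) and overridable per spec. Memory problems are sampled only among
subjects without cognitive problems, because the memory flag is defined as
memory trouble *without* cognitive impairment.

Outcomes come from one of two mechanisms: **model mode** draws an
exponential event time with rate $\lambda_i = -\ln(1 - r_i)/h$, so that
$P(T_i \le h)$ equals the subject's predicted risk $r_i$ by construction
(risk 100% is capped at $\lambda = -\ln 10^{-12}/h$); **null mode** uses a
constant rate regardless of the profile. Uniform censoring on $(0, h]$ can
be applied to a configurable fraction; everyone else is administratively
censored at the horizon.

What a green test does and does not establish: the generator reproduces
published *marginals* and gives calibration-faithful or null outcomes, so
it can validate the statistical machinery (discrimination recovery,
calibration recovery, type-I error). It models no correlation between risk
factors (the sources publish none), no secular trends, no measurement
error, and no competing mortality — so green tests say nothing about how
the score performs on real cohorts.

## Numerical choices

* Risks outside $[0, 1]$ after the survival transform (possible with
  extreme linear predictors) are clipped with a warning.
* End-to-end scores match an independent closed-form recomputation to
  $10^{-12}$ relative tolerance in the tests.
* JSON reports render numbers at 12 significant digits, making the
  simulate → score → validate pipeline byte-identical across reruns with
  the same seed.
* The CSV dialect encodes booleans as 0/1 and missing optionals as empty
  fields; an optional `drinks_per_day` column is converted to the
  `high_alcohol` flag with the ≥ 2 drinks/day convention (the stricter of
  the two published wordings), with a logged message.

## Known limitations

* The shipped base coefficients are a labelled stand-in (above); absolute
  risk levels under the default configuration are illustrative only.
* Comparator equations (e.g. UK-style ischaemic-stroke scores) are
  supported as user-supplied configuration, not reproduced.
* No time-dependent ROC, competing risks, or net-reclassification
  statistics.
* The Hosmer–Lemeshow grouping under heavily tied predictions can produce
  fewer than `g` groups; degrees of freedom follow the effective group
  count.
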