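---
title: "Methods: attributable-fraction estimation and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attributable-fraction estimation and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pafburden)
```

## The estimand and the model

The population attributable fraction (PAF) of a risk factor for a cancer type
is the share of incident cases that would not have occurred had the
population's exposure been at the reference level, under a causal
relative-risk model. With the population split over exposure levels
$i = 1 \dots n$, a proportion $p_i$ at level $i$ and an excess relative risk
$\mathrm{ERR}_i = \mathrm{RR}_i - 1$, `paf_levin()` evaluates

$$\mathrm{PAF} \;=\; \frac{\sum_i p_i\,\mathrm{ERR}_i}
                         {1 + \sum_i p_i\,\mathrm{ERR}_i}.$$

Writing $E[\mathrm{RR}] = \sum_i p_i \mathrm{RR}_i$ over all levels including
the reference (RR 1), the numerator is $E[\mathrm{RR}] - 1$, so the formula
is algebraically identical to $1 - 1/E[\mathrm{RR}]$ — the exact excess-case
fraction of a stratified population whose strata carry multiplicative risks.
This identity is what makes the estimator testable against enumeration and
simulation oracles, and the test suite asserts it to $10^{-12}$ over random
configurations.

The model's assumptions are those of every comparative risk assessment built
on this formula: the RRs are causal and transportable to the target
population, exposure acts multiplicatively on baseline risk, and prevalence
measured one latency period before the incidence year describes the relevant
exposure history.

## From published relative risks to ERRs

`err_from_rr()` supports two framings:

* **harmful** — the RR compares the exposed to the reference group;
  $\mathrm{ERR} = \mathrm{RR} - 1$ directly.
* **reduction** — the published RR describes a *lower*-risk contrast (for
  example, physically active versus inactive). The harmful-direction ERR is
  taken as $\ln(1/\mathrm{RR})$, and when the RR spans several exposure units
  it is divided by the number of units to give a per-unit ERR.

The literal $\ln(1/\mathrm{RR})/n$ transform is implemented as the default
because it is the stated convention of the comparative-risk literature this
package follows. It agrees with $1/\mathrm{RR} - 1$ only to first order in
$\mathrm{RR}-1$ (the suite asserts $|\ln(1/\mathrm{RR}) - (1/\mathrm{RR}-1)|
\le (\mathrm{RR}-1)^2$ on $[0.9, 1.1]$), and the per-unit division could
equally well be applied in RR space. Because the choice is genuinely open,
`reduction_transform = "power"` exposes the exact alternative
$(1/\mathrm{RR})^{1/n} - 1$, so a sensitivity analysis can quantify the
difference instead of burying it.

Associations marked `significant = FALSE` are forced to RR 1 — a zero ERR —
whatever the published point estimate. This is a deliberate statement of
"class I carcinogen, but not statistically supported for this site", and the
pipeline logs every forced cell. A *missing* RR row for a linked cell is, by
contrast, a hard data-gap error: silent defaults and deliberate nulls must
never be confusable.

## Combining factors and negative fractions

Factors acting on the same cancer type are combined as
$1 - \prod_f (1 - \mathrm{PAF}_f)$. This closed form is exactly the
"sequential" procedure of applying each factor's fraction only to cases not
attributed by earlier factors, with the attractive property that the result
does not depend on the ordering; since no ordering is part of the estimand,
the order-free product is the only defensible reading, and permutation
invariance is asserted in the tests. It is also the analytically correct
joint PAF when factors are independent and multiplicative — the regime the
microsimulator constructs.

Net-protective inputs (a prevalence-weighted ERR sum below zero) are rejected
by default: the burden estimate considers only the harmful direction of each
factor, and a negative PAF almost always signals a framing mistake in the
input tables. For methodological work `allow_negative_paf = TRUE` returns the
signed value from the engine; the burden pipeline still floors the reported
cell at zero so that attribution tables keep their `[0, 1]` contract. (The
engine returning the signed value, rather than clamping, is the package's
resolution of an ambiguity between "clamp" and "signed" conventions; the
signed value is the informative one, and clamping is a reporting concern.)

## Pipeline structure and conventions

`paf_burden()` is a classic fitting function returning a classed object with
`print`, `summary`, `coef` and `plot` methods — the shape R users expect of
an estimator — rather than a bundle of scripts. Its conventions:

* **Latency is metadata, not modelling.** A factor's exposure vintage plus
  its stated latency must equal the run's incidence year; a 20-year
  sensitivity analysis is expressed by binding a 20-year-old exposure table,
  not by modelling dose histories. Mismatches are configuration errors, not
  warnings.
* **Incidence filter.** Diagnoses with annual incidence strictly below 10 are
  excluded before attribution. "Population incidence" is read as the
  diagnosis's total across sexes (the per-sex reading is available via
  `filter_per_sex = TRUE`; which one the published study used is not
  stated, so the population-level reading is the default and the choice is
  configurable).
* **Subtype rollup.** When risk estimates target a histologic or site
  subtype, attributable cases are computed against the subtype's incidence
  and then rolled up into the parent diagnosis, re-expressed as a fraction of
  the parent's cases, so that combination and denominators never double-count.
* **Rounding is presentation-only.** All internal arithmetic is unrounded;
  reports round case counts to integers and percentages to one decimal with
  ties away from zero (`round_half_away()`), matching the reporting style of
  national burden studies. Re-aggregating from a written full-precision
  attribution table reproduces every internal percentage.
* **Determinism.** A run is a pure function of its inputs; report files are
  byte-identical across repeated runs, which the tests assert.

Sex is encoded as the literals `"male"`/`"female"`, and a factor applying to
one sex simply has no rows for the other. The denominator of overall and
per-factor shares is the total of *kept, top-level* incidence rows for the
run year.

## The microsimulation oracle

`simulate_population()` exists so that every pipeline stage can be validated
against known truth without any external data. It draws, per sex, a cohort of
`n_individuals` people; assigns each an exposure level per factor,
independently across factors and individuals; and gives each person, for each
cancer type, an independent Bernoulli outcome with probability
$\text{baseline} \times \prod_f \mathrm{RR}_f(\text{level})$. Probabilities
are capped at 1 and the run aborts if more than 0.1% of draws hit the cap,
since a saturated risk breaks the multiplicative interpretation.

The emitted tables are exactly the pipeline's input schemas: the exposure
table carries the cohort's *empirical* prevalences (so the pipeline estimate
and the simulated outcome refer to the same population), the RR table the
true configured risks, and the incidence table the simulated counts. Ground
truth comes in two forms per factor × cancer × sex (plus joint-removal
`"combined"` rows):

* **analytic** — $1 - 1/\prod_f E[\mathrm{RR}_f]$ from the configured
  parameters;
* **empirical** — a coupled-counterfactual measurement: the same uniform draw
  decides each person's outcome under factual and counterfactual
  (factor-at-reference) risk, so the excess-case count is measured on the
  very cohort that produced the incidence table. Its Monte-Carlo standard
  error is approximated binomially on the realized case count, with a floor
  that keeps it positive at small counts.

`recovery_experiment()` runs the full pipeline on the emitted tables and
reports, per cell, the pipeline PAF against both truths. The acceptance test
requires every single-factor and combined pipeline PAF to lie within 3
Monte-Carlo standard errors of the empirical truth on the default fixture.

What the simulator deliberately does **not** emulate: dependent or
synergistic exposures (the estimator assumes their absence, so generating
them would test a different estimand), survival or competing risks, age
structure, and exposure measurement error such as the self-reporting bias of
real surveys. Passing recovery therefore shows the estimator is correct
*under its own assumptions*; it says nothing about confounded RRs or biased
prevalence inputs in real applications.

### The default fixture

The default configuration (`default_sim_config()`) crosses three factors with
four cancer types per sex: a tobacco-like exposure (20% current / 25% former,
RRs up to 8 for the lung-like cancer), an alcohol-like exposure (30%/10%, RRs
1–2.5) and an adiposity-like exposure (30%/15%, RRs 1–2.4), over baseline
annual risks of 6×10⁻⁴ to 3×10⁻³. These magnitudes are chosen once to mirror
the prevalences, risk ratios and registry case counts typical of the
lifestyle exposures the estimator targets, including null cells (RR exactly
1) to exercise exact-zero behaviour. Cohorts are 10⁶ individuals per sex
(`n_individuals` is per-sex because the estimator is fully sex-stratified),
seed 20180101; per-cell case counts are then in the hundreds to thousands,
giving Monte-Carlo standard errors of roughly 0.005–0.05 on the PAF scale.
Unit and property tests use cohorts of 10³–5×10⁴ where only structure or
coarse convergence is at stake; the full fixture is reserved for the
acceptance checks.

## Numerical choices

* Closed-form comparisons are asserted at absolute 10⁻¹²; Monte-Carlo
  comparisons at 3 standard errors.
* Interchange CSVs are written with 17 significant digits, so
  write-then-read is the identity on doubles; `write.csv`'s 15-digit default
  would not be.
* Exposure proportions may leave the reference level implicit; it is
  materialized as $1 - \sum p_i$ under the reserved level id `"ref"`. Sums
  are validated with a 10⁻⁹ slack to absorb floating-point accumulation in
  empirical prevalences.
* Degenerate inputs fail loudly with classed conditions
  (`paf_input_error`, `paf_validation_error`, `paf_config_error`,
  `paf_data_gap_error`, `paf_domain_error`), each naming the file, row,
  column, factor or cell concerned; no partially validated table ever
  escapes a reader.
* `combine_pafs()` short-circuits single-factor and all-null inputs so the
  trivial identities hold exactly in floating point, not just to rounding.

## Known limitations

Confidence intervals are intentionally absent: the PAF here composes point
estimates from heterogeneous sources (survey prevalences, meta-analytic RRs,
adopted direct PAFs), and interval arithmetic over those components would
suggest a precision the inputs do not have. Synergy between factors is not
modelled — the combination formula assumes independent multiplicative action
— and a single fixed latency per factor ignores heterogeneous induction
times. All three limitations are inherited from the comparative
risk-assessment methodology itself, not artifacts of this implementation.
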