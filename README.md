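# pafburden

Population attributable fractions (PAFs) of cancer incidence for sets of
avoidable risk factors, in the comparative risk-assessment style used by
national cancer-burden studies.

The question the package answers is the one prevention planners ask: *of the
cancers diagnosed in a population in a given year, how many would not have
occurred had exposure to a risk factor — or to all studied factors — been at
its reference level?* Its users are cancer epidemiologists and public-health
analysts who have (i) registry incidence counts by cancer type, sex and year,
(ii) population exposure prevalences measured one latency period earlier, and
(iii) published relative risks (or, for some exposures, published PAFs to
adopt directly).

## The model

For one risk factor, one cancer type and one sex, with the population split
over exposure levels *i* = 1 … *n* (proportion *p*ᵢ at level *i*, excess
relative risk ERRᵢ = RRᵢ − 1), the attributable fraction is the multi-level
Levin formula

```
PAF = Σᵢ pᵢ·ERRᵢ / (1 + Σᵢ pᵢ·ERRᵢ)
```

which equals the exact excess-case fraction `1 − 1/E[RR]` of a stratified
population with multiplicative risks. Relative risks published in a
protective framing (e.g. active versus inactive) are converted to the
harmful direction as `ERR = ln(1/RR)`, divided by the number of exposure
units the RR spans; associations the evidence review did not support
statistically are forced to RR = 1. Attributable cases are `PAF × cases`.
Several factors acting on the same cancer type are combined without
double-counting by applying each factor only to cases not already attributed:

```
PAF_combined = 1 − Πf (1 − PAF_f)
```

Diagnoses with an annual population incidence below 10 are excluded before
attribution, and each factor's exposure vintage must match the incidence year
through its assumed latency (10 years by default; a 20-year sensitivity run
simply binds an older exposure table).

## Worked example

Two factors — a tobacco-like exposure with relative risks for lung and
laryngeal cancer, and UV radiation entering as published direct PAFs for
melanoma — against a small registry-style incidence table:

```r
library(pafburden)

incidence <- data.frame(
  cancer_type_id = c("lung", "lung", "larynx", "larynx", "melanoma", "melanoma"),
  subtype_of = NA, sex = rep(c("male", "female"), 3), year = 2018,
  cases = c(2450, 2390, 210, 70, 1380, 1520))
exposure <- data.frame(
  factor_id = "smoking", sex = rep(c("male", "female"), each = 2),
  level_id = rep(c("former", "current"), 2),
  proportion = c(0.28, 0.24, 0.22, 0.20), exposure_year = 2008)
rr <- data.frame(
  factor_id = "smoking", cancer_type_id = rep(c("lung", "larynx"), each = 4),
  sex = rep(rep(c("male", "female"), each = 2), 2),
  level_id = rep(c("former", "current"), 4),
  rr = c(4.1, 10.9, 4.1, 10.9, 2.3, 6.1, 2.3, 6.1), significant = TRUE)
direct <- data.frame(
  factor_id = "uv", cancer_type_id = "melanoma",
  sex = c("male", "female"), paf = c(0.932, 0.895))

factors <- list(
  risk_factor_spec("smoking", display_name = "Tobacco smoking",
                   exposure_year = 2008, latency_years = 10),
  risk_factor_spec("uv", evidence_mode = "direct_paf",
                   display_name = "UV radiation",
                   exposure_year = 2008, latency_years = 10))

fit <- paf_burden(incidence, factors, exposure = exposure, rr = rr,
                  direct_paf = direct, incidence_year = 2018)
summary(fit)
```

```
Attributable cancer burden, incidence year 2018
Overall: 6425 of 8020 cases attributable (80.1%)

By risk factor:
          factor attributable male female paf_%
 Tobacco smoking         3779 2002   1777  47.1
    UV radiation         2647 1286   1360  33.0

By cancer type (combined over factors):
   cancer cases attributable paf_%
     lung  4840         3610  74.6
 melanoma  2900         2647  91.3
   larynx   280          169  60.2
```

Reading the output: 74.6% of the 4,840 lung cancers are attributable to the
smoking prevalences and relative risks supplied (current smokers at RR ≈ 11
dominate), the melanoma rows simply carry the published direct fractions
through to case counts, and the overall 80.1% is the combined attributable
share of this three-cancer toy registry — high because every cancer type here
is strongly linked to one of the two factors. `coef(fit)` returns each
factor's share of all incident cases (0.471 and 0.330 here),
`as.data.frame(fit)` the full attribution table, and
`write_burden_report(fit, dir)` deterministic CSV/log report files.

Validation against ground truth is built in: `simulate_population()` draws an
individual-level population with known multiplicative risks and
`recovery_experiment()` checks that the whole pipeline recovers both the
analytic PAF `1 − 1/E[RR]` and the empirically measured excess-case fraction
of the simulated cohort.

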