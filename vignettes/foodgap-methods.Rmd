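---
title: "Methods: caloric and macronutrient gap accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: caloric and macronutrient gap accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodgap)
```

## The accounting model

`foodgap` measures how far a region can feed itself from its own
production, for nine food groups (cereals, tubers, legumes, vegetables,
fruits, meat, eggs, dairy, aquatic products), at three resolutions:
total dietary energy, the three macronutrients, and the individual
foods.

**Production side.** Raw production mass of food $j$ is converted to
dietary energy and nutrient mass:

$$TCP_j = FP_j \times CF_j \times CalF_j, \qquad TCP = \sum_{j=1}^{9} TCP_j$$

where $FP_j$ is raw production (g), $CF_j$ the edible-conversion factor
(the fraction of raw mass that is consumable) and $CalF_j$ the caloric
factor (kcal per g edible mass). Macronutrient production is obtained
per food from its energy proportions $EP_{j,q}$
($q \in \{\text{carbohydrate}, \text{protein}, \text{fat}\}$) and the
Atwater-style energy-conversion coefficients $ECF_q$ (4, 4, 9 kcal/g by
default):

$$MNP_{j,q} = \frac{TCP_j \times EP_{j,q}}{ECF_q}, \qquad
  MNP_q = \sum_j MNP_{j,q}.$$

Two modelling choices deserve a note. First, nutrient production is
computed from the *per-food* calories $TCP_j$, not the grand total:
only then is the account additive over foods, which the per-food gap
resolution requires. Second, the energy share is *divided* by $ECF_q$,
converting nutrient energy to mass, so that nutrient accounts are
denominated in kilotonnes like the published regional tables; with
shares summing to roughly one and coefficients (4, 4, 9), energy and
mass accounts reconcile (the packaged 2020 account reconciles to about
2%, a residual the demand tests document rather than correct).

**Demand side.** Food demand follows the population pyramid and a
dietary structure: for age stage $a$ (nine bands in the style of the
Chinese dietary guidelines by default), per-capita intake $FI_{a,j}$
(g/person/year) gives

$$TCD_j = \sum_{a=1}^{9} Pop_a \times FI_{a,j} \times CalF_j, \qquad
  TCD = \sum_j TCD_j,$$

and macronutrient demand mirrors the production-side conversion,
$MND_{q,j} = TCD_j \times NRGP_{q,j} / ECF_q$, with the nutrient energy
ratios $NRGP_{q,j}$ defaulting to the factor table's $EP_{j,q}$ (the
same food composition governs both sides). Intake tables may be
age-invariant (`"all"` rows), and may distinguish urban and rural
residents; exact (age, residence) rows take precedence over wildcard
rows.

**Dietary structures.** Three consumption structures are first-class:
S0, the mean of the historical per-capita consumption tables supplied
(e.g. a 2019--2021 average); S1, the dietary-guideline *upper*
consumption limits; and S2, the guideline *lower* limits. S1 dominates
S2 elementwise by construction, and therefore so does its demand at
every resolution — a property the test suite checks on generated
cases.

**The gap.** Self-sufficiency is summarised by the signed percentage

$$Gap = \frac{TCD - TCP}{TCP} \times 100\%$$

applied at all three resolutions. $Gap \le 0$ means local production
meets demand (`met`); $Gap > 0$ means dependence on external supply
(`deficit`). Production exactly zero (or at/below a configurable floor,
default 0) with positive demand makes the percentage explode, so such
entries are flagged `undefined` and reported as an absolute shortfall
instead — the near-zero legume production in the packaged 2020 table is
the motivating case.

**Guideline deviations.** Per-capita consumption is compared to
guideline bounds as $(bound - consumption)/denominator \times 100$ for
below-lower deviations (positive = short of the bound), symmetrically
for above-upper. Published deviation percentages mix two denominator
conventions, so the denominator (guideline bound or observed
consumption) is an explicit argument, defaulting to the guideline
bound, and reports must name the convention.

## Future demand under SSP scenarios

Future demand couples provincial cohort projections under the
SSP1-2.6, SSP2-4.5 and SSP5-8.5 scenarios with the dietary structures:

1. **Downscaling.** The regional pyramid is modelled as a constant
   per-stratum share (stratum = age stage × sex × residence) of the
   provincial pyramid, calibrated on overlapping years. The share is
   the *geometric* mean of the yearly regional/provincial count ratios:
   under multiplicative observation noise the arithmetic mean of ratios
   is biased upward by a factor $(1 + cv^2)$, while the geometric mean
   is consistent; when zero counts occur the arithmetic mean is used as
   a fallback. The per-stratum Pearson correlation of the two series is
   reported as a calibration diagnostic. This constant-share model is
   the simplest one consistent with the very high regional/provincial
   structure correlations typical of the application; a trend in the
   share is deliberately not modelled.
2. **Term windows.** Annual projections are averaged per cohort over
   the basic (2011--2030), near (2021--2040) and mid (2041--2060)
   inclusive windows; each window's mean pyramid then feeds the demand
   equations unchanged.
3. **Future gap.** Projected demand is compared against a *frozen*
   baseline-year production account (default 2020): the question asked
   is whether today's production capacity could carry tomorrow's
   demand, not a production forecast.

For age-invariant structures the relative growth of demand between two
terms depends only on the population trajectory, not on the structure —
the projection tests verify this invariance, and the growth summary in
`run_projection()` reports growth relative to the basic term per
structure.

## Tunable parameters

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| `cf` | edible-conversion factor per food | fraction, (0, 1.5] | see `default_factor_table()` |
| `calf` | caloric factor per food | kcal/g | see `default_factor_table()` |
| `ep_*` | macronutrient energy proportions | fraction in [0, 1], sum in [0.9, 1] | see `default_factor_table()` |
| `ecf` | energy-conversion coefficients | kcal/g | 4 / 4 / 9 |
| `floor` | production floor for the undefined-gap rule | canonical units | 0 |
| `denominator` | guideline-deviation convention | — | `"guideline"` |
| windows | basic/near/mid term year ranges | years | 2011--2030 / 2021--2040 / 2041--2060 |
| `baseline_year` | frozen production year for future gaps | year | 2020 |

The default factor table holds coefficients in the style of Chinese
food-composition compilations. They are package defaults for
demonstration and synthetic work — any real regional analysis should
load its own table — and none of the packaged worked-example results
depend on them: every reproduced statistic is computed from the
*aggregated* published tables (`uma_tables()`), in which the coefficient
effects are already baked in.

## The synthetic-data generator

`generator_config()` defines a complete synthetic study system with
known ground truth: a provincial nine-stage pyramid (two sexes, two
residences) growing exponentially at a configurable rate, a regional
pyramid that is a fixed share of the noise-free provincial trend, a
nine-food production series with per-food exponential trends, and an
S0/S1/S2 intake triple with S1 ≥ S2 by construction and S0 spanning
both deficit and surplus deviations. Observation noise is
multiplicative log-normal with mean 1 and configurable coefficient of
variation — the simplest positive-support noise model, keeping counts
and masses non-negative.

Defaults emulate an oasis metropolitan area inside an arid-region
province: ~25 million provincial residents across nine age bands,
regional share 0.4, 1% yearly cohort growth, production levels of the
order of the region's published 2000s accounts (with a legume-style
decay to below 2% of the initial level over two decades, exercising the
undefined-gap path, and a fruit-style boom), urban share 0.56, and
noise cv 0.02. Each generator draws from its own stream, seeded by a
stable hash of the generator name mixed with the master seed, so adding
a generator never perturbs the draws of another and identical
seed/config give byte-identical output.

What the generator does *not* emulate: census undercount and cohort
survival (cohorts grow independently at a common rate rather than aging
through the pyramid), migration shocks, policy-driven discontinuities
in production series, and correlated errors between foods or strata.
Passing recovery tests therefore demonstrates the correctness of the
accounting and calibration arithmetic under the stated noise model, not
robustness to real yearbook data pathologies.

## Numerical choices

- All computation is in canonical units (g, kcal); `convert_units()`
  handles kt and B kcal for reporting, and round-trips are exact to
  relative 1e-12. Display rounding (two decimals for table quantities,
  one for percentages, integers where customary) happens only in print
  methods; machine-readable outputs keep full precision.
- Equality of partitioned totals (plant + animal = total; nutrient sums)
  is asserted to relative 1e-9; pure arithmetic identities to 1e-12.
- Pyramid/intake alignment is by age-stage *label*, never position;
  misalignment raises an error naming the missing stage.
- Degenerate inputs: zero-production foods stay in every account with
  zero contributions (keeping the per-food resolution defined); zero
  total protein makes the quality-protein share an error for the scalar
  operation and `NA` at account level; a single overlapping calibration
  year yields a share but an `NA` correlation.
- Test and acceptance problem sizes: property sweeps use 20--200
  replicates per invariant, the share-recovery study 200 seeds at 20
  years and cv 0.02, and end-to-end runs use the full 36-cell pyramid
  over 21--50 years. These sizes give comfortable statistical power for
  the stated tolerances while keeping the whole suite around a minute.

## Known limitations

- Grain used for seed, feed, industry or reserves is deliberately not
  deducted: the accounts describe the *maximum* local supply capacity.
- No food waste or loss adjustment on the demand side.
- Micronutrients are out of scope; only the three macronutrients are
  tracked.
- Future *production* is not modelled; future gaps hold production at
  the baseline year.
- The published per-capita deviation percentages mix denominator
  conventions, and some published nutrient-gap percentages are not
  derivable from the published aggregate tables; the package exposes
  the conventions explicitly and reproduces only the internally
  consistent statistics.
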