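# foodgap

Caloric and macronutrient accounting of regional food self-sufficiency.

Cities in resource-constrained settings — the motivating case is an
oasis metropolitan area in an arid region, where agriculture is bounded
by water and land and food otherwise travels long distances — need to
know how much of their residents' food demand local production could
cover if trade were disrupted. `foodgap` implements that assessment for
nine food groups (cereals, tubers, legumes, vegetables, fruits, meat,
eggs, dairy, aquatic products) at three resolutions: total dietary
energy, the macronutrients (carbohydrate, protein, fat), and the
individual foods. It is aimed at food-systems and regional-planning
researchers working from statistical-yearbook production tables, census
pyramids and dietary-guideline intake recommendations.

## The model

Production mass becomes dietary energy and nutrient mass via
edible-conversion factors CF_j, caloric factors CalF_j and
macronutrient energy proportions EP_jq:

    TCP_j = FP_j · CF_j · CalF_j          TCP = Σ_j TCP_j
    MNP_jq = TCP_j · EP_jq / ECF_q        (ECF = 4/4/9 kcal/g)

Demand follows the age–sex–residence population pyramid and a dietary
structure (per-capita intake FI_aj): TCD_j = Σ_a Pop_a · FI_aj · CalF_j,
with macronutrient demand converted the same way. Three consumption
structures are first-class: S0 (historical average), S1 (guideline
upper limits), S2 (guideline lower limits). The balance statistic is
the signed gap

    Gap = (TCD − TCP) / TCP × 100%

(≤ 0: local production meets demand; > 0: external supply needed), with
an `undefined` flag replacing the percentage where production is zero.
Future demand is projected by downscaling provincial SSP cohort
projections with a calibrated constant-share model, averaging over
basic/near/mid term windows (2011–2030, 2021–2040, 2041–2060), and
comparing against frozen baseline-year production. A synthetic-data
generator with known ground truth backs the validation suite, and
transcriptions of the published Urumqi Metropolitan Area (UMA) summary
tables for 2000–2020 ship as worked-example inputs (`uma_tables()`).

See the methods vignette (`vignettes/foodgap-methods.Rmd`) for the full
account of the model, parameter defaults and limitations.

## Worked example

```r
library(foodgap)
tabs <- uma_tables()

# how far would 2020 production fall short of guideline-upper demand?
dm <- tabs$demand; tp <- tabs$production_totals
gap_percent(dm$total_Bkcal[dm$structure == "guideline_upper" & dm$year == 2020],
            tp$total_Bkcal[tp$year == 2020])
#> [1] 7.992979

# a production account from the 2020 nine-food masses (default factors)
fp <- tabs$food_production
m2020 <- setNames(fp$mass_kt[fp$year == 2020], fp$food[fp$year == 2020])
production_account(m2020, default_factor_table(), year = 2020)
#> Food production account (2020)
#>   Total caloric production: 2055.31 B kcal (plant 1723.68, animal 331.62)
#>   Macronutrient production: carbohydrate 363.86 kt, protein 77.54 kt, fat 32.19 kt
#>   High-quality protein share: 31%

# per-capita consumption against a guideline bound
pc <- tabs$per_capita
guideline_deviation(pc$y2000_kg[pc$food == "aquatic products"],
                    pc$lower_kg[pc$food == "aquatic products"])
#> [1] 74.72678
```

The first number says 2020 caloric production would fall 7.99% short of
demand if every resident consumed at the dietary-guideline upper limit.
The production account converts the nine raw production masses into
energy and nutrient terms under the package's default coefficient table
(illustrative — the published energy totals were computed with the
study region's own coefficients, which is why reproduced statistics are
always taken from the aggregated tables, not re-derived from
coefficients). The last number is the classic adequacy statistic:
aquatic-product consumption in 2000 sat 74.7% below the guideline lower
bound.

End-to-end runs are wrapped by `run_assessment()` (production account +
demand accounts + gap reports per structure) and `run_projection()`
(per-scenario, per-term, per-structure future demand and gaps with a
growth summary). Synthetic inputs for experimentation come from
`generator_config()` / `gen_population_pyramid()` /
`gen_production_table()` / `gen_intake_tables()`.

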