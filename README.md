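# digimaturity

Country-level benchmarking of **digital maturity in health** against
**primary health care performance**.

Health systems are digitizing unevenly: mobile coverage, e-government
services, data-protection law, a digitally skilled workforce and equitable
access by gender all mature at different speeds across countries. This
package implements, as a tested and reusable pipeline, a composite-indicator
analysis of that ecosystem for policy analysts and health-systems
researchers:

1. **Index construction.** Each of 14 indicators, grouped into 7
   subcomponents (infrastructure; workforce; leadership & governance;
   strategy & investment; legislation, policy & compliance; gender
   diversity; consumer readiness), is normalized onto 0–100. The digital
   maturity index for country *i* is the unweighted mean of its 14
   normalized indicators,

   `DM_i = (1/14) * sum_k x_ik`,

   and each subcomponent score is the mean of its constituent indicators.
   Only complete cases (all 14 indicators present) receive an overall index.
2. **Missingness profiling** by WHO region and subcomponent (a country
   counts as missing when ≥ 1 relevant indicator is absent).
3. **Country typing** into quartile-based maturity types — *emerging*,
   *transitioner*, *advanced*, *leader* — with the published 2023 cut points
   available as a preset (`paper2023_boundaries()`).
4. **Association** between the maturity index and a 0–100 primary health
   care performance index (the UHC effective coverage index, taken as an
   input): Spearman rank correlation with a Fisher-z or bootstrap confidence
   interval.
5. **Spending efficiency.** Two OLS regressions
   `I_i = beta0 + beta1 * log(HE_i) + e_i` of each index on log current
   health expenditure per capita, validated with a Shapiro–Wilk test of the
   residuals; each country's residual pair (observed − predicted) places it
   in one of four efficiency quadrants (high-high, high-low, low-high,
   low-low).
6. **Synthetic data.** A latent-capacity generator
   (`generate_countries()`, `paper_shape_preset()`) emulates the joint
   structure of indicators, expenditure, performance and region-patterned
   missingness, so the whole pipeline is testable without any external
   database.

## Worked example

```r
library(digimaturity)

g        <- generate_countries(paper_shape_preset(), seed = 7)  # 194 countries
profiles <- build_profiles(g$records)
ms       <- summarize_missingness(g$records)
typed    <- classify_countries(profiles)                # quartile types
pairs    <- scatter_table(profiles, g$records, typed)
assoc    <- spearman_with_ci(pairs$index, pairs$performance_index)

ms$pct_missing_any
#> [1] 44.3
assoc
#> Spearman rho = 0.87 (95% CI 0.81 to 0.91), n = 108, fisher

he  <- g$records$health_expenditure[match(pairs$country_id, g$records$country_id)]
fm  <- fit_loglinear(pairs$index, he, country_id = pairs$country_id,
                     outcome_name = "maturity")
fm
#> <loglinear_fit> maturity = -8.687 + 11.598 * log(HE)  [n = 108, R^2 = 0.777]
#>   Shapiro-Wilk on residuals: W = 0.994, p = 0.921
fp  <- fit_loglinear(pairs$performance_index, he, country_id = pairs$country_id,
                     outcome_name = "performance")
table(assign_quadrants(fm, fp)$quadrant)
#> high-high  high-low  low-high   low-low
#>        34        17        20        37
```

Reading the output: 44.3% of the 194 simulated countries are missing at
least one indicator, so 108 complete cases with a performance value enter
the downstream analysis. Their maturity index correlates strongly and
monotonically with primary health care performance (rho = 0.87). Maturity
rises about 11.6 index points per unit log-expenditure, the residuals pass
the normality check (p = 0.92), and the 34 `high-high` countries
out-perform their spending level on both fronts while the 37 `low-low`
countries under-perform on both.

Real data are supplied as a CSV with columns `country_id`, `region`, the 14
indicator columns named as in `default_catalog()`, `health_expenditure` and
`performance_index`; see `load_country_table()`. `run_pipeline()` (or the
thin CLI in `inst/cli/digimat.R`) wires all stages end to end and writes
every stage table plus a reproducibility manifest.

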