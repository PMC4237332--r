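# psrbdash

Biodiversity-indicator computation for a Pressure–State–Response–Benefit
(PSRB) dashboard, disaggregated from gridded and polygon data to arbitrary
regional and national analysis units.

Conservation reporting (e.g. against the CBD Aichi targets) needs a small
set of indicators that can be computed consistently across countries from
global data. `psrbdash` implements the computational core of such a
dashboard — the numbers behind the maps, trend charts and summary tables —
for four indicators plus a survey-derived monitoring-capacity score:

| Component | Indicator | Baseline | Trend |
|---|---|---|---|
| Pressure | forest cover and annual gross forest cover loss (GFCL) rate | mean % cover, 2000 | % of 2000 baseline lost per year, 2000–2005 |
| State | Red List Index (RLI) of species survival | RLI, last assessment | ΔRLI/yr (×10⁻³), first→last assessment |
| Response | protected-area coverage of key biodiversity areas (KBAs) | mean % of KBA area protected, 2010 | percentage points/yr, 1980–2010 |
| Benefit | quality-weighted freshwater provision index | relative index, 2010 | none (single time step) |
| Capacity | questionnaire monitoring score | P₁ + ½P₂ on [0, 1] | — |

The core statistics:

* **RLI.** With category weights w(LC)=0, w(NT)=1, w(VU)=2, w(EN)=3,
  w(CR)=4, w(EW)=w(EX)=5 over N weighted species (DD/NE excluded),
  `RLI = 1 − Σᵢ w(cᵢ) / (5N)`; 1 means all Least Concern, 0 all Extinct.
  First-assessment categories are back-cast by reversing a species' genuine
  category change only where the driving threat or conservation action
  operated; the annual change divides ΔRLI by the inter-assessment gap
  (mammals 12 yr, birds 20 yr, amphibians 24 yr; combined: the mean, 56/3 yr).
* **GFCL rate.** `rate = 100 · (mean loss area / mean cover₂₀₀₀) / 5`
  %/yr of the 2000 forest baseline; loss is unidirectional (no regrowth
  credit).
* **KBA protection.** Per site, the % of its area inside the union of
  protected areas established by year *y*; per unit, the unweighted site
  mean. Missing PA establishment dates are imputed by resampling known
  same-country dates; bootstrapping the imputation yields a percentile 95%
  band around the 1950–2010 series.
* **Freshwater provision.** Per cell,
  `index = quality(landcover) · runoff · (population strictly downstream)`
  along D8 drainage directions, normalised by the run-wide maximum
  (values are relative, not absolute).
* **Survey score.** `score = P₁ + 0.5·P₂` with P₁/P₂ the fractions
  answering "Monitored"/"Limited Monitoring".

A seeded synthetic-data generator (`gen_scenario()`) emulates all inputs
with known ground truth, so the full pipeline is testable without any
external download.

## Worked example

```r
library(psrbdash)

cfg <- scenario_config(seed = 42)         # 3 countries in 1 region
scn <- gen_scenario(cfg)
dir <- file.path(tempdir(), "scn")
write_scenario(scn, dir)                  # GeoJSON + .asc + CSV inputs

res <- compute_indicators(dir, n_boot = 200, seed = 42)
res$records[res$records$unit_id %in% c("R1", "U1"),
            c("unit_id", "unit_level", "indicator",
              "baseline_value", "trend_value", "trend_scale")]
```

```
   unit_id unit_level      indicator baseline_value trend_value trend_scale
1       R1     region         forest       44.28077      0.5000       1.000
2       R1     region            rli        0.75600     -0.6429       0.001
3       R1     region kba_protection       57.92237      0.8559       1.000
4       R1     region     freshwater        0.13437          NA       1.000
5       R1     region   survey_score       0.55208           NA       1.000
6       U1    country         forest       43.37788      0.5000       1.000
7       U1    country            rli        0.77021     -0.4559       0.001
8       U1    country kba_protection       71.81376      0.9558       1.000
9       U1    country     freshwater       0.07328           NA       1.000
10      U1    country   survey_score       0.61458           NA       1.000
```

Reading the rows: region R1 has 44.3% mean forest cover in 2000 and loses
0.5% of that baseline per year (exactly the rate the generator planted);
its combined-taxon RLI is 0.756 and declining at 0.64×10⁻³/yr
(`trend_scale` 0.001); 57.9% of its KBA area is protected in 2010, rising
0.86 points/yr over 1980–2010; the freshwater index (0.134) is relative
and has no trend; and the mean monitoring-capacity score is 0.55.
`export_products()` writes the table, per-indicator choropleth GeoJSON, a
JSON feed and trend charts; the same pipeline is scriptable via
`Rscript inst/cli/psrb.R simulate|compute|export`.

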