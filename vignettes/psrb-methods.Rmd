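---
title: "Methods: PSRB indicator computation and its synthetic test world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PSRB indicator computation and its synthetic test world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psrbdash)
```

`psrbdash` computes four biodiversity indicators organised by the
Pressure–State–Response–Benefit causal chain, disaggregated to
user-supplied analysis units (regions and countries), plus a
questionnaire-derived monitoring-capacity score. This vignette documents
the models, the parameters that matter, the synthetic test world, and the
numerical and design choices that were genuinely open.

## Spatial model

Units are polygons (rings under the even-odd rule); grids are regular,
axis-aligned rasters. Zonal aggregation uses the **binary cell-center
rule**: a cell belongs to a unit iff its center falls inside the unit
polygon, with no area-weighting of boundary cells. At the coarse
resolutions these indicators are defined on (18.5-km forest cells;
~2,600 km² freshwater cells, represented here as squares because hexagon
tiling adds nothing to a mean), boundary effects are dwarfed by the
resolution caveats of the source products themselves. Nodata cells are
excluded from both numerator and denominator of every zonal mean, and an
all-nodata zone is an error — reported missing, never silently zero.

National statistics are computed over the full country polygon supplied by
the user, and region rows are computed from region-masked inputs rather
than aggregated from country rows; when country polygons extend beyond the
region boundary the two levels deliberately overlap, and any
double-counting semantics in downstream use are the user's choice.

No geospatial stack is required: grid I/O is ESRI ASCII (`.asc`, doubles
written at 17 significant digits so round-trips are lossless), vector I/O
is GeoJSON. Exact overlap areas are computed for axis-aligned rectangles
by coordinate compression; general polygons fall back to a deterministic
dense point-sampling estimate (128×128 lattice by default, accurate to
well under one percentage point on the fixtures tested). GeoTIFF is not
supported.

## Pressure: gross forest cover loss

Inputs are two aligned grids: percent forest cover per cell (2000) and
percent of cell area deforested 2000–2005 (GFCL, unidirectional — no
credit for regrowth or plantation; negative loss is rejected). Per unit,

\[ \text{rate} = 100 \cdot \frac{\overline{\text{loss}}}{\overline{\text{cover}_{2000}}} \cdot \frac{1}{5} \quad [\%\,\text{of baseline}\,/\,\text{yr}] \]

The loss grid's denominator convention (percent of *cell area*, converted
to percent of the *2000 forest baseline* only inside the rate) is the one
reading that keeps "annual percent forest loss from the baseline"
dimensionally coherent; the export labels the convention explicitly. A
zero-cover unit has an undefined rate and is reported missing.

## State: Red List Index

With weights LC=0, NT=1, VU=2, EN=3, CR=4, EW=5, EX=5 over \(N\) species,
\( \mathrm{RLI} = 1 - \sum_i w(c_i)/(5N) \). The weight scheme is the
standard equal-steps one; the endpoint identities (all-LC ⇒ 1, all-EX ⇒ 0)
are reproduced exactly under it and serve as the consistency anchor.
CR(Possibly Extinct) is treated as CR. DD and NE species are excluded
before computation; membership is binary (a species counts fully in every
unit its range touches).

First-assessment categories are **back-cast**: a species' genuine category
change is reversed only in units where the driving process (threat or
conservation action) operated; elsewhere, and for species without genuine
changes, the last category is held at the first date. Annual change
divides ΔRLI by the inter-assessment interval — mammals 1996→2008 (12 yr),
birds 1988→2008 (20 yr), amphibians 1980→2004 (24 yr) — and the combined
figure uses the mean interval, 56/3 ≈ 18.67 yr.

Two open points were decided here. The combined-taxon RLI is computed over
the **pooled species multiset**, not as a mean of per-taxon indices: the
index is defined on a species set, pooling is the definition applied to
the union, and it keeps the combined value consistent with its own
endpoint identities (a mean-of-taxa variant weights a 25-species group
equally with a 3,000-species group). The export flags the convention.
Second, the interpolation of differently-dated per-taxon series onto a
common year grid is a plotting concern only; headline numbers always use
the two-point formula.

## Response: protected-area coverage of KBAs

Per site and year, coverage is
\(100 \cdot \operatorname{area}(S \cap \bigcup_k P_k)/\operatorname{area}(S)\)
over PAs established by that year — a union, so overlapping PAs are never
double-counted. Unit values are unweighted site means.

Missing establishment dates are imputed by drawing, **with replacement**,
from the known dates of same-country PAs (the standard bootstrap reading
of "randomly sampling"); a country with no dated PAs falls back to the
global pool (logged) rather than dropping the PA, which would bias
coverage downward. Bootstrapping the imputation `n_boot` times (default
1000; percentile 2.5/97.5 bounds) yields the 95% band around the
1950–2010 series. Only imputation uncertainty is modelled — sites are not
resampled — so with zero missing dates the band has zero width. PAs only
accumulate (no degazettement), hence every replicate series is monotone
non-decreasing. The 1980–2010 annual rate is the endpoint difference over
30. Imputation draws are keyed to PA ids over sorted date pools, so
results are invariant to PA input order.

A calibration caveat: the percentile band is honest only insofar as the
empirical pool of known same-country dates represents the date
distribution of the undated PAs. With only a handful of dated PAs in a
country the band genuinely undercovers; the coverage acceptance test
therefore runs on a scenario with 20 PAs per country (the real
protected-area inventory has hundreds), where measured coverage of the
true-date series clears 90% of unit-years.

## Benefit: freshwater provision

On aligned grids of D8 drainage direction (ESRI codes, 0 = sink), runoff,
land cover and population:

\[ \mathrm{index}(c) = q(\mathrm{lc}(c)) \cdot \mathrm{runoff}(c) \cdot \mathrm{pop}_{\downarrow}(c) \big/ \max_{c'}(\cdot) \]

where \( \mathrm{pop}_{\downarrow} \) sums population strictly downstream
along the (validated acyclic) flow path — "downstream" read strictly;
an inclusive mode is available by flag. Each source cell is credited with
the **total** downstream population, not a share-of-flow weighting — the
simpler convention, flagged in the export metadata. Division by the
run-wide maximum makes the field relative on [0, 1]: the published
product is explicitly relative, and this makes "relative" precise — the
index is invariant to rescaling all runoff by a positive constant, which
the tests assert. An all-zero field is returned unnormalised (logged).
Default quality coefficients — forest 1.0, shrub 0.7, crop 0.4, urban
0.1 — order land covers by filtration/contamination of delivered water
and are fully user-overridable; there is no authoritative published
vector to copy. Only a single (2010) time step exists, so this indicator
has no trend operation at all.

## Survey score

`score = P₁ + 0.5·P₂`, scaled 0–1. The denominator **includes "Unknown"**
responses by default: the definition speaks of percent of respondents,
unqualified. An exclude-unknown mode is provided since the reading is
ambiguous. Region scores pool respondents across member countries rather
than averaging country scores; both levels are exported. Scale-preference
tabulation counts each distinct respondent once per scale; multiple
selections are allowed, so columns need not sum to 100.

## The synthetic world

`gen_scenario()` produces every input with known ground truth. Defaults
are fixed once, from the magnitudes of the real study systems:

* **Landscape**: 3 countries tiling one region on a 30×30 grid of 18.5-km
  cells; cover ~ Normal(45%, 15) clamped to [0, 100] (national means in
  the source tables span ~7–71%); loss constructed cell-wise as
  `rate · 5 · cover/100` with rate 0.5%/yr (observed national rates span
  0.08–1.2), making the rate recoverable to 1e-9 by construction. The D8
  field routes every cell one Chebyshev step closer to a random edge sink
  (random tie-break), acyclic by construction.
* **Species**: 30 mammals / 45 birds / 25 amphibians per scenario;
  5% of species carry one genuine ±1-step change (the assessed fraction
  with changed categories is 1–6% in the source tables), deteriorations
  80% of the time, planted by shifting the drawn category so declines
  dominate as in real assessments; drivers localised to a random subset of
  the species' units. Multi-step changes are not generated — they add no
  test power and complicate back-casting fixtures. Exact per-unit RLIs at
  both dates are emitted as a sidecar, computed directly from the planted
  categories.
* **Sites**: KBAs are rectangles, pairwise disjoint within a country (one
  horizontal band each) so the true union coverage stays closed-form;
  each PA covers a known fraction of its anchor KBA from the left or
  right edge. Establishment years are uniform on 1950–2010; 30% are
  withheld (truth kept separately).
* **Survey**: 12 respondents per country (every country×indicator cell
  populated), statuses i.i.d. from (0.45, 0.30, 0.15, 0.10) — expected
  score 0.60, matching the mid-range of the observed per-indicator means
  (0.40–0.79); scale-selection probabilities follow the published
  tabulation (site 0.82 … regional 0.65).

Every generator is a pure function of (seed, config), with one sub-stream
per artifact so adding a generator never shifts another's draws. What the
world does **not** emulate: spatial autocorrelation, realistic range maps
or biogeography, non-rectangular geometries, degazetted PAs, non-genuine
(knowledge-driven) category revisions. A green test therefore establishes
arithmetic and contract correctness of the pipeline — not that any
real-world dataset would be reproduced.

## Numerical choices and degenerate inputs

Undefined quantities (empty unit, all-nodata zone, zero forest baseline,
siteless unit, empty species set) raise classed errors and surface as
explicit missing values in the export — never zeros. CSV/JSON exports
write full precision (17 significant digits; rounding only in chart
labels) and are byte-identical across re-runs on identical inputs.
Bootstrap quantiles use the default type-7 percentile estimator. RLI
trends are exported in units of 10⁻³/yr with an explicit `trend_scale`
field to avoid silent magnitude confusion.

## Known limitations

Rectangle-exact overlap math; general polygons are approximated by
sampling. Percentile bands undercover when a country's dated-PA pool is
tiny (see above). The freshwater model is a declared stand-in with the
same inputs and monotonicities as the published hydrological product, not
a reimplementation of it; its values are comparable only within one run.
Region/country overlap semantics are left to the user.
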