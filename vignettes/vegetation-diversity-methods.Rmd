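---
title: "Methods: community structure, diversity and its uncertainty in vegstruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community structure, diversity and its uncertainty in vegstruct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegstruct)
```

vegstruct implements the community-level analysis of quadrat vegetation
surveys: per-species Importance Value Index (IVI), per-quadrat Shannon
diversity with a richness/equitability decomposition, a bootstrap confidence
interval for mean diversity, and a spatially interpolated diversity surface.
This vignette records the models, the parameter choices, and the design
decisions that were genuinely open — what a maintainer needs to know before
changing anything.

## The survey data model

A survey is three tables: sampling units (quadrat id, planar coordinates in
metres, area in m², default 100), observations (unit, species, individual
count ≥ 1, and a canopy cover area in m² and/or two crosswise crown
diameters in m), and a taxon table (species → genus → family → life form,
with five life forms: tree, shrub, succulent, acaulescent rosette, climber).
Cover resolution follows field practice: an explicit cover area wins; crown
diameters are converted as a circle on the mean diameter,
`crown_area(d1, d2) = π((d1 + d2)/4)²`, times the row's count. Duplicate
(unit, species) rows are summed rather than rejected because field sheets
commonly split tallies; aggregation is order-independent, and a read → write
→ read cycle reproduces the dataset exactly. Coordinates are treated as any
projected CRS; no geodesy is attempted.

## Structure metrics and the IVI

With `N_i` the summed count of species *i*, `S` the sampled area in ha,
`P_i` its occupied-quadrat count and `NS` the number of quadrats:
`A_i = N_i/S`, `F_i = P_i/NS`, `D_i = Ab_i/S` (cover `Ab_i` in m²), and each
relative measure is the percentage share of its absolute column. Shares are
computed directly from `N_i`, `P_i` and `ΣAb_i`: the `1/S` and `1/NS`
factors cancel, so no needless division is introduced. `IVI_i = AR_i + FR_i
+ DR_i` sums to 300 over species; the reported default is `ivi = IVI/3`,
which sums to 100 — the convention of the published structure table this
package fixtures. Ties in the ranking are broken alphabetically by
scientific name so output is deterministic. All internal arithmetic is full
precision; only reports round to one decimal.

Two decisions here were open:

* **Family IVI at reporting precision.** `family_ivi()` by default sums the
  species `ivi` values rounded to 1 decimal. The published family total for
  Burseraceae (8.8%) equals the sum of the published one-decimal species
  values, while the full-precision sum is 8.747 — rounding to 8.7. Summing
  at reporting precision keeps the family table arithmetically consistent
  with the species table a reader sees; `digits = NULL` gives the
  full-precision aggregation (which sums to 100 over families exactly).
* **Fixture keeps printed values.** The packaged absolute columns are the
  published (rounded) per-species values; their abundance column sums to
  1794 against a printed total of 1793 and the dominance column to 4557.7
  against 4557.8. Relative columns are therefore always recomputed from the
  absolute columns, never stored, and recovered published percentages are
  checked to ±0.1 points (one species' abundance cell, *Bursera bipinnata*,
  recomputes to 1.84% against a printed 1.9% — the single borderline case).

## Shannon diversity

`H′ = −Σ p_i ln p_i`, natural log, zero counts excluded. Per-quadrat H′
pools all life forms, since the community table treats them as one
assemblage. Summaries report the mean, sample sd (n−1), min and max over
quadrats plus the pooled H′ of the summed counts; the headline statistic is
the per-quadrat mean, with the pooled value alongside. Classification uses
continuous cut points at 1.35 and 3.5 nats (low/medium/high, right-open at
each cut); the conventional statement of these bands leaves a gap between
1.35 and 1.36, which we close by treating the cuts as continuous.

The equitability decomposition reports the effective species number
`e^H` and the deviations `a = r − e^H` (species short of equiabundance) and
`b = ln r − H` (unrealised potential diversity), computed from the
per-quadrat mean H and total richness r; both are ≥ 0 whenever H ≤ ln r,
which holds because every per-quadrat H is bounded by ln r.

Quadrats with zero individuals are possible in sparse vegetation. The
package scores them H = 0 with a warning by default and offers
`drop_empty_units = TRUE` to exclude them from all summaries; both
behaviours are tested, and the choice is surfaced rather than silently made.

## Bootstrap interval and normality check

`bootstrap_mean_ci()` resamples the n per-quadrat H′ values with replacement
B times (default B = 1000, α = 0.05), takes the replicate means, and reports
the bootstrap mean `H̄*`, its sd σ* using a 1/B variance (no B−1 correction
— the replicate count is chosen by the analyst, not estimated), the absolute
bias |mean − H̄*|, and the normal-quantile interval `H̄* ± z₁₋α/₂ σ*`
centred at the bootstrap mean. A percentile interval is available as an
option. The resampling unit is the quadrat-level H′ value, not the raw
individual: the interval quantifies sampling variability of the survey
design (which quadrats were drawn), and σ* then estimates sd/√n of the
per-quadrat statistics. Every call requires a seed; identical seeds give
bit-identical results, and the caller's RNG stream is restored afterwards.

`lilliefors_normal()` computes the Kolmogorov–Smirnov sup distance against a
normal CDF with estimated mean/sd and obtains the p-value by Monte Carlo
(default 10⁴ standard-normal null samples of the same size, re-estimating
parameters each time) rather than table lookup — reproducible, table-free,
and correct for any n ≥ 4. The statistic is cross-checked in the test suite
against an independent reference implementation; the package reports the
plain p-value and automates no accept/reject conclusion.

## Diversity surface

`interpolate_diversity()` evaluates the piecewise-linear barycentric
interpolant over the Delaunay triangulation of the quadrat locations on a
square-cell grid (default 100 × 100 covering the bounding box padded by one
cell). Linear interpolation was chosen over spline variants because it is
exact at the data, cannot overshoot the observed H′ range, and needs no
tuning; cells outside the convex hull are missing rather than extrapolated.
The triangulation is a Bowyer–Watson incremental construction written for
this package (no installed dependency provides one): coordinates are
rescaled to the unit box, circumcircle membership uses a 10⁻¹² relative
slack, duplicate coordinates are averaged (with a warning) before
triangulation, and collinear point sets are rejected. Validity is tested by
the empty-circumcircle property on random point sets and by exact
reproduction (to 10⁻⁹) of planar fields. Barycentric containment uses a
10⁻⁹ tolerance so hull-edge cells are kept; interpolated values are clipped
to the data range, which a linear interpolant cannot legitimately leave.
Export is plain text: an ESRI ASCII raster (rows north to south) and a
long-format CSV.

## The synthetic survey generator

The generator exists because per-quadrat field data of the motivating survey
are not published; it emulates the statistical structure that the analysis
assumes so every stage can be exercised and validated.

* **Sampling design.** Defaults: 54 quadrats of 100 m², centres uniform over
  a 555 m × 555 m site (30.8 ha) with non-overlap enforced by rejection
  sampling — the study design of the fixtures.
* **Species abundance distribution.** Default lognormal with parameters fit
  (log-scale MLE) to the expected per-survey counts implied by the fixture's
  abundance column — one strongly dominant succulent and a long tail of
  near-singletons. `geometric`, `equal` and `fixed` (given expectations)
  modes are available; totals are realised as Poisson draws around the
  expectation and spread over occupied quadrats by multinomial allocation.
* **Occupancy.** Logit-linear in log expected abundance, fit to the
  fixture's sites column, so rare species are also infrequent — the joint
  abundance/occupancy pattern of the real table.
* **Cover.** Per-individual lognormal cover by life form, parameters fit to
  the fixture's per-individual cover (dominance × area / count).
* **Spatial mode.** `uniform_random`, or `clustered` with parent points and
  a Gaussian-decay dispersion (m) that weights which quadrats a species
  occupies.
* **Calibrated preset.** `raboso_config()` pins the expected totals,
  occupancy probabilities and mean per-individual cover to the fixture
  values and uses the real taxon table. Across seeds its mean relative
  abundances track the fixture's shares; within one replicate the dominant
  species' share still varies with binomial sd ≈ 1.5 percentage points
  (~968 individuals), which is the irreducible noise of any
  individual-level realisation.

What the generator does **not** emulate: interspecific spatial association,
within-site environmental gradients, measurement error in cover, or temporal
dynamics (extraction pressure, grazing). Passing tests therefore validate
the pipeline's arithmetic and its statistical behaviour under the stated
sampling model — not ecological realism beyond the abundance/occupancy/cover
structure described above.

Each `generate_survey()` call returns the dataset plus a truth record (exact
SAD expectations and shares, the H′ of those expectations, occupancy
probabilities), consumed by `truth_recovery_report()` and
`replicate_recovery()`. The latter measures bootstrap CI coverage of the
mean per-quadrat H′, with the coverage target estimated by Monte Carlo on a
disjoint seed stream; the package's acceptance test runs 200 evaluation and
200 truth replicates at B = 1000, sizes chosen so the binomial noise of the
coverage estimate (±~3 points at 200 replicates) is well inside the
tolerance band while the experiment stays comfortably fast on one CPU.

## Numerical and degenerate-input policy

Share computations reject all-zero inputs; Shannon rejects empty or all-zero
counts; the decomposition rejects H > ln r (impossible index); the bootstrap
accepts constant input (width 0) but rejects n < 2; the Lilliefors check
rejects zero variance; triangulation rejects < 3 or collinear points.
Relative columns sum to 100 (IVI raw to 300) within 10⁻⁹ relative tolerance
for any dataset, and rescaling all quadrat areas by a constant leaves every
relative quantity and the IVI unchanged.

## Known limitations

Dominance is canopy-cover based; basal-area dominance and DBH metrics are
out of scope, as are Simpson/Hill-number profiles, rarefaction, kriging and
any cartographic output. The bootstrap offers normal-quantile and percentile
intervals only (no BCa/studentised). Taxon names are taken at face value —
no resolution against nomenclature services.
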