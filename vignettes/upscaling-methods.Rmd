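---
title: "Upscaling inland-water greenhouse-gas emissions: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Upscaling inland-water greenhouse-gas emissions: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoghg)
```

This vignette documents the statistical model behind `cryoghg`, the tunable
parameters and their defaults, the numerical choices made where the design
was genuinely open, and what the synthetic-data tests do and do not
demonstrate about real data.

## The estimation problem

Areal greenhouse-gas fluxes from cryosphere lakes and rivers are compiled
from heterogeneous field studies: clustered within sites, strongly seasonal,
heavy-tailed (CO₂ and CH₄ are approximately log-normal across sites),
zero-inflated for CH₄ ebullition, and sign-indefinite for N₂O (undersaturated
waters take N₂O up). Observations are stratified into cells of
gas × pathway × water body × cryosphere zone × month, and each cell's mean
flux is estimated by resampling. Emission = flux rate × open-water area ×
days, summed over cells.

## The two-level bootstrap

One replicate of a cell resamples **sites** with replacement (as many as the
cell has), then **observations** with replacement within each chosen site,
and takes the mean of the pooled values. Means rather than medians are
bootstrapped because extreme values have already been screened and the mean
retains the influence of legitimately high fluxes. The replicate median is
the point estimate; Q1–Q3 is the reported uncertainty band. Resampling sites
first respects the clustering of measurements within sites, so a single
heavily sampled site cannot dominate a cell; `bootstrap_group(multilevel =
FALSE)` provides a plain observation-level bootstrap for comparison.

Each cell draws from its own RNG substream derived deterministically from
the base seed and the cell key, so results are reproducible and independent
of processing order; within a cell, observations are put into a canonical
order before resampling for the same reason. With few distinct sites per
cell the bootstrap dispersion is biased slightly narrow (the classic
(S−1)/S deflation); this is visible in the coverage experiment below as
interval coverage a shade under nominal.

**Uncertainty propagation is replicate-wise, not formula-based.** Every
aggregate (CH₄ = diffusive + ebullitive, zone, water body, month, annual,
CO₂-equivalent, combined-GHG) is computed by summing replicates within each
replicate index and only then taking quantiles. Aggregation is hierarchical
— each level is the replicate-wise sum of the level below — which makes
totals exactly (bitwise) additive inside every replicate. The alternative,
combining group medians and IQRs through a closed-form propagation rule, is
not well defined for skewed, correlated summands; this divergence is
deliberate and is asserted by the test suite.

## Sparse-month substitution

A cell observed fewer than three times (including not at all) discards its
own statistics and inherits those — replicates included, so propagation
stays coherent — of the month in the same gas × pathway × water body × zone
stratum that has at least three observations and the smallest *absolute*
median; ties break toward the earlier calendar month. The absolute-value
criterion picks the weakest defensible signal regardless of sign, making the
fill conservative: poorly observed shoulder-season months are assigned the
flattest month of their stratum rather than an optimistic interpolation.
Strata with no viable donor (for instance N₂O in the glacial zone, which has
no measurements) contribute zero and are reported as missing, not as zero
emissions. The threshold (3) is configurable (`min_obs`).

## Screening

Outliers are removed before estimation in two stages, per gas pooled over
each water-body dataset: Rosner's generalized ESD test (α = 0.05, up to
k_max = 10 outliers, on raw values), then hard caps retaining CO₂ fluxes
strictly below 86 827 and CH₄ below 2 400 mmol m⁻² day⁻¹ (the caps encode
the plausibility limits of the compiled data; values *equal* to a cap are
removed and logged). N₂O has no cap. The α, k_max and pooling level are
conventional defaults — only the caps are externally fixed — and pools
smaller than k_max + 2 skip the ESD stage.

Two properties deserve note. First, the ESD statistic is weak on very
heavy-tailed pools (the extreme value inflates the standard deviation that
normalises it), which is why a hard-cap stage follows it. Second, a single
ESD pass is not a fixpoint operation: re-running it on screened heavy-tailed
data can flag further tail points, and iterating it to convergence strips
2–12 % of perfectly clean log-normal samples. Screening is therefore defined
as one pass, and `screen_dataset()` records the rule set it applied on the
returned object so that re-screening under the same rules is a no-op —
idempotence by provenance, not by re-testing.

## Areas

Monthly open-water areas per zone and water body are consumed as tables.
Two derived components are computed in-package:

- **Small-lake extrapolation.** Lake inventories are binned at 0.0001 km²;
  a log–log OLS of count on mean bin area over the reliable 0.03–0.1 km²
  class gives `count = c · areaᵇ` (back-transformed without smearing
  correction, matching the reference coefficients c = 23.74398,
  b = −1.490131). Unrounded counts are summed over bin centers 0.0001,
  0.0002, …, 0.0300 km² (both endpoints included; the terminal bin
  contributes < 0.2 %). The resulting yearly-maximum area is assumed to
  occur in September and is distributed over months by the monthly/September
  ratios of the smallest observed size class, then allocated across zones
  proportionally to each zone's large-lake area per month — the minimal
  assumption, since the extrapolation is cryosphere-wide but upscaling is
  zonal.
- **River freeze adjustment.** Cryosphere rivers are taken as completely
  frozen in the coldest month: the January area is subtracted from all
  twelve months (clipped at zero).

## Budgets, NEE, and the offset

CO₂-equivalents use IPCC AR6 mass factors (CH₄: 79.7 at GWP₂₀, 27.0 at
GWP₁₀₀; N₂O: 273 at both); N₂O's Gg → Tg conversion happens inside the
conversion so all CO₂e sums are in Tg. Zonal terrestrial NEE is the weighted
sum of gridded values × cell area × the fraction of each cell covered by the
zone; annual NEE uses complete calendar years only (incomplete edge years of
a multi-year product are dropped), with medians and IQRs across years. The
offset statistic is (E − |NEE|) / |NEE| × 100 for a net sink (NEE < 0); a
net-source NEE has no sink to offset and is reported as such. The calendar
is a non-leap 365-day year.

## The synthetic world

The generator emulates the *structure* of the compiled database, not its
values: 8 sites per zone × water body (desk scale; the compiled database has
hundreds per stratum), about 2 observations per site-month at peak sampling
with reduced shoulder-season sampling, log-normal CO₂ and diffusive CH₄ with
zone multipliers and a seasonal sinusoid, zero-inflated ebullition (zero
shares 0.13 lake / 0.39 river), N₂O with prescribed sink shares (0.65 lake /
0.36 river) and no glacial measurements, and qualitative orderings that
mirror the observed system: river CO₂ > lake CO₂, highest ebullition in
sporadic/isolated permafrost, near-zero glacial fluxes with glacial-river
CO₂ slightly negative. Observations are drawn only in months whose zonal
open-water area is positive. Ground truth (group means, areas, annual
emissions) is closed-form.

What passing tests show: the estimator recovers known truth exactly when
noise is zero; 95 % bootstrap percentile intervals cover true annual totals
at close to nominal rate over 100 independently seeded worlds (run at
B = 1000 and full-month sampling so the estimand is identifiable; the
default shoulder-season sparsity instead exercises the substitution rule,
whose conservative fill biases totals a few percent low by design). What
they do not show: robustness to site-level random effects, non-stationary
multi-year trends, spatial autocorrelation between sites, or reporting
heterogeneity across source studies — none of which the generator models.

## Numerical and interface choices

- Quantiles are `stats::quantile` type 7 throughout.
- Period labels that cannot be placed in a calendar month (seasonal or
  annual reporting) are excluded from upscaling and tallied in a coverage
  log; no global season → month mapping exists because source studies define
  seasons site-specifically.
- Sub-daily replicates are averaged at the (site, date, gas, pathway) key at
  ingest.
- CH₄ records labeled `total` enter only for cells lacking both
  pathway-specific series and are never added on top of them.
- The concentration subtable is schema-validated but never used for
  emissions (converting concentrations to fluxes would import gas-transfer
  velocity uncertainty).
- Bootstrap iterations default to B = 1000 in the pipeline (test scale;
  10 000 for release-quality uncertainty bands). The Monte Carlo error of the
  replicate median shrinks as B^(−1/2).
- The pipeline is deterministic given (configuration, seed): identical seeds
  produce byte-identical numeric artifacts.

## Known limitations

Annual emissions are likely conservative: ice-out burst emissions are
under-represented in compiled data, and the sparse-month rule substitutes
the weakest month. The zonal allocation of the extrapolated small-lake area
is an assumption (proportional to large-lake area). The ESD screening level
(α, k_max, pooling) is conventional rather than externally fixed. N₂O totals
omit strata with no measurements rather than imputing them.
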