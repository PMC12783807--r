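---
title: "Methods: river-mouth nutrient stoichiometry assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: river-mouth nutrient stoichiometry assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverstoich)
```

## The problem

Harmful algal blooms in coastal waters are fed not only by the absolute
amounts of nitrogen and phosphorus a river delivers, but by their balance
against dissolved silica. Diatoms — the "good" silica-walled phytoplankton —
can absorb N and P loads only while Si lasts; N or P left over after Si is
spent is available to less desirable taxa. `riverstoich` implements a
concentration-based stoichiometric screening of river-mouth monitoring
records: where does a river's dissolved inorganic nitrogen (DIN), total
phosphorus (TotP) and dissolved silica (Si) mixture sit relative to the
Redfield reference, which nutrient is stoichiometrically depleted, how
eutrophic is the site, and by how much do N and P exceed what the available
Si could balance.

## The model

All index equations work on molar concentrations (µmol l⁻¹) obtained from
mass concentrations with the integer molar masses 14 (N), 31 (P) and
28 (Si) g mol⁻¹. Only the SiO₂→Si conversion uses the precise masses
28.08/60.08, because monitoring programmes report the oxide with that
convention. Keeping the integer masses inside the indices reproduces the
published constants exactly (e.g. the 0.4 and 0.055 critical-concentration
factors below); mixing precise and integer masses would shift them in the
third decimal.

**Ternary coordinates.** Each sample's molar triplet is scaled by the
Redfield reference N:P:Si = 16:1:20 and renormalised:

$$\mathrm{N\%} = 100\,\frac{\mathrm{DIN}/16}{\mathrm{DIN}/16 + \mathrm{TotP} + \mathrm{Si}/20},$$

and analogously for P% (weight 1) and Si% (weight 20). A sample exactly at
16:1:20 sits at the centre, 33.3/33.3/33.3. An element with a percentage
*strictly below* 20% is called depleted; the zone is the depleted set
(`P_depleted`, `NP_depleted`, …, or `balanced`). Equality with the
threshold counts as not depleted. The Si term of the reference is a single
configuration knob (`element_constants(redfield_si = …)`, default 20;
16–40 are in published use from marine to freshwater diatoms) and
propagates consistently to every equation.

**Trophic status.** The Carlson-style index of the *depleted* nutrient is
used: when molar N:P > 16 (evidence of P depletion)
$\mathrm{TSI} = 4.15 + 14.42\,\ln(\mathrm{TotP}\ \mu g\,l^{-1})$, otherwise
$\mathrm{TSI} = 54.45 + 14.43\,\ln(\mathrm{DIN}\ mg\,l^{-1})$. N:P exactly
16 takes the TotP branch — the published equation labels attach "N:P > 16"
to the P form, the tie is measure-zero, and a deterministic rule is
required. Classes are half-open on the left boundary of the higher class:
TSI < 30 ultra-oligotrophic, [30, 40) oligotrophic, [40, 50) mesotrophic,
[50, 60) eutrophic, ≥ 60 hypereutrophic. A zero concentration gives
TSI = −∞, flagged and classed ultra-oligotrophic.

**ICEP and critical concentrations.** The index of coastal eutrophication
potential converts flux imbalances to carbon equivalents
(kg C km⁻² d⁻¹):

$$\mathrm{ICEP}(P) = \left[\frac{P_{flx}}{31} - \frac{Si_{flx}}{28 \times 20}\right] \times 106 \times 12,
\qquad
\mathrm{ICEP}(N) = \left[\frac{N_{flx}}{14 \times 16} - \frac{Si_{flx}}{28 \times 20}\right] \times 106 \times 12.$$

Because flux = concentration × runoff, setting ICEP = 0 yields critical
concentrations independent of runoff: DIN₀ = (14·16)/(28·20)·Si = 0.4·Si
and TotP₀ = 31/(28·20)·Si ≈ 0.055·Si, all in the same mass units.
Exceedance ratios D = measured/critical are then sign-equivalent to ICEP
(D > 1 ⟺ ICEP > 0 for the same branch), which the test suite verifies over
randomized draws. ICEP itself is only computed when runoff is supplied;
the concentration-only route needs no load estimates, which is the
practical appeal of the critical-concentration form. The same N:P ≥ 16
tie rule selects the branch, so every site reports exactly one ICEP basis.

## Ingest and quality control

Raw CSVs carry one row per sample (`site_id, date, totp` plus nitrogen as
`no3_no2`/`no3` and/or `nh4`, silica as `si` or `sio2`). DIN is the sum of
the *available* inorganic-N species — monitoring programmes differ in
whether nitrite is bundled with nitrate and whether ammonium is reported,
so a missing species contributes zero and only all-missing flags the
record unusable. Values below a reported detection limit are replaced by
half the limit (`bdl_policy = "half_limit"`; `"as_is"` keeps them — no
substitution rule is standard, so both are exposed). Duplicate site-date
rows are averaged (order-independent). A `depth` column, when present, is
filtered at 1 m (surface samples). The study window defaults to
2017-01-01–2024-12-31.

A site is retained only if *every* calendar year in the window has at
least 6 samples (inclusive boundary) with DIN, TotP and Si jointly
usable. The joint reading is a choice: applying the rule per analyte
separately could retain a site whose triplets never co-occur, which would
break the per-sample metric computation downstream.

## The aggregation ladder

Every metric is computed per sample first, then averaged — never the
other way round, except where a summary is explicitly defined on
aggregated concentrations (site-level TSI and exceedances, which describe
a site's average status). The ladder: annual value = mean of that year's
samples; overall value = mean of annual values (equal weight per year,
regardless of sampling effort); monthly value for calendar month *m* =
mean over years of the within-year mean of month *m*'s samples. With a
balanced design the two-step and pooled monthly means coincide (tested);
with unbalanced sampling they differ and the two-step form is the
default, a pooled alternative being available via
`aggregate_metrics(mode = "pooled")`. Months with no samples in any year
are dropped from the monthly table with a warning and excluded from the
minimum-Si scan. Arithmetic means only; no flow weighting.

The minimum-Si scan returns each site's most Si-depleted calendar month,
its meteorological season (Mar–May spring, Jun–Aug summer, Sep–Nov
autumn, Dec–Feb winter) and a depletion flag (< 20%). Ties take the
earliest calendar month, for determinism.

For the site-level exceedance summary the monthly critical values use
*month-specific* Si: seasonal Si drawdown is exactly the signal the
monthly ladder exists to expose, and a year-round critical value would
mask it. This is configurable in spirit (the functions accept any
aggregated table) but month-specific is the shipped behaviour.

## The synthetic generator

`synth_generate()` emulates the statistical structure of Nordic
river-mouth monitoring without any external download: monthly sampling
2017–2024; site latitudes uniform on 55–70°N; site-median DIN and TotP
log-linear in latitude spanning roughly 2000→50 and 120→5 µg l⁻¹ south to
north (the simplest monotone structure matching a north–south gradient);
Si latitude-independent with median 2700 µg l⁻¹; lognormal site-level
scatter with sdlog 0.3 (chosen once as a realistic between-river spread,
about ±35% at one sigma); a multiplicative sinusoidal Si drawdown with
trough in May and depth 0.30 (spring diatom uptake); and lognormal
per-sample noise with CV 0.4, matching the strong right skew of real
records, where standard deviations are of the order of the means.
The truth table (zone, trophic basis, minimum-Si month) is computed
*analytically from the site medians*, not from simulated samples, so
recovery tests have an unambiguous target. `make_redfield_site()` inverts
the equations to construct a median triplet in any requested zone and
trophic class, verifying the request against the forward equations.

What the generator deliberately omits: flow time series and
concentration–discharge hysteresis, lake retention, detection-limit
censoring beyond a simple rate, analytical method changes, and long-term
trends. Passing recovery tests therefore shows the *pipeline* inverts its
own generative assumptions, not that real Nordic data meet them.

## Numerical choices and degenerate inputs

All-zero molar triplets are rejected (undefined composition); a depletion
threshold outside (0, 100/3) is rejected (three-way depletion is
impossible above a third); zero concentrations give TSI −∞ flagged rather
than an error; a zero critical concentration (no Si) gives an infinite
exceedance with a warning. Ternary percentages supplied by the user are
validated to sum to 100 within 0.01. File outputs are written at 6
significant digits; all internal computation is double precision.

## Recovery performance and a known limitation

`analysis/03_recovery.R` measures recovery at noise CV 0.2 (half the
generator default), 8 years × 12 months, 50 sites. Two structural limits
emerge, both properties of the study design rather than of the code.
First, zone recovery sits just below full marks (~88–94% across seeds)
because a fraction of sites' true compositions fall within one or two
percentage points of the 20% boundary, where classification is
intrinsically unstable under any noise. Second, minimum-Si *month*
recovery is poor (~30%) even at this moderate noise: a sinusoid is flat
at its trough (April and June sit only ~3% above May), while a monthly
mean of 8 lognormal samples at CV 0.2 still carries ~5–7% noise, so
adjacent months tie. Misses are correspondingly all within two months of
the trough, and the *season* is recovered far more reliably than the
month. With noise removed (CV 0) both recoveries are exact, which the
synthetic-module tests assert. Users screening real data for seasonal Si
depletion should therefore interpret the minimum month as ±1–2 months,
or aggregate to seasons.

## Problem sizes

The shipped tests and analysis scripts run at 50 sites × 8 years ×
12 months (4800 samples), which resolves every qualitative behaviour of
the pipeline while keeping any single run in the seconds-to-a-minute
range on one CPU.
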