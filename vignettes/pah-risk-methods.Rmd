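---
title: "From residues to risk: methods behind pahrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From residues to risk: methods behind pahrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahrisk)
```

## The problem

Polycyclic aromatic hydrocarbons (PAHs) accumulate in medicinal and food
plants from contaminated soil and air. A monitoring laboratory typically
reports, per commodity, the mean concentration of each of the 16 EPA
priority PAHs, with values below the limit of detection (LOD) recorded as
"nd". `pahrisk` turns such a censored herb × analyte table into a full
risk characterization: contamination screening, pollution-source
apportionment, benzo[a]pyrene toxic-equivalency (TEQ) scoring, the
incremental lifetime cancer risk (ILCR) model, and a seeded Monte Carlo
probabilistic assessment with sensitivity analysis. A packaged survey of
seven Chinese herbal medicines (`chm_pah_table()`) serves as the worked
instance throughout.

## Data model and non-detect policy

A `concentration_table` stores concentrations (µg/kg) and a logical
detection matrix; a non-detect has **no stored numeric value**. Every
operation that needs complete numbers takes an explicit `nd_policy`:

* `"zero"` (default) — nd contributes 0, matching the "excluded from
  calculation" convention of monitoring tabulations;
* `"half_lod"` / `"lod"` — substitute LOD/2 or LOD, the standard
  left-censoring conventions; per-analyte LODs default to the registry
  values (4.96–8.14 µg/kg, signal-to-noise ≥ 3 instrument limits).

This keeps censoring a *policy at computation time*, never a property of
the data. The zero policy understates totals when censoring is heavy;
the LOD policy bounds them from above. For the packaged survey the choice
barely matters for the dominant low-ring analytes (detected at 5–30 ×
LOD) but flips nothing in the regulatory flags, which only use detected
values.

## Screening statistics

Per herb: detection rate (detected analytes / 16), total burden (policy
sum), EU PAH4 marker sum (BaA + Chry + BbF + BaP) against the 35 µg/kg
limit and BaP against 5 µg/kg — both strict inequalities, since the
regulatory language is "exceeded". Per analyte: min/max over detected
cells only. Ring-class shares partition the burden over 2–3-, 4- and
5–6-ring analytes on a concentration basis and a TEQ basis
(concentration × TEF); shares of a zero-total herb are undefined and
flagged rather than silently zero. Heterogeneity of detection across
herbs is a Pearson chi-squared test on the herbs × (detected,
not-detected) counts table without continuity correction, df = herbs − 1.

Two documented discrepancies with the source tabulation of the packaged
survey: the printed contamination rate of 35.83% for *Coix lacryma* is
not k/16 for any integer k (the table's column gives 6/16 = 37.5%, which
the package reports), and the chi-squared test on the tabulated detection
counts (11, 10, 6, 6, 8, 9, 6 of 16) gives X² = 6.5, df = 6, p ≈ 0.37 —
not significant, although the narrative accompanying the survey claims
p < 0.05 (plausibly computed on per-replicate counts never tabulated).
The package always reports the value it computed.

## Diagnostic isomer ratios

Source apportionment uses the three conventional isomer ratios,
Flt/(Flt+Pyr), Ant/(Ant+Phe) and BaA/(BaA+Chr), computed from
policy-imputed concentrations; a ratio whose denominator pair is entirely
non-detected is undefined (`NA`), never 0/0. Classification bands are the
literature cut points (`ratio_thresholds()`, fully overridable because
the bands are conventions, not laws):

| ratio | petroleum | mixed / fossil-fuel | combustion |
|---|---|---|---|
| Flt/(Flt+Pyr) | < 0.4 | 0.4–0.5 (fossil fuel) | > 0.5 (biomass/coal) |
| Ant/(Ant+Phe) | < 0.1 | — | ≥ 0.1 |
| BaA/(BaA+Chr) | < 0.2 | 0.2–0.35 | > 0.35 |

Intervals are **lower-closed** (a ratio of exactly 0.4 is fossil-fuel
combustion): a fixed, documented tie-break, since different literature
sources draw the boundary either way. `crossplot_coordinates()` exports
the two standard crossplot panels in long format, omitting undefined
points with a message.

## TEQ and ILCR

The toxic-equivalent concentration is

$$\mathrm{TEQ} = \frac{\sum_i C_i \cdot \mathrm{TEF}_i}{1000},$$

with Nisbet–LaGoy TEFs by default (BaP = DahA = 1 down to 0.001 for the
low-ring analytes). The divisor is exposed in the `tef_scheme` and
recorded in every result because the *unit* of the TEQ depends on it:
µg/kg inputs divided by 1000 give mg/kg BaP-equivalents (despite some
sources labelling the same formula "ng/kg"). The package implements the
formula as conventionally printed and does the unit bookkeeping
explicitly, so the analyst can match the cancer slope factor convention
— CSF in (mg/kg·day)⁻¹ pairs with the mg/kg TEQ.

The risk model is the multiplicative chain

$$\mathrm{ILCR} = \frac{\mathrm{TEQ} \cdot DR \cdot CSF \cdot EF \cdot ED}{BW \cdot AT}$$

with DR the daily intake (g/day), CSF the slope factor, EF the exposure
frequency (365 d/yr for habitual consumption), ED the exposure duration
(yr), BW body weight (kg) and AT the averaging time (d). Bands follow
the EPA decades: < 10⁻⁶ negligible, 10⁻⁶–10⁻⁴ potential (both
boundaries *included*, reading "between" inclusively), > 10⁻⁴
unacceptable. Population exposure factors are survey quantities the
package cannot know; `write_exposure_template()` emits a documented JSON
starting point with placeholder values, and `read_exposure_config()`
validates user-supplied configurations. Consequently the package makes
no claim about any published per-age-group ILCR magnitudes.

## Monte Carlo engine

Stochastic inputs are described by `dist_spec` objects (point, normal,
lognormal, uniform, triangular; optional truncation). Two conventions
matter:

* **Lognormal specs use arithmetic moments.** Published probabilistic
  risk tables report lognormal "Mean" and "SD" on the arithmetic scale;
  `lognormal_from_moments()` converts via
  `sdlog² = log1p((sd/mean)²)`, `meanlog = log(mean) − sdlog²/2`
  (`log1p`/`expm1` keep the round trip at machine precision).
* **Truncation by inverse transform.** Draws map uniforms into the CDF
  mass between the truncation bounds — exact, rejection-free,
  constant RNG cost per draw, hence reproducible streams.

`simulate_ilcr()` draws n (default 10,000) independent joint samples —
inputs are sampled independently, as no dependence structure is asserted
— applies the ILCR chain row-wise, and reports arithmetic moments,
10/50/90th percentiles, a lognormal fit of the output and sensitivity
shares, all stamped with the mandatory seed. Percentiles are linear
interpolation between order statistics (R's `type = 7`); the rule is
fixed and stated because published tables rarely say which quantile
definition generated them.

**Distribution fitting** (`fit_distribution()`): each candidate family is
fitted by maximum likelihood, then scored by the Anderson–Darling (AD)
statistic against the fitted CDF and by a Pearson chi-squared statistic
on equiprobable bins (expected counts ≥ 5). Selection minimizes AD —
listed first among the two criteria — with ties broken by chi-squared,
then candidate order; both statistics are always reported. Candidates
whose support excludes the data are skipped with a message; constant
samples are an error. The triangular fit fixes the endpoints just outside
the sample range and maximizes likelihood over the mode, a pragmatic
estimator (full triangular MLE over all three parameters is ill-posed at
the boundary).

**Sensitivity** is contribution-to-variance in the form commercial risk
add-ins display: for each stochastic input, the squared Spearman rank
correlation with the output, normalized to sum to 100% over inputs, with
the correlation's sign attached (positive = drives risk up, e.g. intake;
negative = drives it down, e.g. body weight). Constant columns get share
0 and are excluded from the normalization. Rank correlation makes the
shares invariant to monotone rescaling of any input.

## Synthetic data: the stated world

`generate_concentration_table()` emulates the structure the analysis
assumes, not any particular survey: each cell's true level is lognormal
with per-analyte median `location` × a plant-part multiplier and
geometric SD `spread`; a cell is reported "nd" iff its true level falls
below the analyte's LOD (a hard threshold — the LOD semantics of
signal-to-noise limits). The uncensored truth matrix is returned
alongside, so tests can verify end-to-end recovery. Defaults, chosen
once as field-plausible and not revisited:

* medians 30 / 10 / 3 / 0.5 µg/kg for 2–3 / 4 / 5 / 6-ring analytes —
  low-ring dominance, the universal observation in plant matrices;
* geometric SD 2.5 — a typical between-sample spread for trace organics;
* part multipliers root_stem 3 > flower 2 > fruit_seed 1 — roots contact
  contaminated soil longest, fruits develop latest (the qualitative
  ordering reported for real surveys); values are configuration, not
  claims;
* LODs = the instrument values of `pah_registry()` (4.96–8.14 µg/kg).

Under these defaults censoring is rare for 2–3-ring analytes (~2–3%),
moderate for 4-ring (~25%) and heavy for 5–6-ring (> 80%), reproducing
the detection pattern of real tables. What the generator deliberately
does **not** emulate: measurement noise on detected means (surveys report
replicate means with small RSDs, not raw replicates), between-analyte
correlation within a herb, matrix effects and recoveries. A green test
on synthetic data therefore establishes the computational chain, not the
chemistry.

`generate_exposure_population()` draws factor populations from
`dist_spec`s with the same machinery (point factors give constant
columns), for probabilistic assessments and for testing the engine
against closed forms.

## Numerical choices and degenerate inputs

* Quantiles: `type = 7`; seeds: mandatory for every generator and
  simulation, restored on exit so library calls never disturb the
  caller's RNG stream.
* Zero-total herbs: ring shares undefined and flagged; zero-denominator
  ratios: `NA` with the "indeterminate" label downstream.
* Boundary conventions, all fixed and tested: regulatory limits strict
  (`>`), risk-band boundaries inclusive into "potential", ratio bands
  lower-closed.
* Chi-squared GOF bins: k = clamp(n/5, 4, 50) equiprobable bins under
  the fitted CDF.
* AD statistic clamps fitted CDF values away from 0/1 by machine epsilon
  before taking logs.

## What the tests establish

The suite reproduces every desk-reproducible published number of the
packaged survey (row sums to printed precision, detection rates,
analyte extremes, derived diagnostic ratios and their classification,
the TEQ of the single-BaP cell, risk bands at published values) and
checks the stochastic machinery against independent oracles: closed-form
lognormal quantiles with bootstrap standard errors, the normal-CDF
censoring probability, textbook chi-squared recomputation, moment
round trips, and family-recovery rates for the fit selector. The 90th
percentile of the published glycyrrhizae risk distribution (printed
4.59 × 10⁻⁵) is recomputed from its arithmetic mean/SD by the full
simulation engine; the closed form gives 4.45 × 10⁻⁵, and seeded runs
land within a few percent of both.

## Known limitations

* The published survey's per-age-group exposure factors live in an
  unavailable appendix, so per-group risk magnitudes and the exact
  79.2%/11.9% sensitivity shares are not reproducible; the machinery is
  tested on synthetic configurations instead.
* Means-with-RSD tables carry no replicate information: no
  between-replicate statistics are attempted.
* Inputs to the Monte Carlo are independent; if intake correlates with
  body weight in a real population, the percentiles will be biased
  accordingly.
* Fitting candidates are the four families above; heavy-tailed
  alternatives (gamma, Weibull) were out of scope for the selector.
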