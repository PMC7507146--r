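---
title: "Methods: dissolved and particulate N:P stoichiometry in stream monitoring records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissolved and particulate N:P stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamstoich)
```

## The analysis

Multi-site stream water-quality records report total nitrogen and
phosphorus (TN, TP, unfiltered digested samples), dissolved inorganic
fractions (ammonia as NH3-N and NH4-N, nitrate+nitrite as NO3-N+NO2-N,
orthophosphate as DIP; filtered samples), and, at a subset of sites, total
dissolved fractions (TDN, TDP). From these this package derives the
suspended particulate fractions

  PN = TN - DIN - DON,    PP = TP - DIP - DOP,

and asks how N and P concentrations, and the molar N:P ratios of the
dissolved and particulate pools, vary with watershed land use, stream
discharge, and each other. Molar ratios use the atomic masses 14.007 (N)
and 30.974 (P); a molar N:P of 16:1 (the Redfield reference) corresponds
to a mass ratio of about 7.2.

Five stages make up the pipeline, each exposed as package functions and
driven by the numbered scripts under `analysis/`:

1. **Ingest** (`read_sample_table()`, `read_landuse_table()`,
   `join_site_data()`): CSV tables are validated and joined; invalid rows
   go to a rejects report, never silently away. NLCD land-cover classes are
   aggregated to crop, hay (pasture), urban (low+medium+high intensity) and
   forest (deciduous+mixed+coniferous), divided by 100 to proportions.
2. **Consistency filter** (`filter_inconsistent()`): records whose reported
   DIN exceeds TN (or DIP exceeds TP) are physically inconsistent and are
   removed, with counts and fractions reported per analyte. The filter acts
   on *reported* values (less-than values at their reporting limits),
   before any Monte Carlo draw.
3. **Censoring imputation** (`impute_qualified_value()`, `impute_table()`):
   "estimated" values are replaced by a Normal(value, cv x value) draw
   truncated at zero by resampling; "less-than" values by a
   Uniform(lower bound, reporting limit) draw. Truncation by resampling
   rather than clipping avoids a spurious point mass at zero.
4. **Particulate derivation** (`estimate_dom_proportions()`,
   `bootstrap_particulate()`, `derive_nutrients()`): the dissolved organic
   share of the total-minus-inorganic residual is estimated empirically
   from paired records as (TDN - DIN)/(TN - DIN); shares outside [0, 1]
   are excluded and counted. For each record, 1000 shares are resampled,
   candidate particulate values residual x (1 - p) formed, and one uniform
   draw taken from the candidates' interquartile range. A non-positive
   draw leaves the record's PN (or PP) missing, excluded pairwise from
   ratio analyses with counts reported.
5. **Statistics**: threshold exceedance, descriptive summaries and
   percentile loess (`stoich` metrics); the homeostasis regression and
   discharge power laws; and the land-use mixed models (below).

## The homeostasis coefficient

Stoichiometric regulation is summarised by the slope 1/H of

  log10(PN:PP) = log10(c) + (1/H) log10(DIN:DIP) + error,

fit by ordinary least squares. A slope near 0 means particulate N:P is
static (chemostatic) across the dissolved supply; a slope near 1 means
particles track the dissolved pool proportionally, as Redfield-style
assimilation would produce. The regression is also refit within low-TP
(< 0.025 mg/L) and high-TP (> 0.10 mg/L) subsets — a proxy contrast for
suspended autotrophic biomass — and per site for sites with strictly more
than 100 complete ratio pairs. Eligibility thresholds are strict
inequalities throughout (("> 100 samples", "> 10 records")).

Plain OLS is used deliberately, with no errors-in-variables correction,
matching standard practice for this regression; because the dissolved
ratio itself carries measurement and imputation noise, the estimated slope
is mildly attenuated relative to a hypothetical error-free predictor. This
caveat is inherited by any analysis built on the fit.

Discharge dependence is summarised per site by the power law
N:P = a Q^b, fit as OLS in log10-log10 space; b = 0 is chemostatic. The
site-specific exponents are then regressed on % agriculture (crop + hay),
% urban and % forest by simple linear regression.

## Land-use mixed models

Each log10 concentration (TN, DIN, PN, TP, DIP, PP) is modelled as

  log10(conc) ~ log10(Q) + pCRO + pHAY + pFOR + pURB + (1 | site),

fit by REML (`lme4`). Wald 95% intervals and z-type p-values are reported;
Wald was chosen because the reported quantity is "intervals that exclude
zero" and Wald is the simplest interval consistent with that use (profile
intervals are available from the underlying `lmerMod` object, which every
fit retains). Standardized coefficients are raw coefficients times the
predictor's sample standard deviation, identical to refitting on z-scored
predictors. Marginal and conditional R² follow the Nakagawa–Schielzeth
variance decomposition for Gaussian identity-link models. Percent
particulate side models use 100 x PN/TN (or PP/TP) as the response with
land-use covariates in percent, so a slope reads as percentage-point
change per percent land use. Complete-case analysis is used per response;
singular fits (site variance at zero) are retained and flagged.

## The synthetic generator

`synthetic_config()` / `generate_landscape()` / `generate_samples()` /
`inject_censoring()` produce panels with full ground truth:

- **Land use**: site compositions over (crop, hay, urban, forest, other)
  from a Dirichlet with concentration (0.40, 0.40, 0.35, 0.60, 0.75) —
  widely dispersed with many near-end-member watersheds, because
  monitoring networks deliberately sample land-use extremes; means are
  about 16/16/14/24/30%, matching the spread typical of continental
  panels. Watershed areas are lognormal (median ~700 km²).
- **Discharge**: log10 Q ~ Normal(2, 1) (median 100 L/s), independent of
  land use by default.
- **Dissolved and particulate N**: log10 DIN, log10 DIP and log10 PN each
  follow intercept + effects x land-use proportions + effect x log10 Q +
  site intercept + noise, with the default effect sizes set to the
  magnitudes reported for continental watershed mixed-model fits (e.g.
  crop effect on log10 DIN = 1.183). Site sd 0.3 and residual sd 0.2
  (log10 mg/L) reproduce conditional R² well above marginal R², as
  observed in such panels.
- **Coupling**: log10(PN:PP) = 0.434 + 0.096 x log10(DIN:DIP) +
  Normal(0, 0.3), and PP is solved from PN and the ratio. Generation order
  (dissolved → organic share → PN → ratio → PP) imposes the true 1/H on
  exactly the quantity the homeostasis stage measures.
- **Mass closure**: DON and DOP are Beta(2, 5) shares of the residual
  (DON = PN x p/(1-p)), so TN = DIN + DON + PN and TP = DIP + DOP + PP
  hold exactly on every record, and TDN/TDP come for free.
- **Censoring**: values below analyte detection limits become "less than"
  the limit; 5% of the remainder are flagged "estimated". Default limits
  follow typical published laboratory reporting limits (ammonia 0.01,
  nitrate+nitrite 0.04, orthophosphate-P 0.004 mg/L as N or P), under
  which the minor ammonia fractions are censored often (tens of percent)
  and dominant nitrate rarely — the regime seen in real records.

What the generator does *not* emulate: storm-event hydrographs and
C-Q hysteresis, seasonality, serial correlation within sites beyond the
random intercept, spatially correlated land use, laboratory method
changes, and correlated errors between totals and dissolved fractions.
Passing recovery tests therefore demonstrate statistical correctness of
the estimators under the assumed structure, not robustness to those
real-data features.

## Numerical choices and known behaviour

- Medians and quartiles use linear interpolation (R's type-7 default),
  stated for reproducibility.
- Exceedance uses strict ">" ("above" a threshold); ties are measure-zero
  on real data.
- Percentile loess: sliding-window empirical percentiles (half-width 5
  land-use % units, grid step 1, at least 10 points per window) smoothed
  with degree-1 loess, span 0.75; sparse grid points are omitted and
  logged. Smoothed curves are rearranged pointwise (cumulative maximum
  across percentile levels) so the 10th–90th curves never cross.
- Reproducibility: every Monte Carlo stage draws from a substream seeded
  by hashing the global seed with identifying keys (site, date, analyte,
  stage), so re-running a configuration reproduces outputs byte-for-byte
  and adding records never perturbs unrelated draws. Outputs carry no
  timestamps.
- Degenerate inputs: zero-variance predictors are excluded with a warning;
  a constant particulate ratio returns slope exactly 0; a point-mass
  organic-share distribution collapses the bootstrap IQR to an exact
  value; empty TP bins warn and are omitted.

Two small systematic effects of the imputation stage are documented here
because they are properties of the method, not defects of the code. First,
Uniform(0, limit) substitution slightly inflates imputed concentrations at
sites whose true values sit far below the reporting limit (low-nutrient,
forested watersheds), which nudges recovered forest effects upward; on the
default synthetic conditions the forest-effect recovery error is about
+0.10 (DIN) and +0.14 (PN) in log10 units, within the +/-0.15 band the
recovery tests use. Second, records whose imputed DIN exceeds TN lose
their particulate value; this selection removes low-PN records
preferentially and shifts the recovered global 1/H by roughly +0.01 on
the defaults (seed-to-seed sd about 0.01), so the recovery test asserts
the mean over a fixed seed panel within +/-0.02 rather than a per-seed
band.

## Problem sizes

The package's test and example runs use a 200-site x 20-observation
spatial panel (4,000 records, 1,000 bootstrap draws per record) and a
13-site x 150-observation temporal panel for the per-site fits; estimator
checks use 100-200 replicate fits at the relevant sample sizes. These
sizes were chosen so the full suite completes in minutes on a single CPU
while leaving seed-level noise well below the tolerances being asserted.
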