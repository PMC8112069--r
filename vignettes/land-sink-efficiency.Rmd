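---
title: "Land carbon sink efficiency: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land carbon sink efficiency: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinkeff)
```

## The quantity and the question

The terrestrial biosphere removes a sizeable share of anthropogenic CO2
emissions. `sinkeff` tracks the *instantaneous land carbon sink
efficiency*

$$E(t) = \frac{B(t)}{F(t) + L(t)},$$

the ratio of the natural land sink $B$ (uptake-positive, Pg C yr$^{-1}$)
to total anthropogenic emissions — fossil fuel and industry $F$ plus net
land-use and land-cover change emissions $L$ (both emission-positive).
$E = 1$ marks a carbon-neutral region whose natural uptake offsets all
its emissions; global values sit near 0.3. Sign conventions are fixed per
flux kind and enforced when a `flux_series` is constructed, so no caller
can silently mix them.

Two derived identities do the bookkeeping:

* atmospheric inversions constrain the *net* land sink $B_L = B - L$, so
  $B = B_L + L$ (`b_from_bl()`), with the land-use flux taken from a
  bookkeeping product;
* a budget-residual sink closes the global carbon budget,
  $B = F + L - G_{atm} - O$ (`residual_land_sink()`), with $G_{atm}$ the
  atmospheric growth and $O$ the ocean sink.

Because different inversions fix different fossil priors, their net land
sinks are harmonized to a common fossil series before comparison:
$B_L^{adj} = B_L + (F_{common} - F_{prior})$ (`adjust_fossil_prior()`).
This conserves the atmospherically constrained combination
$F - B_L$ exactly — the contract the tests check at the bit level on
exactly representable inputs.

## Pipeline

1. **Smoothing.** Interannual variability is large, so a centered 5-yr
   moving average is applied to each flux before the ratio is formed
   (`moving_average()`, `sink_efficiency(window = 5)`). Only full windows
   are used: 1957–2018 inputs yield a 1959–2016 analysis axis. Whether
   one smooths the fluxes and then takes the ratio, or smooths the annual
   ratio, is genuinely open; the flux-first order is the default and the
   other is available via `smooth = "efficiency"` for sensitivity runs.
   Windows of 3 and 1 reproduce the coarser sensitivity variants.
2. **Trends.** A pre-volcanic linear trend (default window 1959–1988) is
   fitted by OLS with a two-sided $t$-test (`fit_linear()`). The
   volcanic years 1991–1993 (a stratospheric-aerosol-driven sink pulse)
   are never special-cased in computation — they are simply outside both
   fit windows.
3. **Breakpoint.** On the post-volcanic window (default smoothed years
   1996–2016) a continuous one-breakpoint segmented regression
   $y = \beta_0 + \beta_1 t + \beta_2 (t - \psi)_+$ is fitted
   (`fit_segmented()`); $s_1 = \beta_1$, $s_2 = \beta_1 + \beta_2$.
4. **Attribution.** Each region (or pair of regions) is removed, the
   global efficiency is rebuilt strictly as the sum of the retained
   regions, the segmented model is re-fitted, and the removal's
   contribution is the slope-change ratio
   $$R_{sc} = \left(1 - \frac{s_2' - s_1'}{s_2 - s_1}\right)\times 100\%$$
   (`slope_change_ratio()`, `leave_one_out()`, `leave_pairs_out()`).
   Positive $R_{sc}$: the removed region strengthened the reversal.
5. **Uncertainty.** A Monte Carlo envelope for $E$ (`mc_efficiency()`)
   and the comparison against interannual variability
   (`compare_uncertainty_to_iav()`).

`run_full_analysis()` executes all stages from a single `run_config()`
and returns (and optionally writes) the report bundle. All thresholds
live in the config: $\alpha = 0.01$ for the global breakpoint,
$\alpha = 0.1$ for removal experiments.

## Breakpoint estimation and inference

**Estimator.** $\psi$ is estimated by profiling the residual sum of
squares over a fine grid of candidate breakpoints (default step 0.01 yr)
spanning the years that leave at least `min_seg = 3` points in each
segment; ties break toward the smallest $\psi$. For fixed $\psi$ the
model is linear, so the profile is computed in closed form for all
candidates at once. The pure-grid profile is the default because it is
exactly reproducible and equals an exhaustive grid search by
construction; `refine = TRUE` additionally polishes the optimum by
continuous search within one grid step. If the best segmented fit does
not improve on the single straight line (relative gain below
`flat_tol`), the fit carries a `no_breakpoint` flag instead of
manufacturing a kink.

**Significance.** The slope-change test is a seeded parametric bootstrap
of the scale-free statistic
$(SSE_{line} - SSE_{seg})/SSE_{seg}$: null series are the fitted H0 line
plus Gaussian noise at the H0 residual scale, and the breakpoint search
is re-run on every draw. Because the statistic is invariant to location,
trend and scale, the p-value is exactly calibrated for white-noise
inputs (the type-I test in the suite verifies the rejection rate at
$\alpha = 0.1$ sits inside the binomial band). A closed-form Davies-type
upper bound on the maximal slope-change $t$-statistic is available as
`method = "davies"`.

A caveat stated rather than hidden: a 5-yr moving average leaves
autocorrelated residuals, so on *smoothed* series the white-noise null
is anti-conservative. The reference analysis works on smoothed series
directly, and this package mirrors that by default;
`ar1_correct = TRUE` redraws the null with AR(1) noise at the estimated
lag-1 residual autocorrelation for users who want the corrected variant.

**Confidence interval.** Default is a seeded parametric bootstrap from
the fitted segmented model (percentile bounds, re-estimated $\psi$ per
draw); the interval always contains the point estimate, and collapses to
the grid resolution on noise-free input. `method = "profile"` instead
inverts the curvature of the SSE profile at the optimum (a delta-method
approximation).

**Attribution mode.** The breakpoint is *re-estimated* on every reduced
series by default (`psi_mode = "free"`), matching the idea that the
remaining regions are re-analysed from scratch; slopes at the fixed
global $\psi$ are available via `psi_mode = "fixed"`. The slope window
always matches the global fit window — no per-removal window selection.

## Monte Carlo uncertainty

Per draw and per year, independently:
$F^* \sim N(F, (0.05 F)^2)$ (the fossil uncertainty is a fixed 5%
relative 1$\sigma$ — the confidence level of that 5% is not specified
upstream, so 1$\sigma$ is the declared reading and the fraction is
configurable), $L^* \sim N(L, \sigma_L^2)$ and
$B_L^* \sim N(B_L, \sigma_{BL}^2)$ with per-year $\sigma$ taken from the
spread (sample SD, $n-1$) of the available products — the package uses
its 4 land-use variants and 7 net-land-sink datasets. Then
$B^* = B_L^* + L^*$ and $E^* = B^*/(F^* + L^*)$; 10,000 draws by
default. Draws are independent across years (no temporal error
correlation is claimed by the inputs), sampling is untruncated normal,
and a draw is resampled only when its denominator is non-positive (the
count is recorded). The MC operates on the smoothed fluxes, mirroring
the efficiency pipeline; interannual variability, by contrast, is judged
on the annual efficiency anomalies after removing the fitted segmented
trend (with the model's residual degrees of freedom).

In the synthetic study conditions the envelope — dominated by the fixed
5% fossil term — *exceeds* the synthetic interannual variability
(ratio ≈ 1.9). That is a property of the scaled-down synthetic world,
whose noise is calibrated to detection robustness rather than to the
much larger variability of real budget residuals; on real data the same
comparison is expected to come out the other way. The ratio is reported
as computed, never forced.

## Climate module

Tropical natural-sink variations are regressed on annual temperature,
precipitation and CO2 concentration (`fit_climate_regression()`, plain
OLS with a collinearity warning via the exact condition number);
"tropics" defaults to Latin America + Africa + Southeast Asia + South
Asia and is configurable, since the regional definition is not
enumerated upstream. Anomalies (not absolutes) are the default reading
for temperature. The predicted sink, pushed through the same smoothing
and segmented fit (`predicted_efficiency_breakpoint()`), checks whether
climate drivers alone reproduce the efficiency reversal. No lag terms
are included. `correlate_index()` gives Pearson correlations against
ENSO/PDO-type indices, and `replace_years()` implements the El Niño
masking sensitivity (e.g. replacing 2015–2016 values by the 2014/2017
mean; target and donor years must be disjoint, which makes the transform
idempotent).

## What the synthetic generator emulates — and what it does not

`generate_panel()` builds an ensemble of regional flux panels with known
truth, at global-carbon-budget scale:

* **Backbones.** Deterministic piecewise-linear region × kind paths
  whose regional pieces sum *exactly* to the global design. Fossil
  emissions rise from ~3.0 Pg C yr$^{-1}$ (1960s mean) to a 2009–2018
  mean of ~9.5, with the growth slowdown after 2009 concentrated in East
  Asia. Land-use emissions stay within 1.0–1.8 Pg C yr$^{-1}$,
  accelerating after 2009 in Africa and East Asia while Latin America's
  decline. The natural sink uses *three* linear pieces — slow rise to
  1994, acceleration 1994–2009, decline after 2009. Two pieces cannot
  simultaneously give the early decreasing efficiency (1959–1988), the
  post-volcanic efficiency rise, and decade-mean sink values at the
  published scale; the mid-1990s acceleration is also what budget
  residuals show.
* **Reversal truth.** The post-2009 sink slope change is carried by
  Latin America (−0.084 Pg C yr$^{-2}$) and Africa (−0.042), with the
  remaining regions approximately offsetting the fossil-slowdown effect
  on the efficiency slope. Consequently every single-region removal
  leaves the global breakpoint detectable, while removing Latin America
  *and* Africa together leaves a near-zero remainder slope change — the
  configuration in which a pair removal can erase the breakpoint.
* **Variability.** AR(1) noise (coefficient 0.3) on all fluxes;
  multiplicative for fossil emissions (which stay non-negative). A
  volcanic sink pulse of 2 Pg C yr$^{-1}$ over 1991–1993 split by
  regional sink share. An ENSO-like AR(1) index with a post-2009 upward
  trend and 2015–2016 warm spikes, coupled negatively into the tropical
  sink; temperature and precipitation covariates load on the index and
  CO2 follows a smooth quadratic rise. Seven dataset variants share the
  fossil series (as real inversions do) and differ by mean-zero AR(1)
  perturbations of the net land sink; four global land-use variants form
  the spread used by the Monte Carlo.
* **Noise scale.** Marginal SDs (sink 0.05, dataset spread 0.06
  Pg C yr$^{-1}$ global-equivalent, allocated across regions by
  $\sqrt{\text{share}}$) were fixed by a design study so that the
  between-dataset breakpoint spread is ~0.8 yr (datasets landing in
  2008–2010) and every dataset detects the break at $p \le 0.01$ — the
  robustness the method is designed around.

What passing tests on this world do **not** show: real budget residuals
have far larger interannual variability and structured (non-AR(1),
cross-regionally correlated) errors; real land-use products disagree
systematically, not by mean-zero perturbations; and transport-model
biases have no synthetic counterpart. The generator validates the
estimators and the plumbing, not the climate science of any particular
product.

## Numerical choices and degenerate inputs

* Breakpoint candidates: closed interval between the `min_seg`-th year
  from each end, step 0.01 yr; ties to the smallest $\psi$.
* Exactly linear input: `no_breakpoint = TRUE`, slope change ~0; its
  CI is refused (the breakpoint is unidentified) rather than invented.
* Efficiency denominator guard: $F + L \le 0.1$ Pg C yr$^{-1}$ (config)
  is an error naming the year — regional series with near-zero emissions
  must fail loudly, not produce infinite efficiencies. Global series
  never approach the guard.
* Strict year alignment everywhere; callers pre-trim (no interpolation).
* Monte Carlo denominator guard $10^{-6}$ with per-cell resampling.
* All stochastic steps (bootstrap p, bootstrap CI, Monte Carlo,
  generator) take explicit seeds; the pipeline derives per-stage
  sub-seeds from one base seed, so a report reproduces byte for byte.

## Problem sizes used by the test suite

The suite validates the estimators at the study's native scale
(21-point smoothed windows, 11 regions, 7 datasets, 62-yr panels) with
replicate counts chosen for stable Monte Carlo assertions: 200 series
for breakpoint recovery, 500 seeds for type-I calibration and
regression-CI coverage, 100 seeds for the end-to-end attribution
ranking, 15 seeds (with 199 bootstrap draws each) for the pair-removal
scan, and 10,000 Monte Carlo draws for the envelope checks.

## Known limitations

* One breakpoint only; no LOESS/spline trend alternatives.
* The default significance test inherits the smoothing-induced
  anti-conservativeness discussed above.
* The bootstrap CI for $\psi$ is percentile-based; no studentization.
* No error covariance across years or datasets in the Monte Carlo.
* Attribution is removal-based ($R_{sc}$ is deliberately not additive
  across regions); no Shapley-style decomposition.
* File-level netCDF ingestion is not included; gridded input enters
  through in-memory arrays via `gridded_flux()`.
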