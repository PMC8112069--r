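# sinkeff

Trend and trend-reversal analysis of the **land carbon sink efficiency**

> E(t) = B(t) / (F(t) + L(t))

— the ratio of the natural land carbon sink *B* to total anthropogenic
emissions (fossil fuel *F* plus land-use change *L*), all in Pg C yr⁻¹.
E = 1 means a region's natural uptake offsets its entire emissions; the
global value sits near 0.3 and its decadal trajectory — decline to the
late 1980s, rise after the Pinatubo years, reversal around 2009 — is a
compact indicator of how the land sink is keeping pace with emissions.

The package is written for carbon-cycle analysts working with regional
annual flux tables from atmospheric inversions and global-carbon-budget
products. It provides:

* **flux data model** — sign-convention-enforced annual series
  (`flux_series`), regional panels with GLOBAL always derived as the sum
  of regions (`flux_panel`, `read_flux_table`), harmonization of
  inversion net land sinks to a common fossil prior
  (`adjust_fossil_prior`, conserving F − BL exactly), the budget
  residual sink (`residual_land_sink`), and grid-to-region aggregation
  (`aggregate_grid`);
* **efficiency** — centered moving-window smoothing and the E series
  (`sink_efficiency`, `panel_efficiency`);
* **trend breaks** — OLS trends (`fit_linear`) and continuous
  one-breakpoint segmented regression `y = b0 + b1·t + b2·(t − ψ)₊`
  with fine-grid SSE profiling (`fit_segmented`), seeded bootstrap
  significance (`breakpoint_significance`) and confidence intervals
  (`breakpoint_ci`);
* **attribution** — leave-one-out / leave-two-out removals and the
  slope-change ratio `R_sc = (1 − (s2′−s1′)/(s2−s1)) × 100%`
  (`leave_one_out`, `leave_pairs_out`, `slope_change_ratio`);
* **uncertainty** — dataset-spread sigmas (`flux_spread`) and Monte
  Carlo propagation to E (`mc_efficiency`,
  `compare_uncertainty_to_iav`);
* **climate** — tropical sink regression on T/P/CO₂
  (`fit_climate_regression`, `predicted_efficiency_breakpoint`), index
  correlations (`correlate_index`) and El Niño masking
  (`replace_years`);
* **synthetic data** — a seeded multi-dataset panel generator with known
  truth (`synthetic_config`, `generate_panel`,
  `generate_two_segment_series`) so every stage is testable offline;
* **pipeline** — `run_config()` + `run_full_analysis()` produce the full
  report bundle (efficiency series, trends, breakpoints with CI,
  attribution tables, Monte Carlo envelope) and write it as CSV/JSON.
  A thin CLI wrapper lives at `inst/scripts/sinkeff.R`
  (`simulate` / `report` subcommands).

## Worked example

```r
library(sinkeff)

sim <- generate_panel(synthetic_config(), seed = 7)   # 7 datasets, 11 regions
p   <- sim$panels[[1]]

e  <- panel_efficiency(p, window = 5)                 # smoothed global E
ft <- fit_segmented(e, window = c(1996, 2016))
ft$p_value <- breakpoint_significance(ft, n_boot = 199, seed = 1)
ft$ci95    <- breakpoint_ci(ft, n_boot = 199, seed = 2)
ft
#> <breakpoint_fit> 1996-2016 (n=21): psi = 2007.66, s1 = 0.005365, s2 = -0.004984 per yr
#>   p = 0.005, 95% CI [2007.18, 2008.28]

loo <- leave_one_out(p, n_boot = 199, seed = 3)
head(loo[order(-loo$r_sc_percent), c("removed", "r_sc_percent", "p_prime", "detectable")], 3)
#>         removed r_sc_percent p_prime detectable
#> 1 Latin America   56.2864045   0.005       TRUE
#> 5        Africa   34.5320565   0.005       TRUE
#> 8       Oceania   -0.5899048   0.005       TRUE
```

The fit says: smoothed efficiency rose at ~+0.005 yr⁻¹ before a
breakpoint at ψ ≈ 2007.7 and fell at ~−0.005 yr⁻¹ after it, a slope
change that survives the bootstrap test at p ≈ 0.005. The attribution
table ranks Latin America first (R_sc ≈ 56%: removing it cancels over
half the global slope change), matching the generator's built-in truth
(`sim$truth$reversal_region`); the breakpoint stays detectable after
every single-region removal.

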