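# microhet

Analysis of nongenetic growth-rate heterogeneity in clonal yeast microcolony
populations.

Isogenic budding-yeast populations grown in a constant environment still
contain a substantial fraction of slowly growing cells. Part of that slow
tail is a genetic confounder — *petite* (respiration-deficient) variants with
low mitochondrial membrane potential — and part is a nongenetic, bet-hedging
state: slow-growing cells with high stress-protein expression (e.g. Tsl1),
elevated Msn2 nuclear occupancy, and strongly increased survival of acute
heat stress. `microhet` implements the quantitative pipeline for separating
and characterising these subpopulations from time-lapse microscopy
measurements, together with a seeded synthetic-data generator that reproduces
the statistical structure of such experiments so the entire pipeline is
testable without imaging data.

## What it computes

* **Growth rates.** Each microcolony's area series (hourly, ~10 h) is fitted
  by log-linear least squares over every contiguous window of at least
  `min_points` time points; the window maximising R² wins (ties go to longer,
  then earlier windows), which absorbs an initial lag phase. Rates are in
  h⁻¹.
* **Medcouple skewness.** The medcouple is the median of the kernel
  h(xᵢ, xⱼ) = ((xⱼ − m) − (m − xᵢ)) / (xⱼ − xᵢ) over pairs straddling the
  sample median m. It is robust, lies in [−1, 1], and is location- and
  scale-invariant; negative values mean a heavier slow tail. Two samples are
  compared with a Z-test using bootstrap standard errors. A compiled fast
  path is bit-identical to the pure-R reference enumeration.
* **Petite exclusion.** The medcouple of retained growth rates is scanned
  over a grid of MitoTracker intensity thresholds; the loess-smoothed curve
  rises (petites removed), plateaus (between the intensity modes), and rises
  again (slow non-petites removed). The threshold is the plateau midpoint,
  e.g. plateau (0.01360, 0.01695) → threshold 0.015275.
* **Petite contamination.** From the fraction *b* of the population below
  the threshold and the fraction *a* of reference rho⁰ petites above it, the
  total petite frequency is p = b/(1 − a) and the contamination of the
  retained set is (p·a)/(1 − b). With the published fractions b = 12.45%,
  a = 21.79% this gives 15.92% and 3.96%. A spike-in simulation quantifies
  the worst-case scenario.
* **Reporter expression vs growth.** Two-stage background correction,
  penalized cubic-spline (GAM) smoothing of intensity on growth rate,
  partitioning-around-medoids clustering of the joint distribution,
  quantile–quantile regression against a control over the 10–25% window,
  and FACS-style top-intensity bin gating.
* **Msn2 nuclear occupancy.** Per-minute nuclear/cytoplasmic median ratios;
  the total nuclear occupancy of a cell is the average excess of the ratio
  over a baseline set by the mean of its four lowest values, regressed
  against microcolony growth rate.
* **Acute heat-shock survival.** Pre/post colony linkage across a global
  stage shift (displacement-histogram mode, then mutual nearest neighbours,
  then median refinement), the inclusive two-fold area-increase survival
  call, logistic regression of survival on growth rate or reporter
  intensity, bulk survival rates, arcsine-ANOVA with Tukey HSD, and nested
  mixed-model likelihood-ratio tests.

## Worked example

```r
library(microhet)

cfg <- run_config(sim = sim_config(n_colonies = 1500, seed = 4),
                  seed = 42, n_msn2_cells = 120)
run <- run_pipeline(cfg)
print(run)
```

```
# microhet run report

Colonies fitted: 1500
Selected MitoTracker threshold: 0.0163965
Excluded below threshold: 250 of 1492 (16.76%)
Estimated total petite frequency 16.89%; after-threshold contamination 0.161%
Occupancy-growth slope -0.111 [-0.1261, -0.0958]
Survival logistic: intercept 3.854, slope -9.525 over 1492 matched pairs
```

Reading the report: 1500 colonies were simulated with a true petite fraction
of 16% and fitted (8 colonies were flagged rather than fitted and are
excluded from gating). The scan-selected MitoTracker threshold removed
16.76% of colonies, and the contamination model estimates a 16.89% total
petite frequency — close to the simulated truth of 16% — with well under 1%
residual petite contamination above the threshold. Msn2 occupancy predicts
slower growth (negative slope, CI excluding zero), and survival of the
simulated heat shock falls steeply with growth rate (logistic slope −9.5
against a generative value of −10).

Individual stages are ordinary functions on data frames and compose with the
pipe: `simulate_population() |> fit_population() |> threshold_scan() |>
loess_smooth() |> detect_plateau() |> select_threshold()`. Result objects
have `tidy()`, `glance()` and `autoplot()` methods.

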