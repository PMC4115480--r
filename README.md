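# frapkin

Quantification and comparison of chromatin-binding kinetics from live-cell
FRAP (fluorescence recovery after photobleaching) experiments on GFP-fusion
proteins — the assay used to measure how tightly bromodomain-containing
proteins are anchored to chromatin and whether a small-molecule inhibitor
displaces them.

In a FRAP experiment a circular region of a GFP-positive nucleus is bleached
after a handful of prescans, and the return of fluorescence into the region
is recorded at ~0.25 s per frame. `frapkin` takes the per-cell region-mean
intensity traces — bleached ROI `F(t)_ROI`, whole nucleus `F(t)_total` and an
extracellular background `F(t)_BG` — and computes, per cell:

1. **Normalization with acquisition-photobleach correction** (double
   normalization in the style of Phair):

   `F_norm(t) = [(F_ROI(t) − F_BG(t)) / (F_total(t) − F_BG(t))] × [(F̄ⁱ_total − F̄ⁱ_BG) / (F̄ⁱ_ROI − F̄ⁱ_BG)]`

   where `F̄ⁱ` are the prebleach means. The ratio to the whole-nucleus signal
   cancels fluorophore loss caused by the imaging laser itself.

2. **Double-exponential association fit** (constrained least squares):

   `y(x) = y0 + A1·(1 − e^(−x/t1)) + A2·(1 − e^(−x/t2))`,  A1, A2 ≥ 0, t1, t2 > 0.

3. **Half-time of recovery** `t½`: the unique time at which `y` reaches
   `y½ = y0 + (A1 + A2)/2`, located by iterative bisection (tolerance 1e-6 s).
   Slower `t½` means tighter chromatin binding.

4. **QC filtering**: cells with fitted plateau > 1.1 or adjusted R² < 0.95
   are excluded as imaging artifacts (focal drift, cell movement, debris).

At the group level: iterative two-sided **Grubbs outlier elimination**
(α = 0.05) before group means ± SEM, one-way **ANOVA with Tukey–Kramer**
multiple comparisons (significance at P < 0.05), and a
**percent-of-control selectivity profile** (each group's mean `t½` relative
to its own wild-type, inhibitor-free control).

Because raw live-cell data of this kind are rarely shareable, the package
also ships a seeded **synthetic-data generator** — at the curve level
(three-channel traces with acquisition bleaching, bleach-event depth,
additive noise, lognormal cell-to-cell kinetic scatter) and at the image
level (TIFF time-lapse stacks with disc/nucleus/background ROI definitions)
— with exact per-cell ground truth, so every stage of the pipeline is
verifiable end to end.

## Worked example

Simulate a wild-type group (calibrated to `t½` = 6.3 s) and an
inhibitor-treated group (calibrated to 2.8 s), quantify every cell and
compare the groups:

```r
library(frapkin)

wt  <- simulate_traces(frap_sim_spec(n_cells = 12,
         kinetics = calibrate_kinetics(6.3), duration_s = 50, seed = 101))
jq1 <- simulate_traces(frap_sim_spec(n_cells = 12,
         kinetics = calibrate_kinetics(2.8), duration_s = 50, seed = 202))

cells <- dplyr::bind_rows(
  dplyr::mutate(quantify_cells(wt),  group = "wt"),
  dplyr::mutate(quantify_cells(jq1), group = "wt + JQ1"))

passed <- dplyr::filter(cells, qc_pass)
summarize_groups(passed)
#> # A tibble: 2 × 6
#>   group    n_before n_after mean_s sem_s removed
#>   <chr>       <int>   <int>  <dbl> <dbl> <list>
#> 1 wt             11      11   6.46 0.402 <dbl [0]>
#> 2 wt + JQ1       12      12   2.80 0.184 <dbl [0]>

anova_tukey(passed)
#> <frap_anova> k = 2 groups, F(1, 21) = 72.34, p = 3.044e-08
#> # A tibble: 1 × 6
#>   group_a group_b  diff_s     q        p_adj significant
#>   <chr>   <chr>     <dbl> <dbl>        <dbl> <lgl>
#> 1 wt      wt + JQ1   3.66  12.0 0.0000000304 TRUE
```

One wild-type cell was excluded by QC (`n_before` counts QC-passed cells
entering outlier elimination); the recovered group means sit on the
simulated truth (6.3 s and 2.8 s), and the treated group recovers
significantly faster — the inhibitor-displacement readout.

Fitted objects follow broom conventions (`tidy()`, `glance()`,
`autoplot()`); `plot_recovery_curves()`, `plot_thalf_bars()` and
`plot_selectivity()` reproduce the standard presentation. A whole study
(simulation → quantification → statistics → report) runs from one YAML
config via `run_frap_pipeline()`, or from a shell through the thin wrapper
`inst/scripts/frap_pipeline.R`.

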