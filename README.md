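# excitokit

Quantification of glutamate excitotoxicity endpoints in primary neuronal
cultures, for researchers analyzing live-cell imaging, plate respirometry
and viability assays of excitotoxic injury and its modulation (e.g. by
bacterial lipopolysaccharide).

Toxic glutamate exposure drives a biphasic cytosolic Ca²⁺ response: a fast
first phase, then — after a cell-specific lag — delayed calcium
deregulation (DCD), a sustained secondary rise synchronized with collapse
of the mitochondrial potential (ΔΨm) and predictive of cell death. The
package starts from extracted per-cell fluorescence traces (F340/F380
ratios, Rh123/SBFI/DiBAC F/F0), well × cycle oxygen-consumption tables and
endpoint count/kinetics tables, and computes:

* **DCD endpoints** — classification of the secondary rise, lag-DCD by
  tangent intersection (lag = time from glutamate addition to the
  intersection of least-squares tangents to the first-phase plateau and
  the steepest segment of the secondary rise), post-washout recovery index
  `X = 100 (R_off − R_end)/(R_off − R_base)` capped at 100%, and
  sister-culture normalization (control median ≡ 1).
* **ΔΨm endpoints** — Rh123 post-washout recovery slope and the
  FCCP/post-glutamate above-baseline AUC ratio.
* **Respirometry** — blank-well correction, NOCR, basal and maximal
  respiration, spare respiratory capacity (maximal = basal + SRC exactly),
  per-agent acute responses, and both basal-respiration and
  pre-injection-OCR normalizations.
* **Viability and morphometry** — live/dead (Syto-13/EthD-1) survival
  index, kinetic MTT initial rate (10-min slope of background-corrected
  absorbance), percent soma-area change and the spherical area→volume
  conversion `v = a^(3/2)`.
* **Statistics** — a distribution-gated ladder (D'Agostino–Pearson
  normality gate, then Mann–Whitney / Welch t / Kruskal–Wallis + Dunn /
  one-way ANOVA + Šidák / two-way RM ANOVA + Dunnett) with a full audit
  trail of every branch decision.
* **Synthetic cohorts** — seeded generators for calcium/Rh123/ion traces,
  flux plates and endpoint tables that ship ground truth for every
  estimated quantity, with calibrated `cortical` (median lag 180 s) and
  `cerebellar` (530 s) presets.

## Worked example

```r
library(excitokit)

p   <- preset_cohort_params("cortical", seed = 1)   # 288 cells
coh <- gen_calcium_cohort(p)
res <- analyze_dcd_cohort(coh)
summarize_cohort(res)
#> # A tibble: 1 x 11
#>       n n_dcd dcd_fraction lag_median lag_q1 lag_q3 recovery_median
#>   <int> <int>        <dbl>      <dbl>  <dbl>  <dbl>           <dbl>
#> 1   288   248        0.861       171.   125.   281.            90.8
#> # i 4 more variables: recovery_q1 <dbl>, recovery_q3 <dbl>,
#> #   n_recovery_excluded <int>, n_lag_missing <int>
```

248 of 288 cells developed DCD; the cohort median lag is 171 s (the
preset's calibrated median is 180 s, recovered here within sampling
noise), and the median cell recovered ~91% of its Ca²⁺ elevation within
the washout horizon. The same cohort couples to Rh123 traces and the
mitochondrial metrics:

```r
mito <- gen_mito_cohort(coh, p)
head(analyze_mito_cohort(mito), 3)
#> # A tibble: 3 x 7
#>   cell_id    slope slope_rmse auc_postglu auc_fccp auc_ratio auc_defined
#>   <chr>      <dbl>      <dbl>       <dbl>    <dbl>     <dbl> <lgl>
#> 1 cell001 -0.00133     0.0539        279.     45.1     0.162 TRUE
#> 2 cell002 -0.00133     0.0541        278.     44.7     0.161 TRUE
#> 3 cell003 -0.00133     0.0524        278.     44.1     0.158 TRUE
```

The end-to-end pipeline simulates a control and an LPS-treated sister
cohort, analyzes both, and writes per-cell CSVs plus a JSON report with
exclusion counts and the statistics audit trail:

```r
run_cohort_pipeline("cortical", seed = 1, out_dir = "out",
                    lps_recovery_factor = 0.7)
```

A thin CLI over the same functions lives at
`inst/scripts/excitokit-cli.R` (subcommands `simulate`, `dcd`, `mito`,
`report`).

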