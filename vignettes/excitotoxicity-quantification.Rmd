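---
title: "Quantifying glutamate excitotoxicity endpoints with excitokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glutamate excitotoxicity endpoints with excitokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excitokit)
```

## The experimental system

Prolonged exposure of cultured neurons to toxic glutamate concentrations
produces a biphasic rise of cytosolic Ca²⁺: a fast first phase that settles
into a plateau, followed in most cells — after a cell-specific lag — by a
second, sustained rise called delayed calcium deregulation (DCD). DCD is
synchronized with a collapse of the mitochondrial membrane potential (ΔΨm,
monitored as a rise of Rh123 F/F0) and predicts subsequent death of the
cell. After glutamate washout, surviving cells pump Ca²⁺ (and, more
slowly, Na⁺) back out; agents such as bacterial lipopolysaccharide (LPS)
slow this recovery without changing resting Ca²⁺.

`excitokit` quantifies this system from extracted per-cell traces and
plate/endpoint tables: it does not segment images or control hardware. Its
estimators are exercised against a synthetic cohort generator that ships
ground truth for every quantity it later estimates.

## The lag-DCD estimator

The onset of DCD is defined geometrically: the intersection of two
least-squares tangents, one to the first-phase plateau and one to the
steepest segment of the secondary rise; the lag is the time from glutamate
addition to that intersection.

Two numerical points matter in practice.

* **The plateau trend must not be extrapolated from a short window.** The
  secondary rise is detected where the smoothed signal exceeds the plateau
  trend by `threshold_k` (default 5) robust SDs, with a floor of
  `min_rise_frac` (default 10%) of the first-phase amplitude. A trend line
  fitted only on a short post-settling reference window has a slope
  standard error that, extrapolated over several hundred seconds, dwarfs
  the detection threshold. `classify_dcd()` therefore refines the
  detection iteratively: a provisional rise start from the reference-window
  fit, then a robust Theil–Sen refit of the plateau over everything before
  that rise (robust, because a fraction of those samples may already sit on
  the ramp), then re-detection. Two passes are enough in practice.
* **A tangent, not a chord.** The secondary tangent is fitted over the
  contiguous `secondary_window_s` (default 30 s) with maximal slope. The
  window must be narrow relative to the rise time of the secondary phase:
  a wide window fits a chord through the sigmoid, which is systematically
  shallower than the tangent and biases the intersection early. With the
  default window the estimator is exact on piecewise-linear traces (the
  two segments *are* the tangents, and the analytic 2×2 solve is the test
  oracle) and shows a residual bias below one sample interval on logistic
  ramps.

Ties at the detection threshold are negative by a strict inequality, and
near-parallel tangents raise a degenerate-geometry error rather than
returning an arbitrary intersection. Intersections outside the glutamate
window are clamped and flagged.

## Recovery index

The post-washout recovery index is a reconstruction (the figure it mirrors
does not print a formula):

\[ X = 100\,\frac{R_\mathrm{off} - R_\mathrm{end}}{R_\mathrm{off} - R_\mathrm{base}} \]

with \(R_\mathrm{base}\) the pre-glutamate baseline mean,
\(R_\mathrm{off}\) the signal at washout and \(R_\mathrm{end}\) the signal
at a fixed horizon (default: the last sample before FCCP). 100% is full
return to baseline; the reported value is capped at 100. Cells with no
elevation at washout have an undefined index and are excluded, with
exclusion counts always carried into cohort summaries. The index is
invariant under affine rescaling of the trace.

## Rh123 metrics

ΔΨm recovery is summarized two ways: the least-squares slope of F/F0 over
the washout window (negative slope = recovery), and the ratio of the
above-baseline area under the curve during FCCP application to the AUC of
the post-glutamate period. The AUC baseline defaults to F/F0 = 1 — the
pre-stimulus normalization level — because no explicit baseline is stated
for the shaded-area quantification; it is a configurable argument.
Windows derive from the event schedule: post-glutamate `[glu_off,
fccp_on)`, FCCP `[fccp_on, iono_on)`. A small ratio means little probe was
left to release at FCCP — sustained depolarization or probe loss; the
module reports the numbers and leaves that interpretation to the user.

## Flux metrics

From a blank-corrected plate (per-cycle mean of the cell-free blank wells
subtracted from every sample well, removing shared instrument drift):
NOCR is the minimum OCR after the antimycin A/rotenone injection; basal
respiration is mean pre-injection OCR minus NOCR ("before application of
the first agent" is read as the mean of *all* pre-injection cycles, for
robustness over a single cycle); maximal respiration is the FCCP-segment
maximum minus NOCR; spare respiratory capacity is maximal − basal, an
identity that holds to floating tolerance on every plate. The acute
response to an agent is the extremum of its segment (the direction with
the larger absolute deviation) minus the last pre-injection value.

Two normalization conventions appear in this assay's practice — dividing
by basal *respiration* (NOCR-subtracted, mapping basal to 1) or by the raw
pre-injection OCR — and they are not identical. Both modes are
implemented; `basal_respiration` is the default because it reproduces the
basal ≈ 1 convention of the usual summary plots, and the mode used is
recorded in the output.

## Viability and morphometry

The survival index is the live/dead ratio (Syto-13⁺/EthD-1⁻ over EthD-1⁺)
normalized to the same ratio in control cultures; conditions with zero
dead cells are reported as undefined, never imputed. The MTT metric is the
initial rate: the least-squares slope of background-corrected absorbance
over the first 10 minutes, which reflects neuronal dehydrogenases better
than endpoint formazan accumulation (dominated by slower glial reduction).
The background wavelength is a metadata field rather than a constant
because the source protocols themselves disagree (620 vs 650 nm); the
package records it and takes no side.

Soma swelling is quantified from contour pixel counts as percent area
change (units cancel) and converted to volume folds under the spherical
assumption, \(v = a^{3/2}\). Cohort area changes aggregate per-experiment
means first and report mean ± SEM across experiments, matching the
experiment-level framing of such data; per-cell aggregation is available
because the pooling unit for the rank tests is genuinely ambiguous.

## The statistics ladder

Each group passes through a D'Agostino–Pearson omnibus normality gate
(α = 0.05 per group; any failure, or any group below n = 8 where the test
is undefined, routes to the nonparametric branch — the n-threshold itself
is a package decision, since none is stated in the conventions being
mirrored). Branches: Mann–Whitney (2 groups, non-normal), Welch's t
(2 groups, normal — a gap-fill: the mirrored convention never names a
parametric 2-group test), Kruskal–Wallis + Dunn with Bonferroni-adjusted
pairwise z (k groups, non-normal), one-way ANOVA + pooled pairwise t with
Šidák adjustment (k groups, normal), and two-way repeated-measures ANOVA
with Dunnett contrasts against control for time × group designs. The
D'Agostino–Pearson K² and Dunn's test are implemented in-package from the
published formulas (no installed package provides them) and are validated
against independent references in the test suite. Every branch decision is
logged in an audit trail that travels with the result. Summaries follow
the reporting convention: median and linear-interpolation quartiles
(Tukey box-plot convention) for nonparametric data, mean ± SD/SEM
otherwise.

## The synthetic cohort generator

The generator emulates the *statistical structure* of the experiments, not
their biophysics (no NMDAR flux, uniporter or ATP dynamics):

* Per-cell DCD status is Bernoulli(`p_dcd`). Lags are log-normal — the
  right-skewed shape such lag distributions show — parameterized by the
  observed median and a log-SD calibrated from the printed interquartile
  ranges (0.85 cortical, 0.71 cerebellar).
* **Lags are truncated to the observable window** (from the first-phase
  settling time to the glutamate window minus the tangent-fit margin), and
  the parent location is solved numerically so the *truncated* median
  equals the preset median. The published medians are medians of lags
  observed within a finite exposure; an untruncated log-normal with the
  cerebellar median and IQR-implied shape would put roughly a quarter of
  its mass beyond the window, biasing the observed median ~19% low. One
  consequence: the generated IQR is narrower than the published one; the
  median is the calibrated quantity.
* The secondary rise is a logistic ramp (steepness default 10 s) whose
  midpoint sits `2 × steepness` after the drawn onset, so the
  tangent-intersection definition of the onset equals the drawn lag by
  construction — the generator and the estimator agree on what "onset"
  means without sharing code.
* Washout recovery is a single exponential toward baseline; LPS acts as a
  multiplicative factor ≤ 1 on the rate (and on the ΔΨm recovery rate).
  No kinetic model is claimed by the source material; this is the simplest
  monotone-recovery model.
* Rh123 traces rise with each cell's DCD onset and decay after washout;
  at FCCP the remaining-polarization-scaled release is added and the
  signal thereafter decays as probe leak, *replacing* the washout decay.
  With an additive pulse instead, slow-recovery cohorts would carry a
  larger residual term through the FCCP window and the AUC ratio would not
  decrease monotonically with the recovery factor — physically, FCCP has
  collapsed the potential, so "recovery" dynamics no longer apply.
* Noise is additive Gaussian, default 2% of the first-phase amplitude.
  Lag and recovery are left independent within a cell (no within-cell
  correlation is reported to calibrate against).
* Flux plates: per-well basal OCR uniform on 100–200 pmol O₂/min, 3/2/3
  min mix/wait/measure cycles (metadata; metrics use measurement values),
  4 cell-free blank wells of 24 carrying only shared drift and noise,
  FCCP segment at 2.1 × basal respiration, non-mitochondrial fraction 0.1,
  acute glutamate response 1.7 × pre-injection OCR decaying back over the
  segment. Ground truth satisfies maximal = basal + SRC exactly.
* Endpoints: live/dead counts are binomial draws (600 cells/condition)
  with survival probabilities 0.900/0.883/0.863/0.860, chosen so the
  implied live/dead odds ratios are 1.00, 0.84, 0.70 and 0.68; MTT
  kinetics are linear for 10 min then saturate, so the initial-rate
  estimator is exact on noiseless input; soma areas get mean-unbiased
  multiplicative per-experiment folds (defaults 1.427 for glutamate, 1.22
  with LPS) over 30 experiments of 20 cells.

What passing tests on these cohorts shows — and what they do not: the
estimators recover the generating parameters under Gaussian noise,
monotone single-exponential recovery and clean event timing. Real traces
add photobleaching, focus drift, partial washout, motion and segmentation
artifacts, and multiphasic responses, none of which the generator
emulates; results on real data therefore depend on upstream quality
control that is out of scope here.

## Problem sizes and determinism

Every generator is seeded through its params object and regenerates
bit-identically. The shipped checks use the calibrated preset sizes
(288/298 cells), 1000 piecewise-linear traces for the tangent oracle,
2000 null replicates (n = 30/group) for the type-I error of the 2-group
branch, three 120-cell cohorts for the LPS monotonicity suite, and
24-well plates; these sizes give each stochastic check a comfortably
small standard error relative to its tolerance.

## Worked example

```{r, eval = FALSE}
p   <- preset_cohort_params("cortical", seed = 1)
coh <- gen_calcium_cohort(p)
res <- analyze_dcd_cohort(coh)
summarize_cohort(res)

mito <- gen_mito_cohort(coh, p)
head(analyze_mito_cohort(mito))

run_cohort_pipeline("cortical", seed = 1, out_dir = "out",
                    lps_recovery_factor = 0.7)
```

## Known limitations

* The recovery index formula is a documented reconstruction, not a quoted
  rule; alternatives (e.g. time-constant fits) would need their own
  validation.
* Lag estimation assumes one secondary phase; multi-phase (>2) responses
  are out of scope and will be summarized by their dominant rise.
* The generator's truncated-lag calibration reproduces medians, not full
  IQRs, within a finite exposure window.
* Dunn and Šidák adjustments follow the common-software conventions
  (Bonferroni over all pairs; pooled-SD pairwise t); other conventions
  exist and give slightly different adjusted p-values.
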