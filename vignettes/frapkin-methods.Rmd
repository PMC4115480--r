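---
title: "FRAP quantification with frapkin: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FRAP quantification with frapkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frapkin)
```

## The measurement

Fluorescence recovery after photobleaching (FRAP) probes how fast tagged
molecules exchange between a bleached region and the rest of the nucleus.
For chromatin readers such as bromodomain-containing proteins, the half-time
of recovery t½ is a proxy for chromatin residence: binding-dead point
mutants and displacing inhibitors both shorten t½. A typical protocol takes
five prescans, bleaches a circular spot (area adjusted per target, roughly
2.5–17.6 µm², to keep t½ in the practical 1–30 s range at a ~0.25 s frame
interval), and then records recovery.

Three region-mean traces feed the analysis: the bleached ROI, the whole
nucleus and an extracellular background. frapkin works on these traces as a
long tidy table (`cell_id`, `frame`, `time_s`, `phase`, `f_roi`, `f_total`,
`f_bg`), one row per cell and frame.

## Per-cell model

**Normalization.** `normalize_trace()` computes, per frame,
$$F_{norm}(t) = \frac{F_{ROI}(t) - F_{BG}(t)}{F_{total}(t) - F_{BG}(t)}
  \cdot \frac{\bar F^i_{total} - \bar F^i_{BG}}{\bar F^i_{ROI} - \bar F^i_{BG}},$$
with $\bar F^i$ the prebleach means. Dividing by the whole-nucleus signal
corrects photobleaching caused by the imaging laser itself: any loss that
affects ROI and nucleus proportionally cancels. The construction forces the
mean normalized prebleach level to 1, and makes the output invariant to
detector gain, to common additive offsets, and (at zero background) to any
common per-frame multiplicative decay of the two fluorescent channels. The
decay invariance is exact when the prebleach ROI/total ratio is frame-wise
constant (e.g. noiseless input); with per-frame noise the prebleach means
weight frames slightly differently, so it holds to noise order rather than
machine precision. Time is re-zeroed at the first post-bleach frame;
normalized prebleach values are kept (at negative times) as diagnostics
only and never enter the fit, since the association model describes
recovery, not the prebleach steady state.

**Recovery model.** `fit_recovery()` fits the double-exponential association
$$y(x) = y_0 + A_1(1 - e^{-x/t_1}) + A_2(1 - e^{-x/t_2})$$
by Levenberg–Marquardt least squares. Amplitudes are constrained
non-negative and time constants positive; the original analysis environment
does not document constraints, but constraints guarantee a monotone fitted
curve, which the half-time bisection relies on (an unconstrained fit remains
available via `constrain = FALSE` for sensitivity checks). Two further box
bounds — $t_1, t_2 \le 10\times$ the observed post-bleach span and
$A_1, A_2 \le 2$ — address a genuine non-identifiability: as $t_2 \to \infty$
the slow component degenerates into a linear drift with arbitrary $A_2$,
producing meaningless plateau estimates from noise-level drifts.
Initialization takes $y_0$ from the first post-bleach point, the plateau
from the mean of the final 10% of frames and $(t_1, t_2)$ at one tenth and
one half of the span, with a fixed deterministic ladder of up to five
rescaled restarts; a fit that still fails is reported `converged = FALSE`,
never silently replaced. Parameters are reported in canonical order
$t_1 \le t_2$; when $t_2/t_1 < 1.05$ a near-single-exponential diagnostic is
set (the half-time is insensitive to the split in that regime). Adjusted R²
uses $p = 5$ free parameters: $1 - (1-R^2)(n-1)/(n-p-1)$.

**Half-time.** `half_recovery_time()` solves $y(t) = y_0 + (A_1+A_2)/2$ by
bisection on $[0, \text{hint}]$, doubling the upper end until the level is
crossed, to an absolute tolerance of 1e-6 s. Under the constraints the
model is strictly increasing, so the crossing is unique. t½ is invariant to
scaling all of $(y_0, A_1, A_2)$ by a common factor and 1-homogeneous in
$(t_1, t_2)$ — the latter is what `calibrate_kinetics()` exploits to build
parameter sets with any requested t½ exactly (compute t½ at $t_1 = 1$,
rescale both constants).

**QC.** Cells whose fitted plateau exceeds 1.1 or whose adjusted R² falls
below 0.95 are excluded as imaging artifacts (focal drift pushes apparent
recovery above the prebleach level; movement or debris wrecks the fit).
The inequalities are strict: boundary values pass. Non-converged fits fail
with reason `no_fit`.

## Group-level statistics

Within each treatment group, `grubbs_outliers()` iteratively removes the
single most extreme value while $G = \max|x_i - \bar x|/s$ exceeds the
two-sided critical value $\frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}$,
$t = t_{1-\alpha/(2n),\,n-2}$, at α = 0.05 — the standard iterative
two-sided form; the sidedness, iteration and α are package choices, as the
usual description of the procedure leaves them implicit. No removal happens
below n = 3 or at zero spread. Outlier elimination precedes the group mean,
SEM (sample SD/√n) and all testing.

`anova_tukey()` computes the one-way ANOVA F on the pooled within-group
mean square and, per pair, the Tukey–Kramer statistic
$q_{ij} = |\bar x_i - \bar x_j| / \sqrt{(MSE/2)(1/n_i + 1/n_j)}$ with
adjusted p-values from the studentized-range distribution (`ptukey`) with
$(k, N-k)$ parameters; the Kramer denominator handles unequal group sizes.
Degenerate inputs (MSE = 0) are flagged: unequal means report adjusted
p = 0, equal means report no significance. The implementation is verified
against `TukeyHSD` to 1e-6 in the test suite.

A caveat worth stating plainly: trimming outliers at α = 0.05 *before*
testing slightly inflates the familywise error of the downstream
comparisons. In the package's own null simulations (four groups of ten,
one lognormal t½ distribution, CV 20%), Tukey–Kramer alone rejects in
~4.6% of replicates, but Grubbs-then-Tukey rejects in ~6–8%. This is an
inherent property of the trim-then-test sequence at these group sizes, not
an implementation artifact; users who need strict familywise control should
raise the Grubbs bar or skip trimming.

`selectivity_profile()` expresses each group's mean t½ as a percentage of
the control group's mean (wild-type without inhibitor), scaling the SEM by
the same factor — the control mean is treated as a constant, matching the
usual error-bar convention for such profiles; `propagate_control_error =
TRUE` adds the control's relative variance in quadrature instead.
Significance versus control comes from the Tukey–Kramer pair set.

## The synthetic-data generator

`simulate_traces()` emits three-channel traces under the forward model the
analysis assumes: prebleach frames at the unbleached level, an instantaneous
bleach event between the last prescan and the first post-bleach frame (no
mid-bleach frame is emitted), ROI recovery following the double-exponential
curve of the cell's true kinetics, geometric per-frame acquisition
bleaching applied to both fluorescent channels (not to the non-fluorophore
background), a bleach-event depth multiplying both fluorescent channels,
constant background, and additive Gaussian noise per channel per frame.
The corruption-free normalization of a simulated trace equals the true
curve exactly, which is what makes round-trip tests sharp.

Default study conditions (chosen once, as a realistic protocol, and
documented here because the original data are not deposited): 5 prescans,
0.25 s frame interval, prebleach ROI signal 1000 and whole-nucleus signal
1200 units over a background of 50, bleach-event depth 6% of the nucleus
signal, acquisition bleaching 5×10⁻⁴ per frame (≈11% loss over a 240-frame
series — consistent with an imaging laser attenuated to ~1% of bleach
power), noise SD 20 units (2% of the prebleach ROI signal) per channel,
and 20% lognormal cell-to-cell scatter applied as one shared factor to both
time constants (median 1), so each cell's true t½ scales by the factor and
canonical ordering is preserved; per-cell truth (parameters and analytic
t½) is attached to every simulated data set. Simulation length should scale
with the kinetics: the pipeline default is max(20 s, 8×t½). A fixed long
window for fast kinetics leaves the signal variance of the trace dominated
by flat plateau frames and pushes adjusted R² below the QC bar for reasons
unrelated to fit quality — the experimental protocol equivalently adapts
spot size and acquisition to keep t½ "practical".

Two features of real data the curve-level generator deliberately does not
emulate: channel-specific noise magnitudes (real whole-nucleus and
background means are quieter than the ROI mean because they average more
pixels; the generator applies one SD to all three channels), and
signal-dependent (photon) noise. Both matter at high acquisition-bleach
rates, where the background-subtracted denominator of the normalization
becomes small and the additive-noise ratio grows unstable late in the
series — passing tests on simulated traces therefore do not certify
behaviour on data with very deep acquisition bleaching.

`simulate_image_stack()` renders the same forward model as a single-channel
pixel stack: an elliptical nucleus, a circular bleach disc whose mask area
matches the requested µm² within one pixel, a wide background strip outside
the nucleus, and optional per-pixel additive plus photon-like noise. Pixels
of the disc follow the recovery curve; the surrounding nucleoplasm declines
slightly as the disc recovers (fluorophore conservation — the recovering
molecules come from the surround), so the whole-nucleus mean tracks the
curve-level total channel exactly and the two generators agree to machine
precision without noise. `extract_traces()` reduces a stack and its ROI
masks to the standard three-channel trace. Stacks round-trip through
multi-page 32-bit float TIFF with TSV sidecars (frames, ROI pixel
coordinates, truth). No optics are modelled: no point-spread function, no
diffusion during the bleach, no 3-D.

## Numerical and testing choices

Bisection tolerance 1e-6 s (asserted against an independent two-stage
dense-grid search at 1e-4 s over 1000 random constrained parameter sets);
calibration reproduces targets to better than 1e-4 s; fits are verified
against an independent unconstrained `nls` oracle on noisy data and to
1e-6 relative error on noiseless data. Statistical routines are verified
against explicit critical-value computations (Grubbs) and `TukeyHSD`
(adjusted p, to 1e-6). Null-calibration and selectivity-sensitivity
properties use 1000 and 20 seeded replicates respectively; image/curve
agreement uses three 96×96 stacks — sizes chosen to keep the default
verification run desk-scale while leaving the estimates' Monte-Carlo error
well inside the asserted margins. All simulations are bit-reproducible
under a fixed seed, with per-cell and per-group derived streams so that
adding a cell or group never perturbs existing draws.

## Known limitations

No reaction–diffusion modelling: the double-exponential association is an
empirical description, and its two time constants should not be read as
physical on- and off-rates. Dose–response structure is not modelled
(concentration series are compared as ordinary groups). The Grubbs-then-test
inflation discussed above is inherited from the emulated workflow. The QC
thresholds (plateau 1.1, adjusted R² 0.95) are fixed conventions of the
assay, tunable via `qc_thresholds()` but not data-adaptive.
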