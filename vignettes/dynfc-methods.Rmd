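---
title: "Sliding-window dynamic functional connectivity: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window dynamic functional connectivity: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynfc)
```

## The problem

Resting-state functional MRI yields one BOLD time series per anatomical
region. *Static* functional connectivity (sFC) summarises the coupling of a
region pair as the absolute Pearson correlation over the whole scan.
*Dynamic* functional connectivity (dFC) asks how much that coupling
fluctuates within the scan, which is clinically interesting because network
dynamics — e.g. between the basal ganglia and the default mode network
(DMN) — have been linked to fatigue in multiple sclerosis. `dynfc`
implements this analysis end to end: tapered sliding-window correlation, two
variability statistics, subnetwork summarisation with global normalisation,
a phase-randomization surrogate null, motion quality control, and the
clinical statistics stage (fatigue scoring, normality-gated comparisons,
hierarchical forward regression).

Because the kind of clinical MRI data this targets is not publicly
shareable, the package also ships a first-class synthetic cohort generator.
Every stage is validated on data with known ground truth.

## Windowed connectivity

The scan of $T$ volumes at repetition time $TR$ is divided into overlapping
windows of $L$ volumes advanced by $S$ volumes; the defaults $L = 27$,
$S = 5$ at $TR = 2.2$ s give 59.4-s windows shifted by 11 s, and 35 windows
for a 197-volume scan (the window count is
$\lfloor (T - L)/S \rfloor + 1$). A rectangular window is convolved with a
Gaussian kernel (sd 9 volumes, truncated at $\pm 3$ sd, same-length
convolution, renormalised) to de-emphasise window edges; several readings of
"convolve a rectangle with a Gaussian" are defensible, so the construction
is isolated in `tapered_window_weights()` and pinned down by a brute-force
convolution oracle in the tests. Within each window the *weighted* Pearson
correlation is computed from weighted means and covariances; with uniform
weights it reduces exactly to ordinary Pearson.

Two variability statistics are computed per connection:

* **Summed difference** (`dfc_summed_difference`):
  $\sum_w |r_{w+1} - r_w|$ on *signed* window correlations. Only the
  differences are absolutised; a flag exposes the alternative of
  absolutising the windows first.
* **Coefficient of variation** (`dfc_coefficient_of_variation`):
  $cv = \sigma/\mu$ across windows of the *absolutised* window
  correlations. The standard deviation convention (sample, $W-1$) is a
  documented default; population sd is available. Connections with zero
  mean strength are undefined and excluded from summaries rather than
  imputed.

Global values average the unique off-diagonal pairs. Subnetwork values
average a named pair set — by default all pairs among the union of the
basal ganglia set (bilateral caudate, putamen, pallidum) and the DMN set
(bilateral medial prefrontal cortex, posterior cingulate, precuneus),
because the wording "connectivity between all these selected regions"
includes within-set pairs; a between-sets-only mode exists. Optional
normalisation divides by the subject's global mean to remove
between-subject differences in overall connectivity strength.

Two numerically identical implementations back `windowed_fc()`: a
sliding-sum formulation (fast when windows are many and regions few, as in
surrogate ensembles) and a per-window accumulation (fast for large region
counts). Tests assert their agreement at $10^{-12}$.

## Preprocessing and motion QC

The pipeline starts from denoised series (ICA-based denoising and
registration are out of scope). It applies, in the order a typical protocol
would: discarding the first 5 volumes; nuisance regression of supplied
signals (e.g. white-matter/CSF means) by OLS; high-pass filtering at
0.01 Hz implemented as regression on a discrete-cosine drift basis —
deterministic, exactly reproducible, and free of the edge transients of
recursive filters; and region extraction from a 4D image with an integer
label volume. Extraction masks out voxels whose temporal-mean intensity
falls in the lowest 25 % of the robust intensity range (2nd–98th
percentile of the mean image, the FSL convention) and drops regions
retaining less than 50 % of their voxels — the coverage threshold is not
externally specified anywhere authoritative, so 50 % is a documented,
configurable default.

Motion is summarised as framewise displacement: the sum of absolute
frame-to-frame deltas of the three translations plus the three rotations
converted to arc length at a 50-mm head radius. The exclusion rule —
more than 0.5 mm displacement in at least 20 % of transitions — treats the
20 % boundary as inclusive (exclusion at exactly 20 %); both threshold and
fraction are configurable since the inclusive/strict reading is a judgment
call.

## The surrogate null

Sliding-window estimates fluctuate even for perfectly stationary coupling,
so observed dFC must be compared against a null that preserves everything
*except* genuine time-localised coupling changes. Phase randomization does
this: randomise the Fourier phases of each series while keeping amplitudes.
The critical design point is that **one phase sequence is drawn per
surrogate and added identically to every region's spectrum**. Independent
per-region phases would destroy the cross-correlation structure; the
common-phase construction preserves each region's amplitude spectrum and
autocorrelation *and* the full static correlation matrix exactly (up to
round-off), which the tests assert at $10^{-10}$/$10^{-8}$. DC and Nyquist
bins are left untouched so the output is real with the original means.

Per subject, the observed global (or raw, un-normalised subnetwork) dFC is
compared with the mean over 100 surrogates; at cohort level a paired t-test
of observed versus surrogate-mean values tests for nonspurious dynamics.
For speed, all of a subject's surrogates are propagated through one FFT and
one sliding-sum sweep; this batched engine draws random phases in the same
order as the sequential path and is tested to agree with it exactly.

## The synthetic cohort generator

The generator is a stand-in: the emulated study is observational and
specifies no generative model, so all choices here are ours and are listed
explicitly.

* **Signal model.** Volumes are independent multivariate Gaussian draws
  with an instantaneous correlation matrix. A static profile has
  off-diagonal entries jittered around a base correlation (default 0.25,
  near typical whole-brain absolute-correlation levels) and is projected to
  the nearest PSD correlation matrix when needed. Time-varying coupling
  follows a sinusoid around the profile, $r_{ij}(t) = r_{ij} + A
  \sin(2\pi t\,TR/P)$, restricted to a chosen pair set, or a supplied
  piecewise-constant state sequence. No haemodynamic convolution is applied
  (analytic tractability; temporally white data also make the surrogate
  null's calibration interpretable), so the generator does not emulate BOLD
  autocorrelation, scanner drift, or physiological noise spectra — passing
  tests demonstrate correctness of the estimators, not robustness to those
  real-data features.
* **Dimensions.** Defaults are 202 volumes at TR 2.2 s (197 usable after
  discarding 5) and 30 regions — large enough to contain the 6 + 6
  subnetwork regions plus cortical filler while keeping whole-cohort
  simulation tractable; the emulated acquisition's 224 regions are
  supported but not the default. Surrogate calibration/power runs use
  compact 4-region subjects at T = 1970 so that 50 replicates of 20-subject
  cohorts with 100 surrogates each complete in minutes.
* **A caveat on timescales.** A 59.4-s window spanning one full period of a
  60-s modulation averages much of it out; window-level *tracking* of the
  target trajectory is only resolvable for modulation periods well above
  the window length (tests use 120–240 s for tracking and monotonicity
  properties), while *variability* statistics and the surrogate test remain
  sensitive at the 60-s default.
* **Groups and fatigue link.** Patients are simulated as the high-dynamics
  group (modulation amplitude 0.3 on the basal ganglia-DMN pairs, jittered
  ±40 % per subject); controls use half that amplitude. Each subject's
  *measured* normalised subnetwork dFC-cv is the true fatigue driver:
  CIS-20r total $=$ intercept $- 15 \cdot z(\text{driver}) + 6 \cdot
  (\text{EDSS} - 3) + \mathcal{N}(0, 12)$, clipped to $[20, 140]$, with
  intercepts 75 (patients) and 47 (controls) near typical group means. The
  negative slope encodes the direction of interest (more dynamics, less
  fatigue); 20 item responses consistent with the total are then drawn and
  rescored through `score_cis20r()`, so the scoring path is exercised.
  Ages are truncated-normal (42, 10) on [18, 65]; patient EDSS is uniform
  on {1.0, …, 6.0} in 0.5 steps.
* **Reproducibility.** One master seed expands into per-subject sub-seeds
  by a fixed counter scheme, so cohorts are bit-reproducible and subjects
  statistically independent.

## Clinical statistics

CIS-20r scoring uses a configurable item-to-subscale map; the instrument's
exact item order and reverse keying are not public domain knowledge the
package can assume, so the shipped default (items 1–8 subjective
complaints, 9–12 motivation, 13–15 physical activity, 16–20 concentration,
no reversal) is an explicit stand-in. Totals at or above 76 classify severe
fatigue.

Group comparisons are gated on a one-sample Kolmogorov–Smirnov normality
check against a normal with estimated parameters (the common
statistics-package behaviour; conservative, and a Lilliefors-style
alternative would be stricter): normal pairs get a t-test — pooled variance
by default, switching to Welch when the variance ratio exceeds 4:1 —
otherwise Mann–Whitney U. Paired (longitudinal) comparisons gate a paired
t-test versus Wilcoxon signed-rank on the normality of the differences.

`hierarchical_forward_regression()` processes predictor blocks in order
(clinical covariates, then volumetrics when available, then dFC measures);
within a block, candidates enter stepwise by smallest partial-t p-value
while below 0.05, without removal. Standardized $\beta$ values are reported
along with $R^2$, adjusted $R^2$, and the $\Delta R^2$ F-test at each
entry. Forward selection inflates family-wise error; matching the emulated
analysis, no multiple-testing correction is applied anywhere, and this is
reported rather than corrected. Post-hoc Spearman correlations and a
Kruskal–Wallis three-group comparison (controls, non-fatigued, fatigued by
the cutoff) with uncorrected pairwise Mann–Whitney follow-ups complete the
stage. One calibration note: at group sizes 19/15/18 and a 1-sd shift in
one group, the omnibus test's true power is about 0.79 (estimated by direct
simulation), so validation asserts a bound consistent with that rather than
a rounder number.

## Numerical choices and degenerate inputs

* Zero-variance regions (static or windowed) yield `NA` entries with a
  warning; summaries skip `NA` cells and report how many were skipped.
* Correlations are clamped to $[-1, 1]$ after floating-point arithmetic.
* All-zero paired differences return statistic 0, p = 1 rather than an
  error; constant samples are classified non-normal.
* Cholesky factorisation adds a $10^{-10}$ diagonal jitter; a
  nearest-PSD eigenvalue projection is the fallback for modulated target
  matrices.
* Trailing volumes not covered by a complete window are dropped; windows
  are 0-based half-open intervals.

## Validation summary

The test-suite properties worth knowing about (all on synthetic data):
exact agreement of every estimator with independent loop oracles
($10^{-12}$); exact spectrum/sFC preservation by surrogates; type-I
calibration of the surrogate test on stationary cohorts (rejection rate at
most ~12 % at $\alpha = 0.05$ over 50 replicates of 20 subjects, T = 1970,
100 surrogates) and power at modulation amplitude 0.3 (≥ 95 % of
replicates); recovery of the planted fatigue predictors (EDSS positive,
subnetwork dFC-cv negative) in ≥ 80 % of 20 cohort replicates; and the
motion-rule boundary (retain at 19 %, exclude at 20 %).
`scripts/acceptance.R` recomputes all of these from scratch.
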