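---
title: "Models and methods behind blockmvpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind blockmvpa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

blockmvpa reimplements, end to end and against simulated data with a
known ground truth, the analysis workflow used to ask whether two tasks
that activate the *same* cortical territory do so with the *same* neural
code: subject-level GLM contrasts, conjunction-defined shared regions of
interest, a mean-activation-level comparison, and multi-voxel pattern
analysis (MVPA) after a two-step normalization that strips the regional
mean signal. The scientific point the workflow can establish is a
dissociation: a region may show no mean-amplitude difference between two
tasks while still carrying a reliably decodable pattern difference —
mean-insensitive information. Because real scanner data for this design
are not redistributable, every stage here is exercised on synthetic
cohorts whose effects are planted, so correctness claims are claims
about recovery of known truth.

## The experimental design being emulated

The simulated paradigm is a two-run block design with three conditions —
NA (action generation to an object noun), NV (verb generation) and NR
(noun reading, the control). Per run: 12 task blocks (4 per condition)
alternate with 12 rest blocks. A task block is a 2 s cue followed by six
trials of a 1 s fixation and a 1.5 s stimulus (a 15 s task epoch); rest
blocks last 10 s. At TR = 2 s a run is exactly
12·(2 + 15) + 12·10 = 324 s = 162 volumes, 324 volumes per session.
`build_design()` is the single source of truth for this arithmetic and
rejects any override whose run length is not a TR multiple.

The block order is stated as counter-balanced in the source design
without the schedule being given; we use a deterministic Latin-square
rotation (each consecutive triple of task blocks is a rotated permutation
of the three conditions, with the rotation offset advancing per triple
and per run). This is balanced, auditable, and recorded in the events
table rather than drawn at random.

## Signal model of the simulator

For voxel $v$ in region $r$ at time $t$:

$$
Y_v(t) = B + \sum_{c} \left(a_{r,c} + p_{r,c}[v]\right) x_c(t)
        + d_v(t) + g_v^\top m(t) + \varepsilon_v(t)
$$

* $B = 100$, so amplitudes read directly as percent signal change.
* $x_c$ is the condition-$c$ boxcar convolved with the canonical HRF —
  built by the *same* code path the analysis-side design matrix uses, so
  simulation and analysis cannot disagree about the hemodynamic model;
  with zero noise the GLM recovers planted betas to machine precision,
  and the tests assert this at 1e-8.
* $a_{r,c}$ is the region-by-condition mean amplitude; $p_{r,c}$ is a
  *fixed, exactly zero-mean* voxel pattern (sd `pattern_sd`), the carrier
  of mean-free information. Patterns are seeded from the effect spec, not
  the subject, so they are population-level features.
* $d_v$ is low-frequency drift: a random combination of the first
  `n_drift_components` discrete-cosine basis functions below 1/128 Hz,
  scaled so its temporal sd equals `drift_amplitude`. Because it lives
  exactly in the span of the analysis-side high-pass regressors, filter
  correctness is testable in the noiseless limit.
* $m(t)$ are six random-walk motion parameters and $g_v$ per-voxel
  couplings (sd `motion_coupling`); motion enters only through this
  regressor leakage, not as spatial displacement.
* $\varepsilon_v$ is stationary AR(1) noise with marginal sd `white_sd`
  and lag-1 autocorrelation `ar1_rho`.

Defaults (`noise_spec()`): `white_sd = 1` (1% of baseline — realistic
task-fMRI noise), `ar1_rho = 0.3` (typical at TR 2 s), `drift_amplitude
= 1`, `n_drift_components = 3`, `motion_coupling = 0.1`, and a
between-subject amplitude sd of 0.3 around the population values. The
source study does not report inter-subject variability, so these are
package choices, fixed once; the tests that depend on them (type-I
calibration, chance-level recovery) are statements about this stated
world, not about the study's unavailable data.

What the generator deliberately does **not** emulate: spatial
displacement from head motion, physiological (cardiac/respiratory)
noise, slice timing, EPI distortion, and spatial noise correlation. A
green test therefore establishes algorithmic correctness and statistical
calibration under this model — not robustness to every artifact of real
acquisitions.

## Subject-level GLM

Per run: optional Gaussian smoothing (default 8 mm FWHM, separable,
reflective boundaries — constants are preserved exactly and interior
mass is conserved); a design matrix with one boxcar⊛HRF regressor per
task condition, one for cues, DCT drift regressors for all frequencies
below 1/128 Hz, the six motion parameters, and a constant. Rest is the
implicit baseline. The 15 s task epoch (first fixation onset to last
stimulus offset) is modeled as one block — the design is a block
paradigm, not event-related.

The HRF is a double-gamma difference, parameterized so the positive
lobe's *mode* sits at `peak_delay` (6 s) and the undershoot's at 16 s,
with unit dispersions and undershoot ratio 1/6. (The classic SPM
parameterization with shape = delay/dispersion peaks at 5 s; we pin the
mode to the nominal peak delay, which is what the package's contract
tests check.) For regressor construction the kernel is normalized to
unit *integral* so a sustained block plateaus at 1 and betas read as
percent signal change at plateau; `hrf_evaluate()` itself is unit-peak.

Serial correlation is handled by pooled two-pass prewhitening in the
Cochrane–Orcutt spirit: OLS, one lag-1 autocorrelation pooled over all
in-mask voxels per run, AR(1) whitening of data and design, refit. With
rho = 0 this is exactly OLS (tested). Contrasts are
$c\hat\beta / \sqrt{\hat\sigma^2\, c (X^\top X)^{-1} c^\top}$ under the
whitened design; subject-level contrast *effects* (not t values) are
averaged across the two runs and carried to the group.

Whether the original analysis modeled the 2 s cue is not stated (only
the three tasks and rest are listed as regressors); we model cues by
default (`model_cue = TRUE`) on the argument that an unmodeled visual
event would bleed into task betas, and expose the switch.

## Group inference and shared ROIs

Group maps are voxelwise one-sample t tests over subject effect maps
(dof = n − 1; zero-variance voxels get t = 0 rather than ±Inf — they only
arise in degenerate synthetic data). Thresholding: one-sided p < 0.001
voxelwise, then cluster-level FWE at 0.05 by **sign-flip permutation of
the maximum cluster extent** (26-connectivity): the subject maps'
signs are flipped (exhaustively when 2^n is small, otherwise a seeded
random subset including the identity), the max cluster size of each
flipped analysis forms the null, and an observed cluster survives if its
extent exceeds the null's 95th percentile. This replaces random-field
theory deliberately: RFT's smoothness and lattice assumptions fail on
desk-scale grids, while the sign-flip test is exact under exchangeability
and its family-wise error is itself verified by simulation in the test
suite (5% ± 3% over 200 null cohorts). This is the one intentional
methodological substitution in the package.

The conjunction of the thresholded NA>NR and NV>NR maps is their
voxelwise intersection (the quoted description of the original procedure
is an intersection, not a minimum-statistic conjunction test), and the
resulting mask is split into shared ROIs by the anatomical parcel each
voxel belongs to, dropping groups below `min_roi_voxels`.

## Mean-level analysis

Per ROI, each subject's NA>NR and NV>NR contrast *parameter estimates*
(effects, not t values — matching the "parametric estimates" the
original figures plot) are averaged over ROI voxels and compared with a
paired t test, Bonferroni-corrected over the number of ROIs tested.
Sidedness is configurable and reported (default two-sided); the source
reporting is ambiguous on this point, so the package refuses to match it
silently. Identical inputs are treated as a well-defined null (t = 0)
while a constant nonzero difference — zero variance with nonzero mean —
is an error, since its t statistic is infinite.

## MVPA

Within each shared ROI and subject:

1. **Run-wise high-pass.** The ROI voxel × time matrix is residualized
   against the sub-1/128 Hz DCT basis per run. This step is standard
   decoding practice and is load-bearing here: voxel-specific slow drift
   is shared between temporally close blocks, and without filtering a
   null cohort decodes at ~58% under the default noise model. With it,
   null accuracy is 50.0% (verified over hundreds of simulated null
   cohorts). It can be disabled (`detrend_cutoff_s = NULL`).
2. **Two-step normalization.** Each voxel's time series is z-scored by
   its own temporal mean and sd, then each time point is z-scored across
   voxels. After stage 2 every time point has spatial mean 0 and sd 1:
   classification sees only the mean-stripped pattern. Constant voxels
   are dropped with a logged warning. The implementation is pinned
   against an independent two-pass oracle at 1e-10 on random matrices.
3. **Sample assembly.** Every volume whose acquisition midpoint, minus a
   4 s hemodynamic shift, falls inside an NA or NV stimulus epoch becomes
   one sample labeled by its block. Under the default timing this yields
   60–61 samples per condition per subject (block onsets alternate
   parity, so blocks contribute 7 or 8 TRs). The source text's "128
   samples per participant" per task is not derivable from its printed
   timing (8 blocks × 15 s / 2 s = 60); the labeling window and shift are
   therefore explicit configuration, and the sample count is reported,
   never forced.
4. **Block-grouped 8-fold CV.** The chronologically k-th block of each
   condition goes to fold k: all samples of a block stay in one fold
   (leakage is asserted structurally on every split), and each fold holds
   one NA and one NV block. TR-level random splits would let temporal
   autocorrelation inflate accuracy; 8 folds arise naturally from the
   8 blocks per condition. Grouped CV with a fixed overall class balance
   carries the usual slight pessimistic bias (null accuracy sits a
   fraction of a point below 50%), which the chance-level tests absorb.
5. **Classifier.** A linear max-margin classifier with fixed
   regularization C = 1: L2-regularized squared-hinge SVM, unpenalized
   intercept, minimized by BFGS with an analytic gradient. No SVM
   library is available in the target environment, so the optimizer is
   part of the package and pinned by its own tests (perfect separation
   on separated clouds; chance on permuted labels). The objective is
   smooth and strictly convex, so results are deterministic; seeds only
   fix fold evaluation order.

Group inference on accuracies is a one-sample t test against the 50%
two-class chance level, one-sided (greater) — decoding below chance is
not evidence of information — Bonferroni-corrected over ROIs. The
source describes this test as one-sample in its methods and as paired in
its results; the one-sample form is the only one coherent with a
constant chance reference, and is what the package implements.

## Calibration of the planted dissociation

The headline validation plants an "SMA-like" region (amplitude *and*
pattern difference between NA and NV) and an "IFG-like" region (pattern
difference only, identical amplitudes) and requires the mean-level test
to fire only in the former while MVPA fires in both. The pattern
strength default (`pattern_sd = 0.2`) comes from a one-off calibration
sweep run during development at n = 21 with ten replicates per level:
MVPA power for the pattern-only region was 20% at `pattern_sd = 0.1` and
100% at 0.2 (with mean-level rejection at the nominal 5% there). The
value was fixed before the acceptance tests were written and has not
been revisited; it is part of the stated world, not a tuning knob.

## Numerical and design choices worth knowing

* **Seeds.** One master seed; every stochastic component (subject,
  region pattern, permutation set, fold order) draws from a child stream
  derived by hashing the master seed with a stream name. Results are
  bit-stable under a fixed seed, and adding a stage does not shift the
  randomness of others.
* **NIfTI-1 I/O** is implemented directly (348-byte header, sform
  affine, float64 by default) because no NIfTI reader exists in the
  dependency set; float64 makes disk roundtrips exact, which is what
  lets the chained CLI stages reproduce the monolithic pipeline
  byte-for-byte.
* **"NA" as a condition label** collides with R's missing-value literal
  in delimited files; the events readers disable NA-string parsing for
  the condition column. A condition named NA is an unfortunate but
  faithful naming choice.
* **Unanimous norming responses** make the action-consistency ratio
  N1/N2 divide by zero; they return `Inf`, which sorts above every
  finite ratio — the ordering the statistic exists to induce — rather
  than erroring or clamping.
* **Voxel indices** are 0-based (i, j, k) in grid space in all exported
  artifacts; world coordinates appear only in reports, via the affine.
* **Connectivity** for clusters is 26-neighborhood by default
  (configurable to 6/18), matching common neuroimaging practice.

## Known limitations

Real-data quantities from the source study (peak MNI coordinates,
shared-ROI voxel counts of 78/38/29, accuracies of 65/61/58%, behavioral
means) depend on unavailable participant data and are *not* reproduction
targets; the package's claims are calibration and recovery claims on its
stated synthetic world. The AR model is a single pooled rho per run, not
ReML with spatially varying variance components. Smoothing at the
default 8 mm on a 20-voxel grid blurs parcels that real-scale analyses
would keep separate, so desk-scale validations of ROI logic typically
run unsmoothed. The permutation FWE needs enough subjects to resolve
p < 0.05 (2^n ≥ 20, i.e. n ≥ 5) — with fewer, nothing can survive, by
construction.
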