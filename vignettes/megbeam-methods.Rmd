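---
title: "Source analysis of stimulus-related oscillatory power with megbeam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source analysis of stimulus-related oscillatory power with megbeam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megbeam)
```

## The analysis problem

MEG studies of visual responses often ask whether stimulus-related changes in
band-limited oscillatory power differ between groups — for example, whether
the induced gamma-band (30–80 Hz) response to faces that is robust in
typically developing children is reduced or absent in children with an autism
spectrum condition, while the early phase-locked (evoked) response is intact.
Answering that requires a chain of steps: a forward model, a spatial filter
that turns 200+ sensor channels into source-space estimates, per-epoch power
contrasts between post-stimulus ("active") and pre-stimulus ("passive")
windows, group inference that controls the family-wise error over thousands
of voxels without distributional assumptions, time-frequency analysis at
selected source locations with an evoked/induced decomposition, and
covariate models linking the physiology to behavioral traits.

`megbeam` implements that chain end to end, together with a synthetic
two-cohort generator that plants the group structure the chain is meant to
detect. The generator is not a test fixture bolted on the side: it is the
package's study definition. Every claim the test suite makes about the
pipeline is a claim about what the pipeline recovers from data whose ground
truth is known.

## Forward model

A homogeneous sphere is used as the conductor. For MEG this is not a crude
approximation in the way it would be for EEG: the external magnetic field of
a current dipole in a spherical conductor has a closed form (the Sarvas
solution), is exactly independent of the conductivity profile, and is blind
to the radial source component. Consequently each source location carries a
2-column lead field spanning the two tangential directions, and grid points
within 20 mm of the sphere center are excluded — near the center the
tangential field vanishes and beamformer weights become numerically
unstable.

The sphere is centered at MNI (0, −18, 15) mm with a 95 mm radius. That
choice is deliberate: the posterior sites this kind of study cares about —
lateral occipital cortex (36, −86, 2), occipital pole (−20, −92, 16),
fusiform gyrus (32, −57, −3) — are interior points of this sphere, whereas
an origin-centered sphere of conventional radius would cut off the occipital
pole. Sensors are laid out deterministically (Fibonacci spiral) on the upper
hemisphere of a concentric 120 mm shell, normals pointing inward, 248 by
default.

All geometry is in millimeters throughout the package; lead fields are in
tesla per nA·m. A single unit for positions avoids the classic
meters/millimeters unit bug at the cost of non-SI inputs to the physics,
which are converted internally.

The source grid is an isotropic lattice (5 mm default) whose nodes sit at
integer multiples of the spacing, ordered lexicographically. Each subject's
grid is this one lattice mapped through their affine, so every subject has
the same number of points in the same order and group maps can be averaged
voxel-by-voxel. Points that an affine pushes outside the sphere are flagged
and masked, never silently zeroed.

## Beamforming

The spatial filter is the scalar minimum-variance (LCMV) beamformer. At each
grid point the source orientation is taken as the tangential direction
maximizing output power — the eigenvector of \(L^\top C^{-1} L\) with the
smallest eigenvalue — and the weights are

\[ w = \frac{C^{-1} l_\theta}{l_\theta^\top C^{-1} l_\theta}, \]

which pass the lead field \(l_\theta\) with unit gain while minimizing
output variance. The covariance \(C\) is estimated from band-filtered data
pooled over the passive and active windows of the contrast at hand, plus
diagonal loading.

Two tunable parameters matter here:

* **Diagonal loading** (`regularization`, fraction of the mean diagonal;
  default 0.02). This is a genuine trade-off, not a formality. With the long
  pooled windows used here the covariance is estimated from tens of
  thousands of samples and is well conditioned, so heavy loading only blurs
  the spatial filter; in side-by-side runs 5% loading dropped single-source
  argmax recovery from 100% to ~93%. But with very light loading (1%) the
  adaptive filter is sharp enough to partially cancel a strong source that
  sits *between* lattice points — the usual situation once subject affines
  are applied — suppressing the very contrast being scanned for. 2% keeps
  exact on-grid localization in all tested runs while retaining off-grid
  sensitivity; both regimes are reachable through the argument.
* **Covariance windows**. The default pools the passive window and the
  active window(s) of the contrast, so both states contribute and the
  filter is not biased toward either.

The per-voxel statistic is a paired t across epochs of (active-window power
− passive-window power), where power is the mean squared amplitude of the
band-filtered virtual-electrode trace in the window. Because this contrast
compares the same voxel's output across time windows, the weight-norm
(depth) scaling cancels, and no separate depth normalization (neural
activity index) is applied.

Subject t-maps are converted to z through the probit transform of the t
cumulative distribution, computed on log scale so deep tails keep their
ordering and clamped at |z| = 8 (flagged). Group inference is a one-sample
t across subjects per voxel, thresholded nonparametrically: random subsets
of subjects have their maps sign-flipped, the maximum |t| over voxels is
recorded per permutation, and the (1 − α) quantile of those maxima is the
family-wise threshold. When all \(2^n\) flip patterns number no more than
the requested permutations they are enumerated exhaustively, which the test
suite exploits to check the engine against an independent enumeration.

The between-groups procedure follows the two-stage logic of contrasting
contrasts: an unpaired two-sample t per voxel on subject-level mean
active-window power (TD vs ASD), the same on passive-window power (the
baseline difference), each with its own 300-permutation label-exchange
maximum-statistic cutoff at p < .001; the reported map is
t\_active − t\_passive and the applied cutoff is whichever of the two tests
required the higher value. The subject-level summary entering this test is
the mean band power over epochs (the raw power, not z), switchable — the
choice between raw and z-converted summaries is genuinely open, and raw
power keeps the two stages on the same scale. The permutation quantile is
used as the cutoff; the parametric p < .001 t-quantile is logged alongside
for comparison.

Inference is two-sided throughout: both power increases (gamma responses)
and decreases (beta desynchronization, the ASD-like gamma reduction) are
real phenomena here.

## Virtual electrodes and time-frequency analysis

A virtual electrode (VE) is the beamformer output at a single location:
site coordinates in MNI space are mapped through each subject's affine, the
lead field is evaluated analytically at the mapped point (not snapped to a
grid node), and the unit-gain weights reconstruct the per-epoch source time
series. Sites come from three modes: the peak |t| of the between-groups
map, the mean position of significant within-group maxima snapped to the
grid, or theory-driven coordinates passed through unchanged (default
(32, −57, −3), right fusiform).

Time-frequency maps use the Stockwell transform in its frequency-domain
form: for analyzed frequency k, the inverse FFT of the spectrum shifted by
k and windowed by the Gaussian voice \(\exp(-2\pi^2 m^2 / k^2)\). Two
structural identities follow from this construction and are asserted by the
tests: the time-marginal of row k equals the DFT coefficient at k (to
machine precision), and temporal resolution scales with frequency.
Frequencies are snapped to DFT bins; the analysis range defaults to
1–100 Hz in 1 Hz steps with ×4 time decimation for tractability, all
configurable. The frequency ceiling deliberately exceeds the 30–80 Hz gamma
band (displays in this literature run past 100 Hz) while staying far below
the 678.17 Hz Nyquist.

The evoked/induced decomposition is operational, not model-based:

* **evoked** — average the traces across epochs, then transform: only
  phase-locked activity survives the averaging (amplitude \(\propto 1/n\)
  for uniformly random phase);
* **induced** — transform every epoch, then average the power: phase is
  irrelevant, so this is *total* power.

"Induced" here is therefore total power, not total-minus-evoked; an
evoked-subtraction variant exists behind `subtract_evoked = TRUE` but is
off by default. The two definitions differ, and the operational one is the
one this analysis tradition actually computes. A direct consequence, tested
as an invariant, is that evoked power never exceeds induced power at any
bin, and that dialing per-epoch phase jitter from 0 to uniform moves the
evoked/induced ratio monotonically from ~1 to ~0.

First-level TF statistics: for each bin in the active span, a paired t
across epochs against that frequency's mean power over the passive window
(−300 to −100 ms). The baseline is per-frequency rather than per-bin
because there is no natural bin-to-bin pairing between a 200 ms active
window and a 200 ms baseline at a different time. Group-level TF inference
reuses the sign-flip maximum-statistic engine on the subjects' first-level
t-maps.

## The synthetic cohort

The generator emulates the face-viewing protocol's geometry: 2000 ms epochs
(−1000 to +1000 ms around stimulus onset), 678.17 Hz sampling, 600 epochs
over 6 emotion-condition labels, 248 magnetometers; a scaled-down preset
(`cohort_spec_demo()`: 8 + 8 subjects, 60 epochs, 64 sensors) exists for
interactive runs. Planted structure:

* an **evoked transient** — a Gabor atom centered at 100 ms, identical in
  every epoch, in both groups (the intact early response);
* **induced gamma** — ongoing 60 ± 10 Hz narrowband noise at the lateral
  occipital and fusiform sites whose amplitude is multiplied by the
  subject's *gamma gain* over 150–650 ms. TD-like gains center on 2.0
  (a power increase), ASD-like on 0.5 (a decrease): one mechanism produces
  both the group difference and the within-group signs of the two cohorts'
  responses. Pure bursts (no baseline) and a sinusoidal carrier with a
  phase-jitter dial are special cases used by the decomposition tests;
* **beta desynchronization** — 12–28 Hz activity at the occipital pole
  halved after 150 ms in both groups;
* **background** — fresh 1/f-shaped dipole noise at random interior
  locations each epoch, plus white sensor noise (30 fT default).

Dipole amplitudes (evoked 30 nA·m, induced baseline 20 nA·m, background
15 nA·m) are stated nowhere in the literature this emulates; they were
chosen once as physiologically plausible values at which the TD-like
occipital gamma maxima clear the permutation thresholds, and are exposed in
the configuration.

Covariates: AQ is Gaussian per group (TD 12.33 ± 6.47, ASD 38.62 ± 6.16,
truncated to 0–50) and coupled to the subject's gamma gain through a
Gaussian copula with within-group correlation r = −0.5 by default. Note the
*pooled* AQ–gain correlation is not r: it also carries the between-group
separation (high-AQ subjects are mostly in the low-gain group). Age and
FSIQ are drawn with identical distributions in both groups, because the
emulated design matched participants pairwise on them — simulating the
matched design means *not* planting group differences in matched
covariates. Affines are identity plus a small rigid perturbation (2° / 3 mm
SD), which is what makes the warped-grid machinery non-trivial in every
test that uses a cohort.

What the generator does **not** emulate: realistic cortical geometry and
BEM conductor effects, eye movements and their artifacts, per-emotion
response differences (condition labels exist but carry no differential
signal), environmental noise needing reference-channel regression, and
between-subject variability in head size. Tests passing on this generator
therefore certify the statistical chain — localization, decomposition,
calibration, recovery in kind — not robustness to those real-data nuisances.

## Numerical choices

* **Filtering** is zero-phase by construction: the squared-magnitude
  response of a 4th-order Butterworth band-pass (identical to a
  forward–backward pass of that filter) applied spectrally on a
  mirror-extended signal. This vectorizes across all channels and epochs at
  once; attenuation one octave outside the band exceeds 40 dB twice over.
* **Artifact rejection** replaces manual inspection with a peak-to-peak
  rule: epochs whose maximum channel peak-to-peak amplitude exceeds 6× the
  median epoch amplitude are masked. Survivors are never modified or
  reordered.
* **Degenerate voxels** (lead-field cross-product condition number above
  1e8, zero-variance contrasts, points warped outside the sphere) are
  flagged and masked from maps and permutation nulls.
* **Permutation quantiles** use linear interpolation (R's default type 7);
  seeds are recorded in every permutation result.
* **Ties** in peak tables break lexicographically by coordinate, so output
  is reproducible across platforms.
* Epoch containers are a versioned R-native serialized layout with a schema
  validator (field presence, shapes, version major); volumetric maps export
  to NIfTI with an affine that reproduces each grid point's MNI coordinate
  exactly, TF maps to CSV with a JSON sidecar.

## Study sizes used by the tests and the acceptance script

The shipped checks run at desk scale, chosen so the full suite completes in
minutes while each check still measures what it claims: localization uses a
5 mm grid cropped to an occipital region (~560 voxels), 64 sensors and 60
epochs over 50 seeded repeats; the family-wise error calibration uses 200
null cohorts of 6 subjects × 15 epochs on a coarse grid; the group-recovery
run uses the 8 + 8 × 60-epoch preset on a 5 mm occipital grid; regression
recovery uses 100 covariate-level cohorts at the full 13 + 12 size. The
regression study deserves one honesty note: its response variable is the
planted per-subject gamma gain plus measurement noise (SD = 0.25 × the gain
SD), not a re-measured VE statistic — re-running the full VE chain 2,500
times would add hours without changing what the test examines (the
backward-elimination behavior). The measurement chain itself is validated
separately: across 25 subjects at default SNR, VE-measured induced gamma
modulation ranks the planted gains with Spearman ρ > 0.95.

One boundary effect is worth knowing about. With two pure-noise covariates
and the lenient p > 0.10 removal rule (the rule this analysis tradition
uses), backward elimination ends with a noise covariate in the model
whenever the smaller of their two p-values lands at or below 0.10 —
probability 1 − 0.9² = 0.19. The probability of recovering the AQ-only
model therefore has an asymptote near 0.81, and a 100-cohort estimate of it
fluctuates by ±4 percentage points across seed sets. That fluctuation is a
property of the procedure, not of the implementation.

## Known limitations

* The spherical forward model is exact for MEG only; nothing here
  generalizes to EEG without a new lead-field module.
* The scalar beamformer assumes a dominant orientation per voxel; vector
  (3-component) beamforming is out of scope.
* Site selection mode 2 averages significant maxima across *all* supplied
  within-group maps without weighting by window or band; when nothing is
  significant the mode errors (the pipeline then skips that site and says
  so).
* Between-group inference on raw power summaries assumes comparable sensor
  gain across subjects — true in simulation, an instrumentation question on
  real systems.
* The behavioral simulator plants RT/accuracy structure at the
  subject × condition level only; trial-level RT modeling (and hence
  mixed-design ANOVA) is out of scope.
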