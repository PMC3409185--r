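# megbeam

Minimum-variance beamforming and virtual-electrode time-frequency analysis
for MEG studies of stimulus-related oscillatory power — with a synthetic
two-cohort generator so the whole chain is testable without any recorded
data.

## What problem this addresses

A recurring design in developmental MEG asks whether the induced (non
phase-locked) gamma-band response to a visual stimulus differs between two
groups — for example robust occipital gamma in typically developing
children but reduced or reversed gamma modulation in children with an
autism spectrum condition, with the early evoked response intact, and the
gamma deficit scaling with a trait covariate such as the Autism Spectrum
Quotient (AQ). `megbeam` is for researchers who want that full analysis
chain as tested, reusable R functions rather than a one-off script pile:

* analytic spherical-conductor (Sarvas) lead fields on an isotropic MNI
  grid, warped per subject by affine transforms;
* scalar LCMV beamforming, `w = C⁻¹lθ / (lθᵀC⁻¹lθ)`, orientation chosen to
  maximize output power;
* per-epoch active-vs-passive band power contrasts (paired t per voxel),
  t→z conversion, group one-sample inference with sign-flip permutation and
  maximum statistics;
* a between-groups "contrast of contrasts": two-sample t-maps on active and
  passive power, each with its own 300-permutation label-exchange cutoff at
  p < .001, reported as t_active − t_passive under the higher of the two
  cutoffs;
* virtual electrodes at MNI sites, Stockwell time-frequency maps, and the
  operational evoked/induced decomposition (average-then-transform vs
  transform-then-average);
* shared statistics: pooled/Welch t (from raw data or printed summaries),
  Bonferroni adjustment, 2-SD outlier trimming, log10 RT transform,
  backward-elimination regression with standardized betas;
* a cohort simulator that plants evoked transients, gain-modulated induced
  gamma (group gains 2.0 vs 0.5 by default), beta desynchronization, 1/f
  background dipoles, and an AQ covariate negatively correlated with each
  subject's gamma gain.

The methods vignette (`vignettes/megbeam-methods.Rmd`) documents the model,
the tunable parameters and every numerical design choice.

## Worked example

Plant a single induced 60 Hz source in right lateral occipital cortex,
localize it with the beamformer, and decompose the response at a virtual
electrode:

```r
library(megbeam)

head <- head_model()
sensors <- build_sensor_array(64, head = head)

src <- source_spec(c(35, -85, 0), orientation = 0.4, components = list(
  source_component("induced", freq = 60, bandwidth = 20,
                   onset = 150, offset = 650, amplitude = 20)))
epochs <- simulate_epoch_set(list(src), sensors, head, n_epochs = 60, seed = 1)
epochs <- reject_artifacts(remove_dc(epochs))
#> <epoch_set> 60 epochs x 64 channels x 1356 samples @ 678.17 Hz, 0 rejected

grid <- crop_grid(build_source_grid(5, head), c(15, -105, -20), c(55, -65, 20))
lf <- lead_field_matrix(grid, sensors, head)
tmap <- scan_volume(epochs, lf, band = c(30, 80),
                    active = c(250, 450), passive = c(-300, -100))
#> peak t = 17.36 (z = 8.00) at MNI (35, -85, 0)

cov <- covariance(bandpass(epochs, c(30, 80)),
                  windows = list(c(-300, -100), c(50, 650)))
ve <- reconstruct_trace(place_ve(ve_site(c(35, -85, 0)), diag(4),
                                 sensors, head, cov), epochs)
ev  <- evoked_tf(ve, 40, 80, 2)
ind <- induced_tf(ve, 40, 80, 2)
#> evoked/induced power ratio at 60 Hz: 0.017
```

The beamformer recovers the planted source at exactly the planted voxel
(t = 17.4 for the 250–450 ms gamma power increase), and because the
planted source is non-phase-locked, averaging the epochs before the
Stockwell transform destroys its power: the evoked/induced ratio is ~0.02.
A phase-locked source gives a ratio near 1 — that dissociation is the
operational definition of "induced" activity.

Group statistics work from printed summaries too:

```r
pooled_t(n1 = 13, mean1 = 38.62, sd1 = 6.16,
         n2 = 12, mean2 = 12.33, sd2 = 6.47)
#> pooled t = 10.407, df = 23.000, p = 3.58e-10
```

`run_pipeline(read_analysis_config(list(...)))` chains everything —
simulate → preprocess → volumetric scans (both bands × three windows) →
within- and between-group permutation maps → VE selection → TF
decomposition and group TF statistics → AQ regression — and writes NIfTI
maps, peak CSVs, TF CSVs and JSON reports when `out_dir` is set.

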