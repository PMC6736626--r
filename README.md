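# stcpipe

Slice timing correction (STC) and its interaction with the rest of the
fMRI preprocessing pipeline, studied on simulated ground truth.

Echo-planar fMRI acquires a volume slice by slice, so the slices of one
volume are samples of the brain taken up to almost a full TR apart. STC
temporally realigns each slice's voxel time series to a reference
acquisition time — but head motion interacts with slice timing (the head
moves *between* slice acquisitions), so the benefit of STC depends on the
motion level, the interleave order, and where STC sits relative to motion
correction (MC), nuisance regression, and spatial smoothing. `stcpipe` is
a desk-scale laboratory for those questions, aimed at methods researchers
and pipeline builders.

## What's inside

* **Simulator** — brain-like phantom with labelled ROIs (one thin cortical
  band spanning most slices), event-related boxcar stimuli convolved with
  the canonical double-gamma HRF and scaled to 4% of the voxel mean,
  cardiac/respiratory sinusoids (1.23 / 0.25 Hz) sampled at each slice's
  own acquisition times, white thermal noise at 5% of the BOLD power, and
  rigid motion traces generated to sit exactly in low / medium / high mean
  framewise displacement bins (< 0.1, 0.25–0.4, 0.6–0.7 mm). Motion and
  slice timing interact at the per-slice level: every slice is extracted
  from the brain volume rigid-transformed to its own acquisition instant.
* **STC algorithms** — `filtershift()` (polyphase Kaiser-windowed sinc,
  cutoff 0.21 Hz, the highest frequency in the canonical HRF),
  `hanning_sinc_stc()` (low-order windowed-sinc interpolation),
  `fourier_phase_stc()` (frequency-domain phase shift), and the
  shifted-regressor (SR) evaluation standard (data only low-pass filtered;
  the GLM regressor carries each slice's delay).
* **Realignment** — `estimate_rigid()` / `realign_series()`: masked SSD,
  Nelder–Mead with a coarse-to-fine pyramid on cubic B-spline
  interpolation; recovers synthetic motion within 0.05 mm / 0.05°.
* **Evaluation** — voxelwise GLM (`Y = X beta + e`, OLS) with the
  standardized beta `beta sd(x)/sd(y)` (the Pearson correlation for a
  single-regressor design) mapped through Fisher's z; top-20 voxel
  selection on a high-delay slice; dice overlap; FIR deconvolution of the
  HRF with unit-normalized SSE; Gaussian smoothing sweeps; split-half
  reliability; ARMA(1,1) prewhitening; paired one-tailed tests.
* **Harness** — `run_pipeline()` / `run_experiment_grid()` /
  `run_study_summary()` orchestrate pipeline-order experiments
  (STC before/after/without MC, with or without motion parameter
  residualization and smoothing) over simulated scan grids.

## Worked example

Simulate a medium-motion, 6:1-interleave scan, build the shifted-regressor
reference, and compare no correction, Hanning-sinc STC, and FilterShift
(all after motion correction) at the reference voxels:

```r
library(stcpipe)
sim <- simulate_scan(shape = c(24, 24, 16), tr_s = 2, interleave = 6,
                     motion_level = "medium", duration_s = 300,
                     seed = 42, n_events = 10)
mean_fwd(sim$trace)
#> 0.325
roi <- sim$phantom$roi_masks$tall_cortex
ref <- sr_reference(sim$scan, sim$stim, sim$hrf, roi, k = 12)
for (m in c("none", "sinc", "filtershift")) {
  res <- run_pipeline(sim$scan, pipeline_spec(m, "before_stc"),
                      sim$stim, sim$hrf, roi, ref_set = ref$set, k = 12)
  cat(sprintf("%-12s mean z = %.2f  dice = %.2f  HRF SSE = %.3f\n",
              m, res$mean_z, res$dice, res$mean_sse))
}
#> none         mean z = 0.99  dice = 0.92  HRF SSE = 0.515
#> sinc         mean z = 1.64  dice = 0.92  HRF SSE = 0.081
#> filtershift  mean z = 1.89  dice = 1.00  HRF SSE = 0.034
```

The selected voxels sit on the highest-delay slice (1.88 s into the TR
here). Without STC their series lag the model by almost a TR: the mean
Fisher z of the model fit drops and the FIR-deconvolved response is a
shifted, distorted HRF (unit-normalized SSE ≈ 0.5). Either corrector
restores the HRF shape (SSE ≈ 0.03–0.08); the moderate-order FilterShift
reconstruction also recovers more of the correlation than the low-order
sinc, and reproduces the reference voxel set exactly (dice 1.0).

A thin command-line wrapper is installed at `inst/cli/stcpipe`
(`simulate`, `stc`, `mc` subcommands) for shell use; scans travel as
NIfTI-1 with a JSON sidecar carrying `SliceTiming` metadata, motion and
events as TSV.

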