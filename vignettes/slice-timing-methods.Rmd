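---
title: "Simulating and evaluating slice timing correction in fMRI pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating slice timing correction in fMRI pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stcpipe)
```

## The problem

Echo-planar fMRI acquires a volume one slice at a time, so within a single
TR the slices of a volume are samples of the brain at *different* times:
with 37 slices and TR = 2 s, the last-acquired slice lags the first by
almost the full TR. Slice timing correction (STC) temporally realigns every
slice's voxel time series to a common reference time. Whether, when, and in
which order to apply STC relative to rigid-body motion correction (MC) is a
long-standing pipeline question, because head motion and slice timing
interact: the head moves *within* a volume, so after spatial realignment a
voxel's series can mix samples acquired at different delays.

`stcpipe` provides the desk-scale machinery to study this quantitatively:

* a ground-truth simulator that couples rigid head motion with slice-wise
  acquisition timing at the individual slice-acquisition level;
* three STC algorithms — a polyphase Kaiser-windowed-sinc *FilterShift*
  corrector, a low-order Hanning-windowed sinc interpolator (the family
  FSL's `slicetimer` belongs to), and a Fourier phase shift (the family
  SPM's routine belongs to) — plus the *shifted regressor* (SR) evaluation
  standard that leaves the data unshifted and moves the model instead;
* rigid-body realignment with sub-voxel parameter recovery;
* a voxelwise GLM evaluation suite: standardized beta / Fisher z,
  motion-parameter residualization (MPR), FIR deconvolution of the HRF,
  dice overlap of top-voxel sets, Gaussian smoothing sweeps, split-half
  reliability, and paired one-tailed tests.

## Acquisition timing model

`build_scheme(tr_s, n_slices, interleave_step)` assigns slice `k` the delay
`tr_s * p_k / n_slices`, where `p_k` is its 0-based position in the
acquisition order. The order groups slices `s, s + step, s + 2 step, ...`
for group starts `s = 1..step`, ascending within groups — the convention of
ascending interleaved EPI. Two useful anchors under a 6:1 (Philips-style)
interleave at TR 2 s: slice 17 of a 41-slice scheme is acquired 1.46 s into
the TR, and slice 18 of a 37-slice scheme at 1.78 s. The reference slice
defaults to the first acquired, so "high-delay slice" means acquired late
in the TR.

## The simulator

`simulate_scan()` ties the pieces together; each is exported separately.

**Phantom.** `build_phantom()` builds an anisotropic ellipsoidal head
(narrower left-right than anterior-posterior so in-plane rotation is
identifiable) with a bright core, dark ventricle-like lobes, smooth 5%
texture, and a partial-volume (slightly blurred) edge. Four ROIs are
labelled; `tall_cortex` is a thin (≈ 2 voxel) cortical band spanning more
than half of all slices, so part of it always falls on a high-delay slice —
the stand-in for a superior-frontal-type region. The default desk grid is
32 × 32 × 20 voxels of 2 × 2 × 3 mm; full-size grids are a parameter away.

**Activity.** Each ROI gets an event-related train of 20 boxcar events
(durations uniform on 2–8 s, ≥ 2 s gaps, jittered onsets) convolved with
the canonical double-gamma HRF (peak delay 6 s, undershoot delay 16 s,
dispersions 1 s, undershoot ratio 1/6, 32 s support; the sampled kernel
peaks near 5 s). The stimulus parameters are configurable; the defaults are
a choice of plausible event-related design, not a derived quantity. The
HRF's spectrum is negligible above 0.21 Hz, which motivates the filter
cutoff below.

**BOLD scaling.** The per-ROI BOLD course is centred, scaled to unit
variance, and multiplied per voxel by 4% of that voxel's baseline
intensity, so the signal standard deviation is 4% of the local mean — a
robust visual-cortex-like amplitude.

**Motion.** `generate_motion_trace()` draws, per rigid parameter, a slow
drift (random sub-0.2 Hz sinusoids plus a random walk) and white
frame-to-frame jitter, mixed so each contributes about half of the
framewise displacement. Because mean framewise displacement (mFWD — mean of
|Δtranslation| summed over axes plus 50 mm times |Δrotation|) measures
per-frame change, the accumulated drift range comes out several times the
mFWD, as real head-motion traces show. mFWD is exactly positively
homogeneous in the trace amplitude, so one rescale places a trace exactly
at its bin centre: low 0.05 mm (bin < 0.1), medium 0.325 mm (0.25–0.4),
high 0.65 mm (0.6–0.7).

**Rendering.** For each volume `v` and slice `k`, acquired at
`t = (v-1) TR + delay_k`: the per-volume trace is spline-upsampled to one
sample per slice acquisition; the instantaneous brain volume (baseline plus
BOLD at `t`) is rigid-transformed by the motion at `t` (cubic B-spline
resampling about the volume centre, background fill); and plane `k` is
extracted. Slice timing and motion therefore interact exactly as in
acquisition. Cardiac (1.23 Hz) and respiratory (0.25 Hz) sinusoids are
added per slice at that slice's own sample times — so they alias exactly as
the scanner would see them — with amplitudes of 1% of the voxel mean
(configurable; in real data cardiac amplitude would be calibrated against
the power measured at the Circle of Willis, which has no desk-scale
equivalent). White thermal noise is added with power equal to 5% of the
BOLD signal power per voxel; "5% of the signal's energy" is read as 5% of
the *BOLD* variance. Alternative readings (up to 5% of the raw series
energy) change the absolute Fisher-z level dramatically; see *Limitations*.

What the simulator does **not** model: spin-history effects, B0
inhomogeneity, susceptibility distortion, or any nonlinear motion artifact.
Passing tests on these scans validate the algorithms under rigid motion and
slice timing only; absolute statistic levels on real data will be lower.

## Slice timing correctors

All three correctors shift slice `k` backward by its delay so every slice
reads as sampled at the reference time; all are linear and shape-preserving.

**FilterShift.** Conceptually: zero-stuff upsample by `L` (default: the
slice count), low-pass filter with a Kaiser-windowed sinc (cutoff 0.21 Hz,
60 dB stopband, 0.08 Hz transition; Kaiser β and tap count from the
standard design formulas), then resample at the grid shifted by the slice
delay. With `L = n_slices` every slice delay lands exactly on the upsampled
grid. The implementation is the polyphase decomposition of that pipeline —
identical output, one small kernel per slice — with circular padding and
each phase branch normalized to unit sum so constants are exactly
preserved. A test verifies the polyphase path against the literal
upsample–filter–resample construction at 1e-10.

**Hanning-windowed sinc.** A truncated (± 3 taps) windowed-sinc fractional
delay per voxel with boundary replication — the "low-order" interpolation
family; zero shift is an exact identity.

**Fourier phase shift.** Multiplies each voxel spectrum by
`exp(-i 2 pi f delay)` (Nyquist bin kept real). Exact for sinusoids; the
series is treated as circular and is not detrended, so a strong linear
trend leaks, as with any phase-shift method.

**Shifted regressor.** The evaluation standard: the data receive only the
same Kaiser low-pass (applied before any MC), and the GLM regressor for
slice `k` is built at the volume times *plus* the slice delay. With no
cross-slice processing this bounds what any STC can achieve; spatial
smoothing breaks that bound because it mixes slices with different delays.

## Realignment

`estimate_rigid()` minimizes the masked mean squared intensity difference
over the reference brain support with a Nelder–Mead simplex, coarse-to-fine
(2× block-mean pyramid), on a cubic B-spline interpolant of the moving
volume. Three numerical details matter at desk scale and are worth
recording:

* volumes are pre-smoothed by a 1-voxel Gaussian before the cost is
  evaluated; without it, interpolation error correlated with image gradients
  pulls rotation estimates toward zero by ~0.07° at 2°;
* output voxels within 3 voxels of the array boundary are excluded from the
  cost — at the optimum these are exactly the samples whose source can touch
  fill-contaminated voxels of the moving volume (a rigid map preserves
  distance to the field-of-view edge);
* after convergence the estimate is applied inversely and the residual is
  re-estimated and composed (one refinement pass), which removes the
  remaining bias for multi-degree rotations.

With these, parameters of noiseless synthetic motion up to 5 mm / 5° are
recovered within 0.05 mm / 0.05° on a 32 × 32 × 24 phantom.
`realign_series()` registers every volume to the middle one, warm-starting
each volume from its neighbour and using a stride-3 cost grid (a speed
setting validated by the recovery tests). One caveat the tests document:
with a 4% BOLD signal on a one-sided cortical band, *signal-driven apparent
motion* of order 0.1 mm / 0.4° is genuinely present in any least-squares
registration of these phantoms — visible here because the desk-scale brain
is small relative to its active region.

## GLM and evaluation

The voxelwise model is `Y = X beta + e` solved by ordinary least squares;
the reported effect is the standardized beta `beta * sd(x) / sd(y)`, which
for a single-regressor-plus-intercept design *is* the Pearson correlation
of regressor and series (asserted to 1e-10 in the tests), mapped through
Fisher's z (`atanh`, with |r| clipped at 1 - 1e-12). The default simulated
design is intercept + task; MPR adds the six rigid parameters and their
backward-difference derivatives (12 columns). ARMA(1,1) prewhitening
estimates (phi, theta) by moment matching on the pooled residual lag-1/lag-2
autocorrelations (AR(1) fallback when not identifiable) and filters data
and design with the whitening recursion.

The evaluation protocol is the top-20 design: the top 20 voxels by t
statistic are selected on the highest-delay slice holding enough ROI
voxels, from the unsmoothed SR reference run; every pipeline is then read
out at those voxels (mean Fisher z), compared as sets (dice overlap of each
pipeline's own top 20 against the reference set), and FIR-deconvolved
(one coefficient per TR lag up to 24 s) with the unit-normalized SSE
against the true HRF. At a 1.9 s slice delay with no STC this SSE is ~0.4,
dominated by the pure time shift, and drops an order of magnitude once the
delay is corrected.

## Problem sizes and determinism

Everything is seeded; identical seeds reproduce scans, tables, and
summaries bit-for-bit. The test suite uses 12–32 voxel grids and 40–150
volumes; the pipeline-ordering check uses five 32 × 32 × 20, 150-volume
medium-motion interleave-6 realizations; `run_study_summary()` (the basis
of `scripts/acceptance.R`) uses five realizations per motion level at
32 × 32 × 37 and 300 volumes (10 min at TR 2 s) — the full slice count and
scan duration with a reduced in-plane matrix. Motion is estimated once per scan
on the SR-filtered data and those transforms realign the raw scan wherever
MC is applied first; pipelines that run STC *before* MC estimate their own
motion on the corrected data, since that estimation difference is the
scientific point of that ordering.

## Known limitations

* The absolute Fisher-z level runs high (top-voxel z ≈ 1–2): under the
  "5% of BOLD variance" thermal reading plus 1% physiological sinusoids the
  per-voxel SNR is higher than real scans exhibit, and at 0.3 mm mFWD the
  per-frame displacement is geometrically small against 2 mm voxels, so the
  top-20 protocol finds motion-immune voxels. The *relative* orderings this
  package is about (both corrections > either alone > none; STC gains
  concentrated on high-delay slices; SR as an unsmoothed ceiling) hold,
  with one caveat: at medium motion this simulator favours STC-only over
  MC-only, whereas on real data rigid realignment typically helps more than
  temporal realignment at that motion level. HRF-shape error
  (unit-normalized SSE) is on the realistic ~0.4 scale for uncorrected
  high-delay slices.
* Only rigid motion is simulated; spin history, B0, and distortion effects
  are absent by design.
* The FilterShift internals (upsample factor, taps, β) are standard Kaiser
  design choices, configurable but not byte-matched to any external tool;
  the Hanning-sinc and Fourier correctors mimic families of algorithms, not
  specific binaries.
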