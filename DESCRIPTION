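Package: stcpipe
Title: Simulation and Evaluation of Slice Timing Correction in fMRI
    Preprocessing Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how slice timing correction (STC) interacts
    with head motion and other steps of the fMRI preprocessing pipeline. The
    package simulates ground-truth 4-D BOLD scans in which rigid head motion
    and slice-wise acquisition timing interact at the per-slice level,
    implements three slice timing correction algorithms (a polyphase
    Kaiser-windowed sinc "FilterShift" filter, a low-order Hanning-windowed
    sinc interpolator, and a Fourier phase shift) together with a
    shifted-regressor gold standard, provides rigid-body volume realignment,
    and evaluates pipelines with a voxelwise general linear model
    (standardized beta / Fisher z, motion parameter residualization, FIR
    deconvolution of the hemodynamic response, dice overlap of top-voxel
    sets, Gaussian smoothing sweeps, and split-half reliability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
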