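test_that("pipeline specifications validate their fields", {
  sp <- pipeline_spec("filtershift", "before_stc")
  expect_s3_class(sp, "pipeline_spec")
  expect_error(pipeline_spec("magic"), "arg")
  expect_error(pipeline_spec("sinc", mpr = NA), "mpr")
  expect_error(pipeline_spec("sinc", smoothing_fwhm_mm = -2), "smoothing")
})

test_that("a zero smoothing kernel leaves pipeline results unchanged", {
  sim <- clean_sim()
  roi <- sim$phantom$roi_masks$tall_cortex
  a <- run_pipeline(sim$scan, pipeline_spec("sinc", "none"),
                    sim$stim, sim$hrf, roi, k = 12L)
  b <- run_pipeline(sim$scan, pipeline_spec("sinc", "none",
                                            smoothing_fwhm_mm = 0),
                    sim$stim, sim$hrf, roi, k = 12L)
  expect_equal(a$mean_z, b$mean_z)
  expect_equal(a$own_set$index, b$own_set$index)
})

test_that("the shifted-regressor design reduces to the plain regressor on the reference slice", {
  sim <- clean_sim()
  sch <- sim$scheme
  d <- sch$slice_times_s[sch$ref_slice] - sch$slice_times_s[sch$ref_slice]
  r0 <- build_task_regressor(sim$stim, sim$hrf, 2, 80, shift_s = 0)
  rref <- build_task_regressor(sim$stim, sim$hrf, 2, 80, shift_s = d)
  expect_identical(r0, rref)
})

test_that("slice timing correction raises the high-delay-slice z of a clean scan", {
  sim <- clean_sim()
  roi <- sim$phantom$roi_masks$tall_cortex
  ref <- sr_reference(sim$scan, sim$stim, sim$hrf, roi, mc = FALSE, k = 12L)
  none <- run_pipeline(sim$scan, pipeline_spec("none", "none"),
                       sim$stim, sim$hrf, roi, ref_set = ref$set, k = 12L)
  fs <- run_pipeline(sim$scan, pipeline_spec("filtershift", "none"),
                     sim$stim, sim$hrf, roi, ref_set = ref$set, k = 12L)
  expect_gt(fs$mean_z, none$mean_z)
  ## SR is the ceiling on clean data (up to filter ripple)
  expect_gte(ref$result$mean_z + 0.05, fs$mean_z)
})

test_that("a one-cell experiment grid is a deterministic single-row-per-pipeline table", {
  g1 <- run_experiment_grid(motion_levels = "medium", interleaves = 2L,
                            n_realizations = 1L, shape = c(12L, 12L, 10L),
                            duration_s = 120, methods = "sinc", n_events = 6L, k = 6L,
                            mc_options = c("after_stc", "none"), seed = 3)
  expect_equal(nrow(g1$table), 2L)
  expect_equal(nrow(g1$manifest), 1L)
  expect_true(all(c("mean_z", "mean_dice", "mean_sse") %in% names(g1$table)))
  g2 <- run_experiment_grid(motion_levels = "medium", interleaves = 2L,
                            n_realizations = 1L, shape = c(12L, 12L, 10L),
                            duration_s = 120, methods = "sinc", n_events = 6L, k = 6L,
                            mc_options = c("after_stc", "none"), seed = 3)
  expect_equal(g1$table, g2$table)
})

test_that("motion parameter residualization and prewhitening run end to end", {
  sim <- clean_sim()
  roi <- sim$phantom$roi_masks$tall_cortex
  ## MPR without realignment: parameters estimated but data untouched
  res <- run_pipeline(sim$scan, pipeline_spec("sinc", "none", mpr = TRUE),
                      sim$stim, sim$hrf, roi, k = 12L)
  expect_false(is.null(res$motion))
  expect_true(is.finite(res$mean_z))
  ## prewhitened fit returns finite statistics on the evaluated slice
  res2 <- run_pipeline(sim$scan, pipeline_spec("sinc", "none",
                                               prewhiten = TRUE),
                       sim$stim, sim$hrf, roi, k = 12L)
  expect_true(is.finite(res2$mean_z))
  ## residualizing motion from a clean scan must not destroy the fit
  expect_gt(res$mean_z, 0.5 * res2$mean_z)
})

test_that("on the reference slice, correction and no correction agree", {
  sim <- clean_sim()
  ref_k <- sim$scheme$ref_slice
  none <- glm_maps_slicewise(sim$scan, sim$stim, sim$hrf, slices = ref_k)
  for (op in list(hanning_sinc_stc, fourier_phase_stc)) {
    cor1 <- glm_maps_slicewise(op(sim$scan), sim$stim, sim$hrf,
                               slices = ref_k)
    expect_equal(cor1$z[, , ref_k], none$z[, , ref_k], tolerance = 1e-8)
  }
})
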