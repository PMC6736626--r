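test_that("a static scene renders identical volumes", {
  ph <- build_phantom(c(12, 12, 10), seed = 2)
  sch <- build_scheme(2, 10, 1)
  hrf <- canonical_hrf(0.1)
  ## constant BOLD series: centred to zero, so the scene is the baseline
  flat <- list(rate_hz = 10, times_s = seq(0, 39.9, by = 0.1),
               series = rep(3, 400))
  tr <- generate_motion_trace("none", 20, 2)
  scan <- render_scan(ph, list(tall_cortex = flat), tr, sch,
                      noise_spec(cardiac_amp_frac = 0, resp_amp_frac = 0,
                                 thermal_energy_frac = 0))
  for (v in 2:20)
    expect_equal(scan$data[, , , v], scan$data[, , , 1])
  expect_equal(scan$data[, , , 1], ph$mean_intensity, tolerance = 1e-12)
})

test_that("without motion or noise every voxel series equals the slice-time-sampled ground truth", {
  sim <- clean_sim()
  gt <- sim$scan$ground_truth$roi_series$tall_cortex
  ph <- sim$phantom
  V <- dim(sim$scan$data)[4]
  for (k in which(apply(ph$roi_masks$tall_cortex, 3, any))[c(2, 5)]) {
    vox <- which(ph$roi_masks$tall_cortex[, , k], arr.ind = TRUE)[1, ]
    series <- sim$scan$data[vox[1], vox[2], k, ]
    tt <- (seq_len(V) - 1) * 2 + sim$scheme$slice_times_s[k]
    amp <- 0.04 * ph$mean_intensity[vox[1], vox[2], k]
    truth <- ph$mean_intensity[vox[1], vox[2], k] +
      amp * approx(gt$times_s, gt$series, xout = tt, rule = 2)$y
    expect_equal(series, truth, tolerance = 1e-10)
  }
})

test_that("physiological sinusoids are sampled at each slice's own acquisition times", {
  ph <- build_phantom(c(12, 12, 10), seed = 2)
  sch <- build_scheme(2, 10, 2)
  flat <- list(rate_hz = 10, times_s = seq(0, 59.9, by = 0.1),
               series = rep(0, 600))
  tr <- generate_motion_trace("none", 30, 2)
  ns <- noise_spec(cardiac_amp_frac = 0.02, resp_amp_frac = 0,
                   thermal_energy_frac = 0)
  scan <- render_scan(ph, list(tall_cortex = flat), tr, sch, ns)
  k <- 4L
  tk <- (0:29) * 2 + sch$slice_times_s[k]
  i <- which(ph$brain_mask[, , k], arr.ind = TRUE)[1, ]
  mu <- ph$mean_intensity[i[1], i[2], k]
  expect_equal(scan$data[i[1], i[2], k, ],
               mu + 0.02 * mu * sin(2 * pi * 1.23 * tk), tolerance = 1e-10)
})

test_that("thermal noise power is the requested fraction of BOLD signal power", {
  ph <- build_phantom(c(16, 16, 10), seed = 3)
  sch <- build_scheme(2, 10, 1)
  hrf <- canonical_hrf(0.1)
  st <- generate_stimulus(6, 200, seed = 4)
  bold <- simulate_bold(st, hrf, 10)
  tr <- generate_motion_trace("none", 100, 2)
  ns0 <- noise_spec(cardiac_amp_frac = 0, resp_amp_frac = 0,
                    thermal_energy_frac = 0)
  ns5 <- noise_spec(cardiac_amp_frac = 0, resp_amp_frac = 0,
                    thermal_energy_frac = 0.05)
  clean <- render_scan(ph, list(tall_cortex = bold), tr, sch, ns0)
  noisy <- render_scan(ph, list(tall_cortex = bold), tr, sch, ns5, seed = 9)
  m <- ph$roi_masks$tall_cortex
  noise <- noisy$data - clean$data
  sig_pow <- (0.04 * ph$mean_intensity[m])^2   # BOLD is unit-variance scaled
  np <- apply(array(noise, c(prod(dim(m)), 100))[which(m), ], 1, var)
  expect_equal(mean(np / sig_pow), 0.05, tolerance = 0.05)
})

test_that("rendering is deterministic for a fixed seed", {
  a <- simulate_scan(c(12, 12, 10), 2, 2, "medium", 80, seed = 21, n_events = 4)
  b <- simulate_scan(c(12, 12, 10), 2, 2, "medium", 80, seed = 21, n_events = 4)
  expect_identical(a$scan$data, b$scan$data)
  c0 <- simulate_scan(c(12, 12, 10), 2, 2, "medium", 80, seed = 22, n_events = 4)
  expect_false(identical(a$scan$data, c0$scan$data))
})

test_that("renderer rejects inconsistent inputs", {
  ph <- build_phantom(c(12, 12, 10), seed = 2)
  sch <- build_scheme(2, 10, 1)
  flat <- list(rate_hz = 10, times_s = seq(0, 39.9, 0.1), series = rep(1, 400))
  tr <- generate_motion_trace("none", 20, 2)
  expect_error(render_scan(ph, list(nope = flat), tr, sch), "unknown ROI")
  tr_bad <- generate_motion_trace("none", 19, 2)
  expect_error(render_scan(ph, list(tall_cortex = flat), tr_bad, sch),
               "volumes")
})
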