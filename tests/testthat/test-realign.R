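test_that("rigid resampling has exact identity, inverse, and rotation behaviour", {
  ph <- reg_phantom()
  vol <- ph$mean_intensity
  id <- resample_rigid(vol, rigid_transform(), c(2, 2, 3), 3)
  expect_equal(id, vol, tolerance = 1e-12)

  ## translate +2 voxels in x and back
  fwd <- resample_rigid(vol, rigid_transform(c(4, 0, 0)), c(2, 2, 3), 1)
  expect_equal(fwd[3:32, , ], vol[1:30, , ], tolerance = 1e-12)
  back <- resample_rigid(fwd, rigid_transform(c(-4, 0, 0)), c(2, 2, 3), 1)
  expect_equal(back[5:28, 5:28, 3:22], vol[5:28, 5:28, 3:22],
               tolerance = 1e-9)

  ## 90 degree rotation about z maps an x-offset point to a y-offset point
  pt <- array(0, c(21, 21, 21)); pt[16, 11, 11] <- 1
  rot <- resample_rigid(pt, rigid_transform(c(0, 0, 0), c(0, 0, pi / 2)),
                        c(1, 1, 1), 1)
  expect_equal(rot[11, 16, 11], 1)
  expect_equal(sum(rot), 1, tolerance = 1e-12)

  expect_error(resample_rigid(array(0, c(3, 3)), rigid_transform()), "3-D")
})

test_that("rigid parameters are recovered within 0.05 mm and 0.05 degrees", {
  ph <- reg_phantom()
  vol <- ph$mean_intensity
  self <- estimate_rigid(vol, vol, c(2, 2, 3))
  expect_lt(max(abs(self$translations_mm)), 0.01)
  expect_lt(max(abs(self$rotations_rad)) * 180 / pi, 0.01)

  cases <- list(list(t = c(1.0, -0.5, 0.4), r = c(0, 0, 0)),
                list(t = c(0, 0, 0), r = c(0, 0, 2) * pi / 180),
                list(t = c(4, -3, 2), r = c(3, -2, 4) * pi / 180))
  for (cs in cases) {
    tf <- rigid_transform(cs$t, cs$r)
    mv <- resample_rigid(vol, tf, c(2, 2, 3), 3)
    est <- estimate_rigid(mv, vol, c(2, 2, 3), n_restarts = 4)
    expect_transform_close(est, cs$t, cs$r, 0.05, 0.05 * pi / 180)
  }
})

test_that("forward and reverse estimates are mutual inverses", {
  ph <- reg_phantom()
  vol <- ph$mean_intensity
  tf <- rigid_transform(c(1.2, -0.8, 0.5), c(0.8, -0.5, 1.2) * pi / 180)
  mv <- resample_rigid(vol, tf, c(2, 2, 3), 3)
  ab <- estimate_rigid(mv, vol, c(2, 2, 3))
  ba <- estimate_rigid(vol, mv, c(2, 2, 3))
  inv <- invert_transform(ab)
  expect_transform_close(ba, inv$translations_mm, inv$rotations_rad,
                         0.05, 0.1 * pi / 180)
})

test_that("series realignment recovers known volume-constant motion", {
  ph <- reg_phantom()
  vol <- ph$mean_intensity
  set.seed(13)
  V <- 8L; ref_v <- 4L
  tr_par <- cbind(runif(V, -1, 1), runif(V, -1, 1), runif(V, -0.8, 0.8))
  ro_par <- cbind(runif(V, -0.008, 0.008), runif(V, -0.008, 0.008),
                  runif(V, -0.012, 0.012))
  tr_par <- sweep(tr_par, 2, tr_par[ref_v, ])
  ro_par <- sweep(ro_par, 2, ro_par[ref_v, ])
  dat <- array(0, c(dim(vol), V))
  for (v in seq_len(V))
    dat[, , , v] <- resample_rigid(vol, rigid_transform(tr_par[v, ],
                                                        ro_par[v, ]),
                                   c(2, 2, 3), 3)
  scan <- fmri4d(dat, c(2, 2, 3), build_scheme(2, dim(vol)[3], 1))
  mc <- realign_series(scan, ref_index = ref_v)
  for (i in 1:3) {
    expect_gt(cor(mc$motion$translations_mm[, i], tr_par[, i]), 0.95)
    expect_gt(cor(mc$motion$rotations_rad[, i], ro_par[, i]), 0.95)
  }
  ## residual motion after realignment is much smaller than the original
  mc2 <- realign_series(mc$scan, ref_index = ref_v, estimate_only = TRUE)
  expect_lt(mean_fwd(mc2$motion), 0.3 * mean_fwd(mc$motion))

  ## idempotence in cost: re-realigning the realigned scan changes the
  ## mismatch to the reference volume by under 1%
  msd <- function(s) mean(sapply(seq_len(V)[-ref_v], function(v)
    mean((s$data[, , , v] - s$data[, , , ref_v])^2)))
  second <- realign_series(mc$scan, ref_index = ref_v)
  expect_lt(abs(msd(second$scan) - msd(mc$scan)) / msd(mc$scan), 0.01)
})

test_that("a motion-free scan yields near-zero estimates", {
  ## static brain plus thermal noise: the estimator must not hallucinate
  ## motion from noise alone
  ph <- reg_phantom()
  set.seed(31)
  V <- 10L
  dat <- array(ph$mean_intensity, c(dim(ph$mean_intensity), V)) +
    rnorm(length(ph$mean_intensity) * V, sd = 2)
  scan <- fmri4d(dat, c(2, 2, 3), build_scheme(2, dim(dat)[3], 1))
  mc <- realign_series(scan, estimate_only = TRUE)
  expect_lt(max(abs(mc$motion$translations_mm)), 0.02)
  expect_lt(max(abs(mc$motion$rotations_rad)) * 180 / pi, 0.02)

  ## with task signal present, the signal-induced apparent motion stays
  ## well below a voxel
  sim <- clean_sim()
  mcs <- realign_series(sim$scan, estimate_only = TRUE)
  expect_lt(max(abs(mcs$motion$translations_mm)), 0.5)
  expect_lt(max(abs(mcs$motion$rotations_rad)) * 180 / pi, 1)
})
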