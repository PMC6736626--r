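test_that("top-voxel selection respects mask, slice, k, and tie order", {
  set.seed(3)
  tmap <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  mask <- array(TRUE, dim(tmap))
  one <- select_top_voxels(tmap, mask, 2, k = 1)
  sl <- tmap[, , 2]
  expect_equal(one$coords[1, 1:2], unname(which(sl == max(sl), arr.ind = TRUE)[1, ]),
               ignore_attr = TRUE)
  top <- select_top_voxels(tmap, mask, 2, k = 20)
  expect_equal(top$k_top, 20L)
  expect_equal(length(unique(top$index)), 20L)
  expect_true(all(top$coords[, 3] == 2))
  expect_true(all(min(top$selection_stat) >= sort(sl, decreasing = TRUE)[20]))

  ## excluding the global max moves selection to the within-mask max
  m2 <- mask
  m2[one$coords[1, 1], one$coords[1, 2], 2] <- FALSE
  one2 <- select_top_voxels(tmap, m2, 2, k = 1)
  expect_false(identical(one2$index, one$index))
  expect_equal(tmap[one2$index], max(sl[m2[, , 2]]))

  ## ties break by ascending linear index
  tt <- array(0, c(4, 4, 1))
  tied <- select_top_voxels(tt, array(TRUE, dim(tt)), 1, k = 3)
  expect_equal(tied$index, 1:3)

  expect_error(select_top_voxels(tmap, mask, 2, k = 100), "eligible")
})

test_that("dice overlap matches its closed forms and is symmetric", {
  a <- list(index = 1:20); class(a) <- "voxel_set"
  b <- list(index = 1:20); class(b) <- "voxel_set"
  expect_equal(dice_overlap(a, b), 1)
  d <- list(index = 21:40); class(d) <- "voxel_set"
  expect_equal(dice_overlap(a, d), 0)
  h <- list(index = c(1:10, 101:110)); class(h) <- "voxel_set"
  expect_equal(dice_overlap(a, h), 0.5)
  expect_equal(dice_overlap(h, a), dice_overlap(a, h))
  expect_error(dice_overlap(integer(), integer()), "empty")
})

test_that("normalized HRF SSE has its closed-form values and invariances", {
  h <- canonical_hrf(0.5)$kernel
  expect_equal(hrf_sse(h, h), 0)
  expect_equal(hrf_sse(-h, h), 4)
  expect_equal(hrf_sse(3.7 * h, h), 0)            # scale invariance
  ## small perturbation: SSE is the squared orthogonal component
  set.seed(2)
  hn <- h / sqrt(sum(h^2))
  eps <- rnorm(length(h)) * 1e-4
  eperp <- eps - hn * sum(eps * hn)
  expect_equal(hrf_sse(h + eps, h), sum((eperp / sqrt(sum(h^2)))^2),
               tolerance = 1e-6)
  expect_error(hrf_sse(h * 0, h), "zero-norm")
})

test_that("Gaussian smoothing realizes the requested kernel width and conserves mass", {
  sch <- build_scheme(2, 15, 1)
  d <- c(21, 21, 15)
  delta <- array(0, c(d, 2)); delta[11, 11, 8, ] <- 1
  scan <- fmri4d(delta, c(2, 2, 2), sch)
  expect_identical(gaussian_smooth(scan, 0), scan)
  const <- fmri4d(array(4, c(d, 2)), c(2, 2, 2), sch)
  expect_equal(gaussian_smooth(const, 6)$data, const$data, tolerance = 1e-9)

  sm <- gaussian_smooth(scan, 5)
  prof <- sm$data[, 11, 8, 1]
  half <- max(prof) / 2
  above <- which(prof >= half)
  fwhm_mm <- (max(above) - min(above)) * 2   # voxel size 2 mm
  expect_lt(abs(fwhm_mm - 5), 2)             # within a voxel
  expect_equal(sum(sm$data[, , , 1]), 1, tolerance = 1e-3)
  expect_error(gaussian_smooth(scan, -1), "fwhm")
})

test_that("split-half reliability is near one for noise-free signal and fails on one voxel", {
  sim <- clean_sim()
  mask <- sim$phantom$roi_masks$tall_cortex
  r <- split_half_reliability(sim$scan, sim$stim, sim$hrf, mask)
  expect_gt(r, 0.99)
  m1 <- array(FALSE, dim(mask)); m1[which(mask)[1]] <- TRUE
  expect_error(split_half_reliability(sim$scan, sim$stim, sim$hrf, m1),
               "2 voxels")
})

test_that("the paired one-tailed test has its closed-form cases", {
  a <- rnorm(30)
  eq <- paired_one_tailed_t(a, a)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 0.5)
  expect_equal(eq$dof, 29L)
  ## 400 paired values (20 voxels x 20 scans) give 399 degrees of freedom
  set.seed(1)
  x <- rnorm(400)
  expect_equal(paired_one_tailed_t(x + 1, x)$dof, 399)
  ## constant positive difference with tiny jitter is overwhelming evidence
  y <- rnorm(50)
  res <- paired_one_tailed_t(y + 0.5 + rnorm(50, sd = 1e-4), y)
  expect_lt(res$p, 0.001)
  expect_error(paired_one_tailed_t(1:3, 1:4), "length")
})
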