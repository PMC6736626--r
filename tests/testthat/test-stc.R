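test_that("FilterShift realigns band-limited slice samples to the reference time", {
  bl <- bandlimited_scan()
  cor1 <- filtershift(bl$scan)
  ref_times <- (20:130 - 1) * 2
  truth <- bl$sig(ref_times)
  for (k in c(2, 7, 12)) {
    err <- max(abs(cor1$data[1, 1, k, 20:130] - truth))
    expect_lt(err, 0.02)  # percent-level reconstruction in the passband
  }
})

test_that("FilterShift leaves constants unchanged and reduces to the low-pass at zero delay", {
  bl <- bandlimited_scan(n_vols = 80L)
  const <- stcpipe:::with_data(bl$scan, array(5, dim(bl$scan$data)))
  out <- filtershift(const)
  expect_equal(out$data, const$data, tolerance = 1e-12)

  spec <- filter_spec(upsample_factor = bl$scheme$n_slices)
  ref <- bl$scheme$ref_slice
  fs_out <- filtershift(bl$scan, spec)
  lp <- kaiser_lowpass(bl$scan$data[1, 1, ref, ], 0.5, spec)
  expect_equal(fs_out$data[1, 1, ref, ], lp, tolerance = 1e-12)
})

test_that("Hanning-sinc interpolation shifts series as designed", {
  bl <- bandlimited_scan()
  ## zero shift is an exact identity
  seq_scan <- bl$scan
  seq_scan$scheme$slice_times_s[] <- 0
  out0 <- hanning_sinc_stc(seq_scan)
  expect_equal(out0$data, seq_scan$data, tolerance = 1e-12)

  ## half-sample shift of a slow sinusoid matches the analytic shift
  n <- 200; tr <- 2
  sch <- build_scheme(tr, 2, 1)   # slice 2 delayed by half a sample
  f0 <- 0.03
  dat <- array(0, c(1, 1, 2, n))
  for (k in 1:2) dat[1, 1, k, ] <- sin(2 * pi * f0 * ((seq_len(n) - 1) * tr +
                                                        sch$slice_times_s[k]))
  sc <- fmri4d(dat, c(2, 2, 3), sch)
  out <- hanning_sinc_stc(sc)
  truth <- sin(2 * pi * f0 * (19:180) * tr)
  expect_equal(out$data[1, 1, 2, 20:181], truth, tolerance = 0.01)

  ## interior points of a linear ramp are recovered under a small shift
  sch1 <- build_scheme(2, 1, 1)
  ramp <- array(seq_len(n), c(1, 1, 1, n))
  sc2 <- fmri4d(ramp, c(2, 2, 3), sch1)
  sc2$scheme$slice_times_s[1] <- 0.6   # 0.3-sample delay
  out2 <- hanning_sinc_stc(sc2)
  expect_equal(out2$data[1, 1, 1, 10:190], seq_len(n)[10:190] - 0.3,
               tolerance = 0.02)
})

test_that("the Fourier phase shift is exact for sinusoids and additive", {
  n <- 128L; tr <- 2
  sch <- build_scheme(tr, 4, 2)
  f1 <- 3 / (n * tr); f2 <- 10 / (n * tr)   # exact DFT bins
  mk <- function(f) {
    dat <- array(0, c(1, 1, 4, n))
    for (k in 1:4) dat[1, 1, k, ] <-
        cos(2 * pi * f * ((seq_len(n) - 1) * tr + sch$slice_times_s[k]))
    fmri4d(dat, c(2, 2, 3), sch)
  }
  s1 <- mk(f1); s2 <- mk(f2)
  o1 <- fourier_phase_stc(s1)
  for (k in 1:4)
    expect_equal(o1$data[1, 1, k, ], cos(2 * pi * f1 * (seq_len(n) - 1) * tr),
                 tolerance = 1e-9)
  ## zero shift: reference slice untouched
  expect_equal(o1$data[1, 1, sch$ref_slice, ], s1$data[1, 1, sch$ref_slice, ],
               tolerance = 1e-12)
  ## linearity: shifted sum equals sum of shifted components
  both <- stcpipe:::with_data(s1, s1$data + 2 * s2$data)
  o12 <- fourier_phase_stc(both)
  o2 <- fourier_phase_stc(s2)
  expect_equal(o12$data, o1$data + 2 * o2$data, tolerance = 1e-10)
})

test_that("all three correctors are linear operators that preserve geometry", {
  set.seed(8)
  sch <- build_scheme(2, 6, 2)
  mk <- function() fmri4d(array(rnorm(4 * 4 * 6 * 60), c(4, 4, 6, 60)),
                          c(2, 2, 3), sch)
  X <- mk(); Y <- mk()
  aXbY <- stcpipe:::with_data(X, 1.3 * X$data - 0.7 * Y$data)
  for (op in list(filtershift, hanning_sinc_stc, fourier_phase_stc)) {
    oX <- op(X); oY <- op(Y); oS <- op(aXbY)
    expect_equal(oS$data, 1.3 * oX$data - 0.7 * oY$data, tolerance = 1e-9)
    expect_equal(dim(oX$data), dim(X$data))
    expect_equal(oX$voxel_size_mm, X$voxel_size_mm)
  }
})

test_that("FilterShift reconstructs band-limited signals at least as well as the low-order sinc", {
  for (freqs in list(c(0.02, 0.06), c(0.05, 0.11, 0.17), c(0.15))) {
    bl <- bandlimited_scan(freqs = freqs, n_slices = 10L, n_vols = 150L,
                           interleave = 2L)
    truth <- outer(rep(1, 10), bl$sig((20:130 - 1) * 2))
    err <- function(out) sqrt(mean((out$data[1, 1, , 20:130] - truth)^2))
    e_fs <- err(filtershift(bl$scan))
    e_hs <- err(hanning_sinc_stc(bl$scan))
    expect_lte(e_fs, e_hs)
  }
})
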