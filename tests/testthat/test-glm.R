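test_that("task regressor shifting behaves as the shifted-regressor design requires", {
  hrf <- canonical_hrf(0.1)
  st <- generate_stimulus(8, 200, seed = 2)
  r0a <- build_task_regressor(st, hrf, 2, 100, shift_s = 0)
  r0b <- build_task_regressor(st, hrf, 2, 100, shift_s = 0)
  expect_identical(r0a, r0b)
  expect_error(build_task_regressor(st, hrf, 2, 100, shift_s = 2.5), "TR")

  ## a regressor shifted by the slice delay correlates better with that
  ## slice's series than the unshifted regressor (simulator as oracle)
  d <- 1.5
  bold <- simulate_bold(st, hrf, 20)
  series <- stcpipe:::sample_series(bold, (0:99) * 2 + d)
  rs <- build_task_regressor(st, hrf, 2, 100, shift_s = d)
  expect_gt(cor(rs, series), cor(r0a, series))

  ## an empty stimulus gives a constant column the design rejects
  empty <- structure(list(onsets_s = numeric(), durations_s = numeric(),
                          total_duration_s = 200), class = "stimulus_train")
  z <- build_task_regressor(empty, hrf, 2, 100)
  expect_true(all(z == 0))
  expect_error(design_matrix(z), "constant")
})

test_that("motion nuisance expansion gives 6 parameters plus 6 derivatives", {
  tr <- generate_motion_trace("medium", 30, 2, seed = 1)
  nn <- motion_nuisance(tr)
  expect_equal(ncol(nn), 12L)
  ## ramp translation: derivative constant after the leading zero
  ramp <- motion_trace((0:29) * 2, cbind(0:29 * 0.1, 0, 0),
                       matrix(0, 30, 3))
  nr <- motion_nuisance(ramp)
  expect_equal(unname(nr[1, "d_tx"]), 0)
  expect_true(all(abs(nr[-1, "d_tx"] - 0.1) < 1e-12))
})

test_that("the GLM reproduces the standardized-beta / Pearson identity", {
  set.seed(6)
  n <- 120
  hrf <- canonical_hrf(0.1)
  st <- generate_stimulus(8, 240, seed = 3)
  task <- build_task_regressor(st, hrf, 2, n)
  Y <- 3 * task + matrix(rnorm(n * 40), n, 40) + 5
  fit <- fit_glm(Y, design_matrix(task))
  for (j in seq_len(ncol(Y)))
    expect_equal(fit$r[j], cor(task, Y[, j]), tolerance = 1e-10)
  expect_equal(fit$dof, n - 2L)
  ## z transform properties
  expect_equal(fit$z, atanh(fit$r))

  ## perfect fit: r clipped just below 1
  yperf <- 2 * task + 1
  fperf <- fit_glm(yperf, design_matrix(task))
  expect_equal(fperf$r[1], 1 - 1e-12)
  ## orthogonal data: r near 0
  yorth <- rnorm(n)
  yorth <- yorth - task * sum(yorth * task) / sum(task^2)
  forth <- fit_glm(yorth, design_matrix(task))
  expect_lt(abs(forth$r[1]), 0.15)

  ## residuals orthogonal to the design
  X <- design_matrix(task)
  res <- Y - cbind(1, task) %*% solve(crossprod(cbind(1, task)),
                                      crossprod(cbind(1, task), Y))
  expect_lt(max(abs(crossprod(unclass(X), res))) / max(abs(Y)), 1e-6)
})

test_that("nuisance columns orthogonal to task and data leave beta unchanged", {
  set.seed(7)
  n <- 100
  task <- sin(2 * pi * 0.05 * (1:n))
  y <- 2 * task + rnorm(n) * 0.1
  ## build nuisance orthogonal to task, intercept and y
  M <- cbind(1, task, y)
  nu <- matrix(rnorm(n * 2), n, 2)
  nu <- nu - M %*% solve(crossprod(M), crossprod(M, nu))
  f0 <- fit_glm(y, design_matrix(task))
  f1 <- fit_glm(y, design_matrix(task, nu))
  expect_equal(f1$beta[1], f0$beta[1], tolerance = 1e-8)
  expect_equal(f1$dof, f0$dof - 2L)
})

test_that("a rank-deficient design is rejected with the collinear column named", {
  task <- sin(2 * pi * 0.05 * (1:50))
  X <- design_matrix(task, cbind(dup = task))
  expect_error(fit_glm(rnorm(50), X), "collinear")
})

test_that("ARMA(1,1) prewhitening removes simulated serial correlation", {
  set.seed(9)
  n <- 400
  task <- sin(2 * pi * 0.04 * (1:n))
  X <- cbind(1, task)
  ## white residuals: parameters near zero, data almost unchanged
  yw <- 2 * task + rnorm(n)
  pw <- prewhiten_arma11(yw, X)
  expect_lt(abs(pw$phi), 0.15)
  expect_lt(abs(pw$theta), 0.3)
  expect_gt(cor(pw$Y, yw), 0.95)

  ## AR(1) noise with phi = 0.4: whitened residual lag-1 acf below 0.05
  e <- as.numeric(arima.sim(list(ar = 0.4), n))
  y <- 2 * task + e
  pw2 <- prewhiten_arma11(y, X)
  b <- solve(crossprod(pw2$X), crossprod(pw2$X, pw2$Y))
  r2 <- pw2$Y - pw2$X %*% b
  ac <- acf(r2, plot = FALSE, lag.max = 1)$acf[2]
  expect_lt(abs(ac), 0.05)

  ## noise-free fit is preserved by whitening
  y0 <- 2 * task + 0.5
  pw3 <- prewhiten_arma11(y0, X)
  b0 <- solve(crossprod(X), crossprod(X, y0))
  b3 <- solve(crossprod(pw3$X), crossprod(pw3$X, pw3$Y))
  expect_equal(as.numeric(b3), as.numeric(b0), tolerance = 1e-8)

  expect_error(prewhiten_arma11(rnorm(10), cbind(1, rnorm(10))), "20")
})

test_that("FIR deconvolution inverts the discrete convolution exactly", {
  hrf <- canonical_hrf(0.1)
  st <- generate_stimulus(15, 600, seed = 5)
  tr <- 2; V <- 300
  s <- stcpipe:::stim_at_tr(st, tr, V)
  hTR <- approx(hrf$times_s, hrf$kernel, xout = (0:12) * tr, rule = 2)$y
  y <- numeric(V)
  for (j in 0:12) y <- y + hTR[j + 1] * c(rep(0, j), s)[1:V]
  fir <- fir_deconvolve(y, st, tr)
  expect_lt(hrf_sse(fir$hrf[1:13], hTR), 1e-6)

  ## amplitude scaling leaves the unit-normalized estimate unchanged
  fir2 <- fir_deconvolve(17 * y, st, tr)
  expect_equal(fir2$hrf / sqrt(sum(fir2$hrf^2)),
               fir$hrf / sqrt(sum(fir$hrf^2)), tolerance = 1e-10)

  ## pure-noise series: normalized SSE near the two-random-unit-vector level
  set.seed(10)
  sse_noise <- replicate(20, {
    fn <- fir_deconvolve(rnorm(V), st, tr)
    truth <- approx(hrf$times_s, hrf$kernel, xout = fn$lags_s, rule = 2)$y
    hrf_sse(fn$hrf, truth)
  })
  expect_equal(mean(sse_noise), 2, tolerance = 0.25)

  ## under-determined: more lags than usable time points
  expect_error(fir_deconvolve(rnorm(8), st, tr, window_s = 30), "FIR|rank")
})
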