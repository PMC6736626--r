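#' Build the task regressor
#'
#' Convolves the boxcar stimulus with the HRF on a dense grid and samples
#' the result at the volume acquisition times plus `shift_s`. A positive
#' shift builds the regressor as seen by a slice acquired `shift_s`
#' seconds into the TR — the shifted-regressor construction.
#'
#' @param stim A [generate_stimulus()] train.
#' @param hrf A [canonical_hrf()] model.
#' @param tr_s Repetition time in seconds.
#' @param n_vols Number of volumes.
#' @param shift_s Sampling shift in seconds, `|shift_s| < tr_s`.
#' @param dense_rate_hz Rate of the internal dense grid (default 20 Hz).
#' @return Numeric regressor of length `n_vols`.
#' @export
build_task_regressor <- function(stim, hrf, tr_s, n_vols, shift_s = 0,
                                 dense_rate_hz = 20) {
  check_num(tr_s, "tr_s", positive = TRUE)
  n_vols <- check_count(n_vols, "n_vols")
  check_num(shift_s, "shift_s")
  if (abs(shift_s) >= tr_s) stopf("|shift_s| must be below one TR")
  if (length(stim$onsets_s) &&
      max(stim$onsets_s + stim$durations_s) > n_vols * tr_s + tr_s)
    stopf("stimulus extends beyond the scan")
  bold <- simulate_bold(stim, hrf, dense_rate_hz)
  sample_series(bold, (seq_len(n_vols) - 1) * tr_s + shift_s)
}

#' Motion nuisance regressors
#'
#' Expands a per-volume motion trace into 12 nuisance columns: the six
#' rigid parameters plus their temporal derivatives (backward differences
#' with a leading zero).
#'
#' @param trace A per-volume [motion_trace()].
#' @return An `n_vols x 12` matrix with named columns
#'   (`tx, ty, tz, rx, ry, rz` and `d_` derivatives).
#' @export
motion_nuisance <- function(trace) {
  if (!inherits(trace, "motion_trace")) stopf("trace must be a motion_trace")
  if (trace$rate != "volume") stopf("motion nuisance needs a per-volume trace")
  P <- cbind(trace$translations_mm, trace$rotations_rad)
  D <- rbind(0, diff(P))
  out <- cbind(P, D)
  colnames(out) <- c("tx", "ty", "tz", "rx", "ry", "rz",
                     "d_tx", "d_ty", "d_tz", "d_rx", "d_ry", "d_rz")
  out
}

#' Assemble a GLM design matrix
#'
#' @param task Task regressor (numeric vector).
#' @param nuisance Optional matrix of nuisance columns.
#' @return An object of class `design_matrix`: the numeric matrix with an
#'   `intercept` first column, plus attributes `task_col`,
#'   `nuisance_cols`, and `condition_number`.
#' @export
design_matrix <- function(task, nuisance = NULL) {
  if (sd(task) == 0) stopf("task regressor is constant")
  X <- cbind(intercept = 1, task = task)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    keep <- apply(nuisance, 2, sd) > 0
    X <- cbind(X, nuisance[, keep, drop = FALSE])
  }
  sv <- svd(scale(X[, -1, drop = FALSE], scale = FALSE))$d
  structure(X, task_col = 2L,
            nuisance_cols = if (ncol(X) > 2) 3:ncol(X) else integer(),
            condition_number = if (min(sv) > 0) max(sv) / min(sv) else Inf,
            class = c("design_matrix", "matrix"))
}

#' Fit the voxelwise GLM
#'
#' Ordinary least squares `beta = (X'X)^{-1} X' Y` per voxel, with the
#' t statistic for the task column, the standardized beta
#' `r = beta * sd(x) / sd(y)` (equal to the Pearson correlation of the
#' task regressor with the series in a single-regressor design), and the
#' Fisher z transform `z = atanh(r)` with `|r|` clipped at `1 - 1e-12`.
#'
#' @param scan An [fmri4d()] scan, or a numeric matrix
#'   (time x voxels), or a single series.
#' @param design A [design_matrix()] (or plain matrix whose second column
#'   is the task regressor).
#' @param mask Optional logical array/vector selecting voxels (default:
#'   all).
#' @return An object of class `glm_maps`: list with `beta`, `t`, `r`, `z`,
#'   `residual_var` (each a vector over fitted voxels, or an array of the
#'   scan's spatial shape when a scan was given), `dof`, and `coords`.
#' @export
fit_glm <- function(scan, design, mask = NULL) {
  if (inherits(scan, "fmri4d")) {
    d <- dim(scan$data)
    Y <- matrix(scan$data, nrow = prod(d[1:3]), ncol = d[4])
    Y <- t(Y)
    spatial_dim <- d[1:3]
  } else {
    Y <- if (is.null(dim(scan))) matrix(scan, ncol = 1) else as.matrix(scan)
    spatial_dim <- NULL
  }
  X <- unclass(design)
  if (nrow(X) != nrow(Y))
    stopf("design has %d rows but the data has %d time points",
          nrow(X), nrow(Y))
  task_col <- attr(design, "task_col") %||% 2L
  keep <- if (is.null(mask)) seq_len(ncol(Y)) else which(as.vector(mask))
  Yk <- Y[, keep, drop = FALSE]
  XtX <- crossprod(X)
  ok <- tryCatch({ XtXi <- solve(XtX); TRUE }, error = function(e) FALSE)
  if (!ok) {
    qrX <- qr(X)
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stopf("rank-deficient design (collinear columns: %s)",
          paste(bad, collapse = ", "))
  }
  beta_all <- XtXi %*% crossprod(X, Yk)
  res <- Yk - X %*% beta_all
  dof <- nrow(X) - qr(X)$rank
  rv <- colSums(res^2) / dof
  beta <- beta_all[task_col, ]
  t_stat <- beta / sqrt(pmax(rv * XtXi[task_col, task_col], 1e-300))
  sx <- sd(X[, task_col])
  sy <- apply(Yk, 2, sd)
  r <- ifelse(sy > 0, beta * sx / sy, 0)
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  z <- atanh(r)
  shape <- function(v) {
    if (is.null(spatial_dim)) return(v)
    full <- rep(NA_real_, prod(spatial_dim))
    full[keep] <- v
    array(full, dim = spatial_dim)
  }
  structure(list(beta = shape(beta), t = shape(t_stat), r = shape(r),
                 z = shape(z), residual_var = shape(rv), dof = dof,
                 voxels = keep),
            class = "glm_maps")
}

#' ARMA(1,1) prewhitening
#'
#' Estimates ARMA(1,1) noise parameters from the lag-1 and lag-2
#' autocorrelations of the OLS residuals (moment matching:
#' `phi = rho2 / rho1`, `theta` from the ARMA(1,1) lag-1 equation), then
#' filters both the data and every design column with the whitening
#' recursion `w[t] = y[t] - phi y[t-1] - theta w[t-1]`. Falls back to
#' AR(1) (`theta = 0`) when the moment estimates are not invertible.
#'
#' @param Y Numeric series (vector) or (time x voxels) matrix; whitening
#'   parameters are estimated from the pooled residual autocorrelation.
#' @param X Design matrix.
#' @return List with `Y`, `X` (whitened), `phi`, `theta`, and `warning`
#'   (character, non-empty when the AR(1) fallback was taken).
#' @export
prewhiten_arma11 <- function(Y, X) {
  Ym <- if (is.null(dim(Y))) matrix(Y, ncol = 1) else as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(Ym)
  if (n < 20L) stopf("need at least 20 time points for prewhitening")
  beta <- solve(crossprod(X), crossprod(X, Ym))
  res <- Ym - X %*% beta
  acf_pooled <- function(lag) {
    num <- colSums(res[seq_len(n - lag) + lag, , drop = FALSE] *
                     res[seq_len(n - lag), , drop = FALSE])
    den <- colSums(res^2)
    mean(num / pmax(den, 1e-300))
  }
  r1 <- acf_pooled(1L); r2 <- acf_pooled(2L)
  warning_msg <- character()
  ## below sampling noise the residuals are treated as white
  phi <- if (abs(r1) > 2 / sqrt(n)) r2 / r1 else 0
  theta <- 0
  if (phi == 0) {
    ## nothing to whiten
  } else if (abs(phi) >= 0.999) {
    phi <- sign(phi) * 0.99
    warning_msg <- "phi clipped; AR(1) fallback"
  } else {
    ## rho1 = (1 + phi*theta)(phi + theta) / (1 + 2 phi theta + theta^2)
    f <- function(th) (1 + phi * th) * (phi + th) /
      (1 + 2 * phi * th + th^2) - r1
    sol <- tryCatch(stats::uniroot(f, c(-0.999, 0.999))$root,
                    error = function(e) NA_real_)
    if (is.na(sol)) {
      warning_msg <- "theta not identifiable; AR(1) fallback"
      theta <- 0
    } else theta <- sol
  }
  whiten <- function(M) {
    W <- M
    if (nrow(M) >= 2) {
      for (t in 2:nrow(M))
        W[t, ] <- M[t, ] - phi * M[t - 1L, ] - theta * W[t - 1L, ]
    }
    W
  }
  Yw <- whiten(Ym)
  Xw <- whiten(X)
  list(Y = if (is.null(dim(Y))) drop(Yw) else Yw, X = Xw,
       phi = phi, theta = theta, warning = warning_msg)
}

#' FIR deconvolution of the haemodynamic response
#'
#' Estimates the HRF at TR resolution as the free coefficients of lagged
#' copies of the stimulus indicator: the design has one column per TR lag
#' from 0 to `window_s`, plus an intercept, solved by OLS.
#'
#' @param series Voxel time series (vector) or (time x voxels) matrix; a
#'   matrix returns one estimate per column.
#' @param stim A [generate_stimulus()] train.
#' @param tr_s Repetition time.
#' @param window_s Length of the estimated response (default 24 s).
#' @return A list with `lags_s` and `hrf` (vector, or lags x voxels
#'   matrix).
#' @export
fir_deconvolve <- function(series, stim, tr_s, window_s = 24) {
  check_num(tr_s, "tr_s", positive = TRUE)
  check_num(window_s, "window_s", positive = TRUE)
  Ym <- if (is.null(dim(series))) matrix(series, ncol = 1) else as.matrix(series)
  nv <- nrow(Ym)
  s <- stim_at_tr(stim, tr_s, nv)
  nlag <- floor(window_s / tr_s) + 1L
  if (nv < nlag + 2L)
    stopf("under-determined FIR system: %d time points for %d lags", nv, nlag)
  X <- sapply(seq_len(nlag) - 1L, function(l) c(rep(0, l), s[seq_len(nv - l)]))
  X <- cbind(1, X)
  if (qr(X)$rank < ncol(X))
    stopf("under-determined FIR system: too few events for %d lags", nlag)
  beta <- solve(crossprod(X), crossprod(X, Ym))
  hrf <- beta[-1, , drop = FALSE]
  list(lags_s = (seq_len(nlag) - 1L) * tr_s,
       hrf = if (is.null(dim(series))) drop(hrf) else hrf)
}

## Stimulus indicator on the TR grid: fraction of an event covering the
## TR-wide bin centred on each volume's acquisition time (v-1)*TR.
stim_at_tr <- function(stim, tr_s, n_vols, dense = 50L) {
  tt <- ((seq_len(n_vols * dense) - 0.5) / dense - 0.5) * tr_s
  box <- sample_boxcar(stim, tt)
  colMeans(matrix(box, nrow = dense))
}
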