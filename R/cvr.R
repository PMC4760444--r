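# Preprocessing ---------------------------------------------------------------

# 1D Gaussian kernel as a banded convolution matrix, renormalized to sum 1
gaussian_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmax(1L, i - r):pmin(n, i + r)
    K[i, j] <- k[j - i + r + 1]
  }
  K
}

# separable 3D convolution of one volume via per-axis matrix products
conv3_separable <- function(vol, kx, ky, kz) {
  d <- dim(vol)
  m <- kx %*% matrix(vol, d[1], d[2] * d[3])
  vol <- array(m, d)
  vol <- aperm(vol, c(2, 1, 3))
  m <- ky %*% matrix(vol, d[2], d[1] * d[3])
  vol <- aperm(array(m, d[c(2, 1, 3)]), c(2, 1, 3))
  vol <- aperm(vol, c(3, 1, 2))
  m <- kz %*% matrix(vol, d[3], d[1] * d[2])
  aperm(array(m, d[c(3, 1, 2)]), c(2, 3, 1))
}

#' Spatially smooth a BOLD series with a Gaussian kernel
#'
#' Each volume is convolved with a separable 3D Gaussian of the requested
#' full-width-at-half-maximum, converted to per-axis voxel units via
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`. Smoothing is mask-aware: the
#' masked data and the mask itself are smoothed and their ratio taken, so
#' intensities near the brain edge are renormalized rather than diluted by
#' the background.
#'
#' @param series A [bold_series()].
#' @param fwhm_mm Kernel FWHM in mm; 0 returns the series unchanged.
#' @return A smoothed [bold_series()].
#' @export
smooth_spatial <- function(series, fwhm_mm = 6) {
  stopifnot(inherits(series, "bold_series"))
  if (fwhm_mm < 0) stop("fwhm must be non-negative")
  if (fwhm_mm == 0) return(series)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / series$voxel_size
  d <- dim(series$data)
  kx <- gaussian_conv_matrix(d[1], sigma_vox[1])
  ky <- gaussian_conv_matrix(d[2], sigma_vox[2])
  kz <- gaussian_conv_matrix(d[3], sigma_vox[3])
  m <- series$mask + 0
  sm_mask <- conv3_separable(m, kx, ky, kz)
  out <- series$data
  for (t in seq_len(d[4])) {
    sv <- conv3_separable(series$data[, , , t] * m, kx, ky, kz)
    v <- array(0, d[1:3])
    inside <- sm_mask > 1e-8
    v[inside] <- sv[inside] / sm_mask[inside]
    v[!series$mask] <- series$data[, , , t][!series$mask]
    out[, , , t] <- v
  }
  series$data <- out
  series
}

#' Temporal high-pass filter by Gaussian-weighted running line subtraction
#'
#' For every voxel, a straight line is fit at each time point by weighted
#' least squares with Gaussian weights of width `sigma_s` centred on that
#' point; the fitted local trend is subtracted and the voxel's temporal mean
#' restored. Slow drifts are removed while fluctuations on time scales well
#' below `sigma_s` pass. The trend is a linear smoother, so its hat matrix is
#' precomputed once and applied to all voxels.
#'
#' @param series A [bold_series()].
#' @param sigma_s Gaussian width of the running-line fit, seconds. The
#'   default passes a multi-minute stepped stimulus protocol.
#' @param allow_short Set `TRUE` to override the guard against `sigma_s`
#'   shorter than `2 * TR`, which would remove nearly everything.
#' @return A filtered [bold_series()].
#' @export
highpass_temporal <- function(series, sigma_s = 50, allow_short = FALSE) {
  stopifnot(inherits(series, "bold_series"))
  if (sigma_s <= 0) stop("sigma_s must be positive")
  if (sigma_s < 2 * series$tr && !allow_short) {
    stop("sigma_s shorter than 2*TR removes the signal of interest; ",
         "set allow_short = TRUE to override")
  }
  d <- dim(series$data)
  H <- running_line_hat(d[4], series$tr, sigma_s)
  flat <- t(matrix(series$data, prod(d[1:3]), d[4]))  # t x voxels
  trend <- H %*% flat
  mu <- colMeans(flat)
  flat <- flat - trend + matrix(mu, d[4], ncol(flat), byrow = TRUE)
  series$data <- array(t(flat), d)
  series
}

# hat matrix of the Gaussian-weighted running-line trend estimate
running_line_hat <- function(n_t, tr, sigma_s) {
  tt <- (seq_len(n_t) - 1) * tr
  H <- matrix(0, n_t, n_t)
  for (i in seq_len(n_t)) {
    w <- stats::dnorm(tt - tt[i], sd = sigma_s)
    X <- cbind(1, tt - tt[i])
    XtW <- t(X * w)
    H[i, ] <- solve(XtW %*% X, XtW)[1, ]  # prediction at tt[i]
  }
  H
}

# apply the same high-pass to a regressor as to the data (mean restored), so
# the GLM compares like with like and slow stimulus components are not
# attenuated out of the data alone
highpass_vector <- function(v, H) {
  as.vector(v - H %*% v) + mean(v)
}

# GLM -------------------------------------------------------------------------

#' Build the CVR design matrix
#'
#' Columns: intercept; mean-centred petCO2 (explanatory, mmHg); mean-centred
#' SpO2 (nuisance, fraction, computed from the delay-corrected petO2 series
#' via [severinghaus_spo2()]).
#'
#' @param series Aligned end-tidal series (tibble with `petco2`, `peto2`).
#' @param include_spo2 Include the SpO2 nuisance column.
#' @param filter_hat Optional running-line hat matrix; when the data were
#'   high-pass filtered the regressors must pass through the same filter.
#' @return Numeric matrix with columns `intercept`, `petco2`, and optionally
#'   `spo2`.
#' @export
cvr_design <- function(series, include_spo2 = TRUE, filter_hat = NULL) {
  pet <- series$petco2
  spo2 <- if (include_spo2) severinghaus_spo2(series$peto2) else NULL
  if (!is.null(filter_hat)) {
    pet <- highpass_vector(pet, filter_hat)
    if (!is.null(spo2) && stats::sd(spo2) > 0) {
      spo2 <- highpass_vector(spo2, filter_hat)
    }
  }
  X <- cbind(intercept = rep(1, nrow(series)),
             petco2 = pet - mean(pet))
  if (include_spo2) {
    X <- cbind(X, spo2 = spo2 - mean(spo2))
  }
  if (qr(X)$rank < ncol(X)) {
    # a perfectly clamped petO2 gives a constant, hence empty, SpO2 column
    keep <- c(TRUE, TRUE, apply(X[, -(1:2), drop = FALSE], 2, stats::sd) > 0)
    X <- X[, keep, drop = FALSE]
    if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  }
  X
}

#' Fit the voxelwise GLM
#'
#' Ordinary least squares of every in-mask voxel time course on the design.
#' The baseline mean used later for percent normalization is the voxel
#' temporal mean of the series handed in (the high-pass filter preserves it).
#'
#' @param series A preprocessed [bold_series()].
#' @param design Design matrix from [cvr_design()]; must contain a `petco2`
#'   column and be full rank.
#' @return An object of class `glm_result`: per-voxel arrays `beta_petco2`,
#'   `se_petco2`, `sigma2`, `baseline`, plus `dof`, the `mask` and residuals.
#' @export
fit_glm <- function(series, design) {
  stopifnot(inherits(series, "bold_series"))
  n_t <- n_volumes(series)
  stopifnot(nrow(design) == n_t, "petco2" %in% colnames(design))
  rank <- qr(design)$rank
  if (rank < ncol(design)) stop("design matrix is rank deficient")
  dof <- n_t - rank
  if (dof < 1) stop("not enough volumes for the design")

  dims <- dim(series$data)[1:3]
  vox <- which(as.vector(series$mask))
  Y <- matrix(series$data, prod(dims), n_t)[vox, , drop = FALSE]
  baseline <- rowMeans(Y)

  XtX_inv <- solve(crossprod(design))
  B <- XtX_inv %*% crossprod(design, t(Y))        # coef x voxels
  res <- t(Y) - design %*% B                      # t x voxels
  sigma2 <- colSums(res^2) / dof
  j <- which(colnames(design) == "petco2")
  se <- sqrt(sigma2 * XtX_inv[j, j])

  to_map <- function(v) {
    a <- array(NA_real_, dims)
    a[vox] <- v
    a
  }
  structure(
    list(
      beta_petco2 = to_map(B[j, ]),
      se_petco2 = to_map(se),
      sigma2 = to_map(sigma2),
      baseline = to_map(baseline),
      dof = dof,
      mask = series$mask,
      voxel_size = series$voxel_size,
      residuals = res,
      vox_index = vox,
      dims = dims
    ),
    class = "glm_result"
  )
}

#' Convert petCO2 parameter estimates to a CVR map
#'
#' CVR in percent signal change per mmHg:
#' `100 * beta_petco2 / baseline mean`, sign preserved. Voxels with
#' non-positive baseline cannot be percent-normalized; they are dropped from
#' the mask and their count recorded in the `n_dropped` attribute.
#'
#' @param fit A [fit_glm()] result.
#' @return List of class `cvr_map`: `cvr` array (% per mmHg, NaN outside the
#'   mask), `mask`, `voxel_size`.
#' @export
cvr_from_glm <- function(fit) {
  stopifnot(inherits(fit, "glm_result"))
  bad <- fit$mask & !is.na(fit$baseline) & fit$baseline <= 0
  mask <- fit$mask & !bad
  cvr <- array(NaN, dim(fit$beta_petco2))
  cvr[mask] <- 100 * fit$beta_petco2[mask] / fit$baseline[mask]
  structure(
    list(cvr = cvr, mask = mask, voxel_size = fit$voxel_size,
         n_dropped = sum(bad)),
    class = "cvr_map"
  )
}

#' z-statistic map from the GLM fit
#'
#' The petCO2 t-statistic at the fit's degrees of freedom is mapped through
#' the t cumulative probability to the standard normal quantile, preserving
#' sign. Degenerate statistics (zero residual variance) and overflow are
#' clipped to +/-38, about the largest z a double can represent a tail
#' probability for.
#'
#' @param fit A [fit_glm()] result.
#' @return List of class `stat_map`: `z` array, `dof`, `mask`, `voxel_size`,
#'   and `n_clipped`.
#' @export
zstat_map <- function(fit) {
  stopifnot(inherits(fit, "glm_result"))
  if (fit$dof < 1) stop("needs at least one residual degree of freedom")
  tval <- array(NA_real_, dim(fit$beta_petco2))
  m <- fit$mask
  tval[m] <- fit$beta_petco2[m] / fit$se_petco2[m]
  # voxels whose residual variance is numerical dust relative to their signal
  # level: a zero beta there is a perfectly flat fit, not evidence
  tol <- 1e-9 * pmax(abs(fit$baseline[m]), 1)
  deg <- fit$se_petco2[m] < tol
  tval[m][deg] <- ifelse(abs(fit$beta_petco2[m][deg]) < tol[deg], 0,
                         sign(fit$beta_petco2[m][deg]) * Inf)
  z <- t_to_z(tval, fit$dof)
  n_clip <- sum(abs(z[m]) >= 38 | !is.finite(tval[m]), na.rm = TRUE)
  z[m & !is.finite(z)] <- 0
  structure(
    list(z = z, dof = fit$dof, mask = m, voxel_size = fit$voxel_size,
         n_clipped = n_clip),
    class = "stat_map"
  )
}

# t -> z through matched tail probabilities, numerically stable in the tails
t_to_z <- function(tval, dof) {
  z <- tval
  ok <- is.finite(tval)
  lt <- stats::pt(abs(tval[ok]), dof, lower.tail = FALSE, log.p = TRUE)
  zz <- stats::qnorm(lt, lower.tail = FALSE, log.p = TRUE)
  z[ok] <- sign(tval[ok]) * pmin(zz, 38)
  z[!ok & !is.na(tval)] <- sign(tval[!ok & !is.na(tval)]) * 38
  z
}

# Resel correction ------------------------------------------------------------

#' Estimate map smoothness and resel count from GLM residuals
#'
#' Residuals (not the data, which carry the stimulus) are standardized and
#' their lag-1 spatial autocorrelation `rho` computed along each axis, pooled
#' over volumes. Under a Gaussian autocorrelation model the kernel FWHM along
#' axis i is `sqrt(4*log(2) / (-2*log(rho_i)))` voxels. Estimates are floored
#' at 1 voxel (white noise), so the resel count — mask volume divided by the
#' FWHM product, the number of effectively independent samples in the map —
#' never exceeds the voxel count.
#'
#' @param fit A [fit_glm()] result carrying residuals, or a plain t-by-voxel
#'   residual matrix plus `mask`.
#' @param mask,dims Only needed when `fit` is a matrix.
#' @return List of class `smoothness_estimate`: `fwhm_vox` (per axis),
#'   `resel_count`, `search_voxels`.
#' @export
estimate_smoothness <- function(fit, mask = NULL, dims = NULL) {
  if (inherits(fit, "glm_result")) {
    res <- fit$residuals
    mask <- fit$mask
    dims <- fit$dims
    vox <- fit$vox_index
  } else {
    res <- fit
    stopifnot(!is.null(mask), !is.null(dims))
    vox <- which(as.vector(mask))
  }
  if (nrow(res) < 2) stop("need at least two residual volumes")
  if (sum(mask) < 27) stop("mask smaller than 3x3x3 voxels")

  # standardize each voxel's residual time course
  s <- sqrt(colMeans(res^2))
  s[s == 0] <- 1
  res <- res / matrix(s, nrow(res), ncol(res), byrow = TRUE)

  rho <- numeric(3)
  for (ax in 1:3) {
    num <- 0
    den <- 0
    shift <- c(0, 0, 0)
    shift[ax] <- 1
    idx <- arrayInd(vox, dims)
    nb <- sweep(idx, 2, shift, "+")
    ok <- nb[, ax] <= dims[ax]
    nb_lin <- (nb[, 3] - 1) * dims[1] * dims[2] + (nb[, 2] - 1) * dims[1] + nb[, 1]
    pos <- match(nb_lin[ok], vox)
    pair <- which(ok)[!is.na(pos)]
    pos <- pos[!is.na(pos)]
    if (length(pos) < 2) {
      rho[ax] <- 0
      next
    }
    a <- res[, pair, drop = FALSE]
    b <- res[, pos, drop = FALSE]
    rho[ax] <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  rho[!is.finite(rho)] <- 0  # exactly-zero residuals carry no smoothness
  fwhm <- rep(1, 3)
  pos <- rho > 0 & rho < 1
  fwhm[pos] <- pmax(1, sqrt(4 * log(2) / (-2 * log(rho[pos]))))
  v <- sum(mask)
  structure(
    list(fwhm_vox = fwhm, resel_count = max(1, v / prod(fwhm)),
         search_voxels = v, rho = rho),
    class = "smoothness_estimate"
  )
}

#' Resel-corrected z threshold
#'
#' The smallest z* at which the expected number of false positives among
#' `resel_count` effectively independent samples is `alpha`:
#' `resel_count * P(|Z| > z*) = alpha` (two-sided by default). Because the
#' resel count of a smooth map is far below its voxel count, this threshold
#' is less conservative than a voxelwise Bonferroni correction.
#'
#' @param smoothness A [estimate_smoothness()] result, or a bare resel count.
#' @param alpha Family-wise error target in (0, 1).
#' @param two_sided Two-sided thresholding (the default: negative CVR is a
#'   finding, not noise).
#' @return List: `z_threshold`, `alpha`, `n_comparisons`, `two_sided`.
#' @export
resel_corrected_threshold <- function(smoothness, alpha = 0.05,
                                      two_sided = TRUE) {
  r <- if (inherits(smoothness, "smoothness_estimate")) {
    smoothness$resel_count
  } else {
    as.numeric(smoothness)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  p_vox <- alpha / r
  z <- if (two_sided) {
    stats::qnorm(p_vox / 2, lower.tail = FALSE)
  } else {
    stats::qnorm(p_vox, lower.tail = FALSE)
  }
  list(z_threshold = z, alpha = alpha, n_comparisons = r,
       two_sided = two_sided)
}

#' Threshold a z map into a significance mask
#'
#' Voxels with `|z| >= threshold` whose CVR estimate matches the requested
#' sign. z and CVR share sign by construction (both are scaled versions of
#' the same beta), so the sign filter acts on either equivalently; the CVR
#' map is used.
#'
#' @param stat A [zstat_map()] result.
#' @param cvr_map A [cvr_from_glm()] result on the same grid.
#' @param threshold Positive z threshold (e.g. from
#'   [resel_corrected_threshold()]).
#' @param sign `"both"`, `"positive"` or `"negative"`.
#' @return Logical 3D array.
#' @export
significant_mask <- function(stat, cvr_map, threshold,
                             sign = c("both", "positive", "negative")) {
  sign <- match.arg(sign)
  thr <- if (is.list(threshold)) threshold$z_threshold else threshold
  if (thr <= 0) stop("threshold must be positive")
  m <- stat$mask & cvr_map$mask & !is.na(stat$z) & abs(stat$z) >= thr
  if (sign == "positive") m <- m & cvr_map$cvr > 0
  if (sign == "negative") m <- m & cvr_map$cvr < 0
  m & !is.na(m)
}

# Orchestration ----------------------------------------------------------------

#' Map CVR from a BOLD series and an end-tidal series
#'
#' Runs the full single-session pipeline: optional motion/slice-timing hooks
#' (identity by default; phantoms are motion-free), spatial smoothing,
#' temporal high-pass, cross-correlation delay alignment of the end-tidal
#' regressors to the whole-brain BOLD signal, voxelwise GLM with petCO2 as
#' the explanatory and SpO2 as the nuisance variable, CVR and z maps,
#' residual-based smoothness estimation and the resel-corrected significance
#' threshold.
#'
#' @param series A [bold_series()].
#' @param end_tidal Per-volume end-tidal series (tibble with `petco2`,
#'   `peto2`), e.g. from [resample_to_tr()].
#' @param fwhm_mm Spatial smoothing FWHM, mm (0 disables).
#' @param highpass_sigma_s Temporal high-pass width, seconds (NULL disables).
#' @param max_lag_s Delay search range, seconds.
#' @param alpha Family-wise error target for the significance mask.
#' @param two_sided Threshold both signs.
#' @param motion_correct,slice_time Hook functions `(bold_series) ->
#'   bold_series`; identity by default.
#' @return An object of class `cvr_fit` bundling the CVR map, z map,
#'   significance mask, smoothness estimate, threshold, applied lag and the
#'   GLM fit. `glance()` summarizes the run; `tidy()` returns a per-voxel
#'   tibble.
#' @export
map_cvr <- function(series, end_tidal,
                    fwhm_mm = 6, highpass_sigma_s = 50,
                    max_lag_s = 20, alpha = 0.05, two_sided = TRUE,
                    motion_correct = identity, slice_time = identity) {
  stopifnot(inherits(series, "bold_series"))
  series <- slice_time(motion_correct(series))
  if (fwhm_mm > 0) series <- smooth_spatial(series, fwhm_mm)
  H <- NULL
  if (!is.null(highpass_sigma_s)) {
    H <- running_line_hat(n_volumes(series), series$tr, highpass_sigma_s)
    series <- highpass_temporal(series, highpass_sigma_s)
  }
  aligned <- align_to_bold(end_tidal, global_signal(series), series$tr,
                           max_lag_s = max_lag_s)
  design <- cvr_design(aligned$series, filter_hat = H)
  fit <- fit_glm(series, design)
  cvr <- cvr_from_glm(fit)
  z <- zstat_map(fit)
  sm <- estimate_smoothness(fit)
  thr <- resel_corrected_threshold(sm, alpha = alpha, two_sided = two_sided)
  sig <- significant_mask(z, cvr, thr, sign = "both")
  structure(
    list(
      cvr = cvr, z = z, significant = sig,
      smoothness = sm, threshold = thr,
      lag_s = aligned$lag_s, lag_volumes = aligned$lag_volumes,
      glm = fit,
      params = list(fwhm_mm = fwhm_mm, highpass_sigma_s = highpass_sigma_s,
                    max_lag_s = max_lag_s, alpha = alpha,
                    two_sided = two_sided)
    ),
    class = "cvr_fit"
  )
}

#' @export
print.cvr_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0("<cvr_fit> %d voxels, lag %.3g s, FWHM (%.2f, %.2f, %.2f) vox, ",
           "%.0f resels, |z| >= %.3f (alpha %.3g), %d significant\n"),
    g$n_voxels, g$lag_s, x$smoothness$fwhm_vox[1], x$smoothness$fwhm_vox[2],
    x$smoothness$fwhm_vox[3], g$resel_count, g$z_threshold, g$alpha,
    g$n_significant
  ))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
glance.cvr_fit <- function(x, ...) {
  tibble::tibble(
    n_voxels = sum(x$cvr$mask),
    lag_s = x$lag_s,
    dof = x$glm$dof,
    fwhm_x = x$smoothness$fwhm_vox[1],
    fwhm_y = x$smoothness$fwhm_vox[2],
    fwhm_z = x$smoothness$fwhm_vox[3],
    resel_count = x$smoothness$resel_count,
    z_threshold = x$threshold$z_threshold,
    alpha = x$threshold$alpha,
    n_significant = sum(x$significant),
    mean_cvr = mean(x$cvr$cvr[x$cvr$mask])
  )
}

#' @export
tidy.cvr_fit <- function(x, ...) {
  idx <- which(x$cvr$mask)
  ijk <- arrayInd(idx, dim(x$cvr$cvr))
  tibble::tibble(
    i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
    cvr = x$cvr$cvr[idx],
    z = x$z$z[idx],
    significant = x$significant[idx]
  )
}

#' Write the outputs of a CVR fit as NIfTI volumes plus a JSON sidecar
#'
#' @param fit A [map_cvr()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the sidecar path.
#' @export
write_cvr_fit <- function(fit, dir, prefix = "cvr") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- fit$cvr$voxel_size
  write_volume(fit$cvr$cvr, file.path(dir, paste0(prefix, "_map.nii.gz")), vs)
  write_volume(fit$z$z, file.path(dir, paste0(prefix, "_zstat.nii.gz")), vs)
  write_volume(fit$significant, file.path(dir, paste0(prefix, "_sig.nii.gz")), vs)
  sidecar <- file.path(dir, paste0(prefix, "_run.json"))
  jsonlite::write_json(
    list(
      lag_s = fit$lag_s,
      fwhm_vox = fit$smoothness$fwhm_vox,
      resel_count = fit$smoothness$resel_count,
      z_threshold = fit$threshold$z_threshold,
      alpha = fit$threshold$alpha,
      two_sided = fit$threshold$two_sided,
      params = fit$params,
      package_version = as.character(utils::packageVersion("cvrmap"))
    ),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(sidecar)
}
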