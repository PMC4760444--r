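test_that("spatial smoothing is identity at fwhm 0 and preserves constants", {
  fx <- fix_noiseless_fit()
  bs <- fx$series
  expect_identical(smooth_spatial(bs, 0)$data, bs$data)
  const <- bold_series(array(7, c(8, 8, 8, 2)), tr = 2, voxel_size = c(3, 3, 3))
  smc <- smooth_spatial(const, 6)
  expect_equal(smc$data, const$data, tolerance = 1e-10)
  expect_error(smooth_spatial(const, -1), "non-negative")
})

test_that("a delta impulse smooths to the analytic discrete Gaussian", {
  d <- array(0, c(15, 15, 15, 1))
  d[8, 8, 8, 1] <- 1
  bs <- bold_series(d, tr = 2, voxel_size = c(3, 3, 3))
  sm <- smooth_spatial(bs, 6)$data[, , , 1]
  # FWHM 6 mm at 3 mm voxels = 2 voxels: value at offset 1 is half the peak
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3
  expect_equal(sm[9, 8, 8] / sm[8, 8, 8], exp(-1 / (2 * sigma^2)),
               tolerance = 1e-6)
  expect_equal(sm[9, 8, 8] / sm[8, 8, 8], 0.5, tolerance = 1e-6)
  # separable: diagonal neighbour is the product of axis ratios
  expect_equal(sm[9, 9, 8] / sm[8, 8, 8], 0.25, tolerance = 1e-6)
})

test_that("high-pass removes slow drift but passes fast oscillation", {
  n_t <- 150
  tt <- (seq_len(n_t) - 1) * 2
  osc <- sin(2 * pi * tt / 20)        # 20 s period, well under sigma
  drift <- 0.05 * tt                  # slow linear trend
  d <- array(0, c(2, 2, 2, n_t))
  d[1, 1, 1, ] <- 100 + drift
  d[2, 1, 1, ] <- 100 + drift + osc
  d[1, 2, 1, ] <- 55                  # constant voxel
  bs <- bold_series(d, tr = 2, voxel_size = c(3, 3, 3))
  hp <- highpass_temporal(bs, sigma_s = 50)$data
  # drift voxel: flat after filtering, mean preserved
  expect_lt(stats::sd(hp[1, 1, 1, ]), 0.05 * stats::sd(drift))
  expect_equal(mean(hp[1, 1, 1, ]), mean(100 + drift), tolerance = 1e-9)
  # oscillation amplitude preserved within 5%
  amp <- function(y) {
    co <- stats::lm(y ~ sin(2 * pi * tt / 20) + cos(2 * pi * tt / 20))$coefficients
    sqrt(sum(co[2:3]^2))
  }
  expect_equal(amp(hp[2, 1, 1, ]), 1, tolerance = 0.05)
  # constant voxel unchanged
  expect_equal(hp[1, 2, 1, ], rep(55, n_t), tolerance = 1e-9)
  expect_error(highpass_temporal(bs, sigma_s = 3), "allow_short")
})

test_that("voxelwise GLM matches closed-form OLS on a two-level design", {
  # 20 volumes, petCO2 steps 0 -> 10, signal rises 2%
  x <- c(rep(0, 10), rep(10, 10))
  s0 <- 500
  y <- s0 * (1 + 0.002 * x)
  d <- array(rep(y, each = 8), c(2, 2, 2, 20))
  bs <- bold_series(d, tr = 2, voxel_size = c(3, 3, 3))
  et <- tibble::tibble(petco2 = x, peto2 = 100)
  fit <- fit_glm(bs, cvr_design(et))
  # closed form two-group OLS slope: (mean(y1) - mean(y0)) / (x1 - x0)
  slope <- (mean(y[11:20]) - mean(y[1:10])) / 10
  expect_equal(fit$beta_petco2[1, 1, 1], slope, tolerance = 1e-10)
  expect_equal(fit$beta_petco2[1, 1, 1], 1.0, tolerance = 1e-10)
  expect_equal(fit$sigma2[1, 1, 1], 0, tolerance = 1e-10)
  expect_equal(fit$dof, 20 - 2)  # constant SpO2 column is dropped
  expect_equal(fit$baseline[1, 1, 1], mean(y))
})

test_that("GLM betas agree with lm() on randomized small instances", {
  set.seed(31)
  for (rep in 1:5) {
    n_t <- 30
    et <- tibble::tibble(petco2 = stats::rnorm(n_t, 40, 4),
                         peto2 = stats::rnorm(n_t, 100, 3))
    y <- 300 + 2 * et$petco2 + stats::rnorm(n_t, 0, 5)
    d <- array(y, c(1, 1, 1, n_t))
    bs <- bold_series(d, tr = 2, voxel_size = c(3, 3, 3))
    X <- cvr_design(et)
    fit <- fit_glm(bs, X)
    ref <- stats::lm(y ~ X[, "petco2"] + X[, "spo2"])
    expect_equal(fit$beta_petco2[1, 1, 1], unname(stats::coef(ref)[2]),
                 tolerance = 1e-9)
    expect_equal(fit$se_petco2[1, 1, 1],
                 unname(summary(ref)$coefficients[2, 2]), tolerance = 1e-9)
  }
})

test_that("rank-deficient designs are rejected", {
  bs <- bold_series(array(1:64, c(2, 2, 2, 8)), tr = 2, voxel_size = c(3, 3, 3))
  X <- cbind(intercept = rep(1, 8), petco2 = rep(2, 8))
  expect_error(fit_glm(bs, X), "rank deficient")
})

test_that("CVR conversion is percent-per-mmHg with sign preserved", {
  fx <- fix_noiseless_fit()
  tru <- fx$series$truth
  cvr <- fx$fit$cvr
  m_pos <- tru$cvr == 0.30
  m_wm <- tru$cvr == 0.15
  m_neg <- tru$cvr == -0.20
  expect_lt(abs(mean(cvr$cvr[m_pos]) - 0.300), 0.003)
  expect_lt(abs(mean(cvr$cvr[m_wm]) - 0.150), 0.003)
  expect_lt(abs(mean(cvr$cvr[m_neg]) + 0.200), 0.003)
})

test_that("CVR map is invariant to global intensity rescaling", {
  fx <- fix_noisy_fit()
  bs2 <- fx$series
  bs2$data <- bs2$data * 3.7
  et <- fix_trace()$series
  fit2 <- map_cvr(bs2, et, fwhm_mm = 0, highpass_sigma_s = 50)
  expect_equal(fit2$cvr$cvr, fx$fit$cvr$cvr, tolerance = 1e-9)
})

test_that("beta/baseline arithmetic and non-positive baselines are handled", {
  d <- array(0, c(2, 1, 1, 10))
  x <- c(rep(0, 5), rep(10, 5))
  d[1, 1, 1, ] <- 500 + 1.0 * (x - mean(x)) + 500 * 0  # baseline 500, beta 1
  d[1, 1, 1, ] <- 500 * (1 + 0.002 * (x - mean(x)))
  d[2, 1, 1, ] <- -5                                    # non-positive baseline
  bs <- bold_series(d, tr = 2, voxel_size = c(3, 3, 3))
  et <- tibble::tibble(petco2 = x, peto2 = 100)
  fit <- fit_glm(bs, cvr_design(et))
  cvr <- cvr_from_glm(fit)
  expect_equal(cvr$cvr[1, 1, 1], 100 * fit$beta_petco2[1, 1, 1] / 500,
               tolerance = 1e-10)
  expect_equal(cvr$cvr[1, 1, 1], 0.2, tolerance = 1e-10)
  expect_false(cvr$mask[2, 1, 1])
  expect_equal(cvr$n_dropped, 1)
})

test_that("t to z mapping matches numerical CDF evaluation and clips", {
  # frozen: qnorm(pt(2.5, df = 100)) = 2.4561
  z <- cvrmap:::t_to_z(2.5, 100)
  expect_equal(z, stats::qnorm(stats::pt(2.5, 100)), tolerance = 1e-9)
  expect_equal(z, 2.4561, tolerance = 1e-4)
  expect_equal(cvrmap:::t_to_z(0, 10), 0)
  expect_equal(cvrmap:::t_to_z(1.96, 1e8), 1.96, tolerance = 1e-4)
  expect_equal(cvrmap:::t_to_z(Inf, 10), 38)
  # heavy t tails: an extreme t at 5 dof is only a modest z, no clipping
  expect_equal(cvrmap:::t_to_z(-500, 5),
               stats::qnorm(stats::pt(500, 5, lower.tail = FALSE)),
               tolerance = 1e-9)
  # at large dof the same t is astronomical and clips
  expect_equal(cvrmap:::t_to_z(-500, 1000), -38)
  expect_equal(cvrmap:::t_to_z(-2.5, 100), -z)
})

test_that("z and CVR share sign voxelwise", {
  fx <- fix_noisy_fit()
  m <- fx$fit$cvr$mask & abs(fx$fit$cvr$cvr) > 1e-12
  expect_true(all(sign(fx$fit$z$z[m]) == sign(fx$fit$cvr$cvr[m])))
})

test_that("smoothness estimation recovers the applied kernel within 10%", {
  set.seed(12)
  dims <- c(22, 22, 22)
  mask <- array(TRUE, dims)
  n_t <- 12
  res <- matrix(0, n_t, prod(dims))
  kx <- cvrmap:::gaussian_conv_matrix(dims[1], 2 / (2 * sqrt(2 * log(2))))
  for (t in seq_len(n_t)) {
    v <- array(stats::rnorm(prod(dims)), dims)
    res[t, ] <- as.vector(cvrmap:::conv3_separable(v, kx, kx, kx))
  }
  sm <- estimate_smoothness(res, mask = mask, dims = dims)
  expect_equal(sm$fwhm_vox, rep(2, 3), tolerance = 0.1)
  # resel count is voxels over the FWHM product
  expect_equal(sm$resel_count, prod(dims) / prod(sm$fwhm_vox))

  # unsmoothed white noise: resel count within 25% of the voxel count
  res_w <- matrix(stats::rnorm(n_t * prod(dims)), n_t)
  sm_w <- estimate_smoothness(res_w, mask = mask, dims = dims)
  expect_equal(sm_w$resel_count, prod(dims), tolerance = 0.25)
  expect_error(estimate_smoothness(res_w[1, , drop = FALSE], mask, dims),
               "two residual")
})

test_that("resel-corrected thresholds invert the normal tail correctly", {
  # frozen: single comparison two-sided at 0.05 is 1.960
  expect_equal(resel_corrected_threshold(1, 0.05)$z_threshold,
               stats::qnorm(0.975), tolerance = 1e-9)
  # frozen numerical inversion: 1000 resels -> 4.056
  thr1000 <- resel_corrected_threshold(1000, 0.05)$z_threshold
  expect_equal(thr1000, 4.0556, tolerance = 1e-4)
  expect_equal(1000 * 2 * stats::pnorm(thr1000, lower.tail = FALSE), 0.05,
               tolerance = 1e-9)
  # less conservative than voxelwise Bonferroni on 8000 voxels (4.518)
  bonf <- stats::qnorm(0.05 / (2 * 8000), lower.tail = FALSE)
  expect_equal(bonf, 4.51777, tolerance = 1e-5)
  expect_lt(thr1000, bonf)
  expect_error(resel_corrected_threshold(1000, 1.2), "alpha")
})

test_that("significance masks honour threshold and sign", {
  fx <- fix_noiseless_fit()
  tru <- fx$series$truth
  sig <- fx$fit$significant
  # noiseless strong-CVR phantom: mask equals the true nonzero support
  expect_equal(sig, tru$cvr != 0 & fx$fit$cvr$mask)
  neg <- significant_mask(fx$fit$z, fx$fit$cvr, fx$fit$threshold,
                          sign = "negative")
  expect_equal(neg, tru$cvr < 0 & fx$fit$cvr$mask)
  # all-zero z map gives an empty mask
  z0 <- fx$fit$z
  z0$z[] <- 0
  expect_equal(sum(significant_mask(z0, fx$fit$cvr, 3)), 0)
})

test_that("gray:white CVR ratio of a 2:1 phantom is recovered within 10%", {
  fx <- fix_noisy_fit()
  tru <- fx$series$truth
  gm <- mean(fx$fit$cvr$cvr[tru$labels == 2 & tru$cvr > 0])
  wm <- mean(fx$fit$cvr$cvr[tru$labels == 3])
  expect_equal(gm / wm, 2, tolerance = 0.1)
})

test_that("cvr_fit glance and tidy expose the run summary", {
  fx <- fix_noisy_fit()
  g <- glance(fx$fit)
  expect_equal(g$lag_s, 6)
  expect_equal(g$n_voxels, sum(fx$fit$cvr$mask))
  td <- tidy(fx$fit)
  expect_equal(nrow(td), g$n_voxels)
  expect_true(all(c("cvr", "z", "significant") %in% names(td)))
})
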