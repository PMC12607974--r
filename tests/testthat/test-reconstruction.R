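test_that("spectral rendering obeys the white-point normalisation and linearity", {
  ones <- rep(1, 401)
  wp <- render_spectrum(ones)
  expect_equal(unname(wp["Y"]), 100)
  expect_equal(unname(render_spectrum(rep(0, 401))), c(0, 0, 0))
  set.seed(2)
  s <- runif(401)
  expect_equal(render_spectrum(s / 2), render_spectrum(s) / 2, tolerance = 1e-12)
  bad_ill <- list(wavelengths = 380:779, power = rep(1, 400))
  expect_error(render_spectrum(ones, bad_ill, cmf_cie1931()), "grid")
  expect_error(render_spectrum(rep(1, 400)), "401")
})

test_that("a zero-variance chart yields a zero-component model returning the mean", {
  R <- matrix(0.4, 401, 24)
  chart <- chart_from_spectra(R)
  calib <- fit_correction(chart, chart_camera_xyz(chart))
  recon <- fit_reconstruction(chart, calib)
  expect_identical(recon$k, 0L)
  spec <- reconstruct_spectrum(recon, calib, c(0.9, 0.1, 0.4))
  expect_equal(spec, rep(0.4, 401), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(fit_reconstruction(chart, calib, variance_threshold = 0),
               "variance_threshold")
  expect_error(fit_reconstruction(chart, calib, variance_threshold = 1.2),
               "variance_threshold")
})

test_that("rank-3 synthetic ensembles are recovered with k = 3 across a 20-seed sweep", {
  for (seed in 1:20) {
    models <- closed_loop_models(seed)
    expect_identical(models$recon$k, 3L)
    expect_gte(models$recon$variance_retained, 0.999)
    # singular values beyond rank 3 vanish (brute-force check)
    sv <- svd(models$chart$reflectance_ref -
                rowMeans(models$chart$reflectance_ref))$d
    expect_lt(sv[4] / sv[1], 1e-10)
  }
})

test_that("the PCA basis is orthonormal and spans the training spectra at full rank", {
  models <- closed_loop_models(4)
  B <- models$recon$basis
  expect_equal(B %*% t(B), diag(nrow(B)), tolerance = 1e-8)
  # with every component retained, PCA reconstruction of training spectra
  # is exact
  R <- models$chart$reflectance_ref
  full <- fit_reconstruction(models$chart, models$calib,
                             variance_threshold = 1)
  Bf <- full$basis
  Xc <- R - rowMeans(R)
  expect_equal(t(Bf) %*% (Bf %*% Xc), Xc, tolerance = 1e-8)
})

test_that("training chart patches reconstruct their reference spectra", {
  models <- closed_loop_models(6)
  expect_lte(max(models$recon$train_rmse), 0.05)
  for (j in c(1, 12, 24)) {
    spec <- reconstruct_spectrum(models$recon, models$calib,
                                 models$chart$rgb_measured[j, ])
    expect_lte(spectral_rmse(spec, models$chart$reflectance_ref[, j]), 0.05)
  }
  # determinism: identical colours give identical spectra
  rgb <- models$chart$rgb_measured[5, ]
  expect_identical(reconstruct_spectrum(models$recon, models$calib, rgb),
                   reconstruct_spectrum(models$recon, models$calib, rgb))
})

test_that("a colour rendered from the mean spectrum reconstructs near the mean", {
  models <- closed_loop_models(8)
  mean_spec <- models$recon$mean_spectrum
  rgb <- render_with_camera(models$cam, mean_spec)
  spec <- reconstruct_spectrum(models$recon, models$calib, rgb)
  expect_lte(spectral_rmse(spec, mean_spec), 0.05)
})

test_that("training spectral error is nonincreasing in the component count", {
  # a full-spread chart outside the rank-3 family: smooth random spectra
  set.seed(21)
  wl <- spectral_grid()
  R <- sapply(1:24, function(i) {
    co <- runif(6, -1, 1)
    bumps <- t(sapply(runif(6, 400, 760),
                      function(mu) exp(-0.5 * ((wl - mu) / 40)^2)))
    pmin(pmax(0.45 + colSums(0.05 * co * bumps), 0), 1)
  })
  chart <- chart_from_spectra(R)
  calib <- fit_correction(chart, chart_camera_xyz(chart))
  ev <- svd(R - rowMeans(R))$d^2
  cumvar <- cumsum(ev) / sum(ev)
  # pooled training RMSE over all patches, per component count
  rmse_by_k <- sapply(1:6, function(k) {
    thr <- if (k == 1) cumvar[1] / 2 else (cumvar[k - 1] + cumvar[k]) / 2
    m <- fit_reconstruction(chart, calib, variance_threshold = thr)
    stopifnot(m$k == k)
    sqrt(mean(m$train_rmse^2))
  })
  expect_true(all(diff(rmse_by_k) <= 1e-9))
})

test_that("whole-frame conversion matches per-pixel reconstruction and validates input", {
  models <- closed_loop_models(10)
  ph <- make_phantom(10, c(32, 32), "varicose")
  cube <- convert_image(models$recon, models$calib, ph$frame)
  expect_equal(dim(cube$data), c(32, 32, 401))
  # memoised path equals direct per-pixel reconstruction
  for (px in list(c(1, 1), c(17, 5), c(32, 32))) {
    direct <- reconstruct_spectrum(models$recon, models$calib,
                                   ph$frame[px[1], px[2], ])
    expect_equal(cube$data[px[1], px[2], ], direct, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # constant frame: all spectra identical
  flat <- array(rep(c(0.6, 0.5, 0.4), each = 4), dim = c(2, 2, 3))
  fc <- convert_image(models$recon, models$calib, flat)
  expect_identical(fc$data[1, 1, ], fc$data[2, 2, ])
  expect_error(convert_image(models$recon, models$calib,
                             array(0, dim = c(0, 4, 3))), "pixels")
  expect_error(convert_image(models$recon, models$calib,
                             array(0, dim = c(4, 4, 2))), "RGB")
})

test_that("direct-spectrum regression agrees with the score path on in-family data", {
  models <- closed_loop_models(12)
  direct <- fit_reconstruction(models$chart, models$calib, direct = TRUE)
  rgb <- models$chart$rgb_measured[7, ]
  expect_equal(reconstruct_spectrum(direct, models$calib, rgb),
               reconstruct_spectrum(models$recon, models$calib, rgb),
               tolerance = 1e-6)
})
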