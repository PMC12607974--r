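test_that("chart generation is seeded, bounded and 24 patches wide", {
  c1 <- make_chart(17)
  c2 <- make_chart(17)
  expect_identical(c1$reflectance_ref, c2$reflectance_ref)
  expect_false(identical(c1$reflectance_ref, make_chart(18)$reflectance_ref))
  expect_identical(dim(c1$reflectance_ref), c(401L, 24L))
  expect_true(all(c1$reflectance_ref >= 0 & c1$reflectance_ref <= 1))
  expect_identical(dim(c1$xyz_target), c(24L, 3L))
  # standard mode is deterministic regardless of seed
  expect_identical(make_chart(1, "standard")$reflectance_ref,
                   make_chart(99, "standard")$reflectance_ref)
  expect_error(make_chart(1, "fancy"), "arg")
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(77)
  before <- runif(1)
  set.seed(77)
  invisible(make_chart(5))
  invisible(make_phantom(5, c(32, 32), "normal"))
  expect_identical(runif(1), before)
})

test_that("the synthetic camera forward model is bilinear and matches rendering", {
  # scaled down so the doubled stimulus stays inside the sensor's range
  s <- 0.4 * make_chart(3)$reflectance_ref[, 1]
  # zero spectrum, identity transfer, no dark/noise -> exactly zero
  cam_id <- synthetic_camera(transfer = "identity")
  expect_equal(unname(render_with_camera(cam_id, rep(0, 401))), c(0, 0, 0))
  # doubling the illuminant is equivalent to doubling the spectrum
  # (direct mode, linear transfer, noiseless)
  sens <- with(cmf_cie1931(), rbind(xbar, ybar, zbar))
  cam_d <- synthetic_camera("direct", sensitivities = sens,
                            transfer = "identity")
  ill <- illuminant_led()
  ill2 <- list(wavelengths = ill$wavelengths, power = 2 * ill$power)
  # the white-point normaliser also rescales, so compare unnormalised effect
  k1 <- 1 / sum(ill$power * cmf_cie1931()$ybar)
  k2 <- 1 / sum(ill2$power * cmf_cie1931()$ybar)
  expect_equal(render_with_camera(cam_d, s, ill2) / k2,
               render_with_camera(cam_d, 2 * s, ill) / k1,
               tolerance = 1e-9)
  # CIE-matching sensitivities reproduce render_spectrum up to the Y scale
  got <- render_with_camera(cam_d, s, ill)
  expect_equal(unname(got) * 100, unname(render_spectrum(s, ill)),
               tolerance = 1e-9)
  expect_error(synthetic_camera("direct", sensitivities = matrix(1, 3, 10)),
               "401")
})

test_that("noisy cameras are seeded and reproducible", {
  s <- make_chart(4)$reflectance_ref
  cam <- synthetic_camera(noise_sd = 0.01, seed = 9)
  r1 <- render_with_camera(cam, s)
  r2 <- render_with_camera(cam, s)
  expect_identical(r1, r2)
  r3 <- render_with_camera(synthetic_camera(noise_sd = 0.01, seed = 10), s)
  expect_false(identical(r1, r3))
})

test_that("phantoms are deterministic with darkened vessels and valid cubes", {
  p1 <- make_phantom(21, c(32, 40), "inflammation")
  p2 <- make_phantom(21, c(32, 40), "inflammation")
  expect_identical(p1$frame, p2$frame)
  expect_identical(dim(p1$frame), c(32L, 40L, 3L))
  expect_identical(dim(p1$cube$data), c(32L, 40L, 401L))
  expect_true(any(p1$vessel_mask))
  b415 <- extract_band_image(p1$cube, 415, 10)
  expect_lt(mean(b415[p1$vessel_mask]), mean(b415[!p1$vessel_mask]))
  expect_true(all(p1$cube$data >= 0 & p1$cube$data <= 1))
  expect_error(make_phantom(1, c(16, 16), "normal"), "32")
  expect_error(make_phantom(1, c(32, 32), "polyp"), "unknown")
})

test_that("every phantom class produces a distinct mean colour signature", {
  sigs <- sapply(phantom_classes(), function(cl) {
    ph <- make_phantom(30, c(32, 32), cl, store_cube = FALSE)
    apply(ph$frame, 3, mean)
  })
  expect_gt(min(dist(t(sigs))), 0.01)
})

test_that("dataset generation honours the requested layout", {
  tmp <- withr::local_tempdir()
  counts <- data.frame(class = c("normal", "cancer", "staining"),
                       train = c(3L, 4L, 0L), validation = c(1L, 2L, 0L),
                       test = c(1L, 1L, 0L))
  man <- make_dataset(file.path(tmp, "ds"), seed = 2, counts = counts,
                      size = c(32, 32))
  man <- read.csv(file.path(tmp, "ds", "manifest.csv"))
  expect_identical(nrow(man), 12L)
  expect_identical(sum(man$split == "train"), 7L)
  # zero-count class omitted without error
  expect_false("staining" %in% man$class)
  expect_true(all(file.exists(file.path(tmp, "ds", man$path))))
  # frames are readable PNGs of the requested size
  f <- read_frame(file.path(tmp, "ds", man$path[1]))
  expect_identical(dim(f), c(32L, 32L, 3L))
  # reruns are byte-identical
  make_dataset(file.path(tmp, "ds2"), seed = 2, counts = counts,
               size = c(32, 32))
  a <- file.path(tmp, "ds", man$path[3]); b <- file.path(tmp, "ds2", man$path[3])
  expect_identical(unname(tools::md5sum(a)), unname(tools::md5sum(b)))
  expect_error(make_dataset(file.path(tmp, "bad"), counts =
    data.frame(class = "x", train = -1L, validation = 0L, test = 0L)),
    "nonnegative")
})
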