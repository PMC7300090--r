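test_that("fiber fields echo their ground truth and honor the angle model", {
  # empty field: background only, empty truth
  f0 <- simulateFiberField(fiberFieldSpec(n_fibers = 0, image_hw = c(64, 64),
                                          background_noise_sd = 0, seed = 1))
  expect_identical(nFibers(f0$truth$fibers), 0L)
  expect_identical(max(pixelArray(f0$image)), 0)

  # single specified capsule is echoed exactly
  f1 <- simulateFiberField(capsuleFieldSpec(width = 6, angle = 0))
  tr <- fiberMeasurements(f1$truth$fibers)
  expect_identical(nrow(tr), 1L)
  expect_equal(tr$length_px, 100, tolerance = 1e-6)
  expect_equal(tr$width_px, 6, tolerance = 1e-6)
  expect_lt(tr$angle_deg, 1e-3)

  # von Mises axial sampling concentrates at mu: oracle is the doubled-angle
  # vector mean computed directly from the ground-truth angles
  fv <- simulateFiberField(fiberFieldSpec(
    n_fibers = 500, image_hw = c(512, 512), seed = 77,
    angle_model = list(type = "von_mises_axial", mu_deg = 90, kappa = 8)))
  a2 <- 2 * fv$truth$fibers@fibers$angle_deg * pi / 180
  mu <- (atan2(mean(sin(a2)), mean(cos(a2))) * 90 / pi) %% 180
  expect_lt(min(abs(mu - 90), 180 - abs(mu - 90)), 3)
})

test_that("generated distribution moments converge to the model (n = 2000)", {
  spec <- fiberFieldSpec(n_fibers = 2000, image_hw = c(512, 512), seed = 23)
  tr <- simulateFiberField(spec)$truth$fibers@fibers
  expect_equal(median(tr$length_px), exp(spec$length_model$mu_log),
               tolerance = 0.05)
  expect_equal(median(tr$width_px), exp(spec$width_model$mu_log),
               tolerance = 0.05)
  expect_equal(mean(tr$length_px),
               exp(spec$length_model$mu_log + spec$length_model$sigma_log^2 / 2),
               tolerance = 0.05)
})

test_that("IHC fields carry exact per-cell labels and invert analytically", {
  # degenerate positive fractions are echoed exactly
  for (p in c(0, 1)) {
    f <- simulateIhcField(ihcFieldSpec(n_cells = 50, tumor_fraction = 1,
                                       positive_fraction = p, seed = 11))
    expect_identical(sum(f$truth$cells$is_positive), as.integer(50 * p))
  }

  # noise-free forward model is exactly invertible: -log then projection
  # onto the stain basis recovers the per-pixel densities
  f <- simulateIhcField(ihcFieldSpec(n_cells = 40, marker = "ECadherin",
                                     positive_fraction = 0.5,
                                     noise_sd_od = 0, seed = 2))
  dens <- deconvolveStains(rgbToOD(f$image), defaultStainVectors())
  for (s in names(f$densities))
    expect_lt(max(abs(dens[[s]] - f$densities[[s]])), 1e-6)

  # placement failure names the remedy
  expect_error(simulateIhcField(ihcFieldSpec(n_cells = 100,
                                             image_hw = c(70, 70))),
               "larger frame")
})

test_that("spheroid frames have disk geometry with optional protrusions", {
  s <- simulateSpheroidSeries(c(100, 80, 60), 0, c(256, 256), seed = 1)
  areas <- vapply(s, function(x) sum(maskMatrix(x$mask)), numeric(1))
  expect_equal(areas[1], pi * 50^2, tolerance = 0.02)
  expect_true(all(diff(areas) < 0))
  expect_identical(vapply(s, function(x) x$truth$diameter_px, numeric(1)),
                   c(100, 80, 60))

  sp <- simulateSpheroidSeries(100, 8, c(256, 256), seed = 2)[[1]]
  expect_gt(sum(maskMatrix(sp$mask)), areas[1])
})

test_that("vessel fields record exact counts and lumen areas", {
  v0 <- simulateVesselField(0, image_hw = c(128, 128), seed = 1)
  expect_identical(v0$truth$count, 0L)
  expect_identical(nrow(v0$truth$lumens), 0L)

  v <- simulateVesselField(35, c(8, 14), c(768, 768), seed = 3)
  expect_identical(v$truth$count, 35L)
  expect_identical(nrow(v$truth$lumens), 35L)
  # rendered pixel counts agree with the analytic disk areas within 5%
  expect_true(all(abs(v$truth$lumens$area_px_rendered -
                      v$truth$lumens$area_px) / v$truth$lumens$area_px < 0.05))
})

test_that("trichrome fields hit requested pixel counts exactly", {
  N <- 256 * 256
  t1 <- simulateTrichromeField(0.5, 0.5, c(256, 256), seed = 5)
  expect_identical(t1$truth$background_px, 0L)
  t2 <- simulateTrichromeField(0, 0, c(256, 256), seed = 5)
  expect_identical(t2$truth$background_px, as.integer(N))
  t3 <- simulateTrichromeField(0.3, 0.2, c(256, 256), seed = 5)
  expect_identical(t3$truth$blue_px, as.integer(round(0.3 * N)))
  expect_identical(t3$truth$red_px, as.integer(round(0.2 * N)))
})

test_that("equal specs give bit-identical images and ground truth", {
  a <- simulateFiberField(fiberFieldSpec(n_fibers = 25, image_hw = c(128, 128),
                                         seed = 9))
  b <- simulateFiberField(fiberFieldSpec(n_fibers = 25, image_hw = c(128, 128),
                                         seed = 9))
  expect_identical(pixelArray(a$image), pixelArray(b$image))
  expect_identical(a$truth$fibers@fibers, b$truth$fibers@fibers)

  i1 <- simulateIhcField(ihcFieldSpec(n_cells = 30, seed = 4))
  i2 <- simulateIhcField(ihcFieldSpec(n_cells = 30, seed = 4))
  expect_identical(pixelArray(i1$image), pixelArray(i2$image))
  expect_identical(i1$truth$cells, i2$truth$cells)

  v1 <- simulateVesselField(5, seed = 8)
  v2 <- simulateVesselField(5, seed = 8)
  expect_identical(pixelArray(v1$image), pixelArray(v2$image))
})
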