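test_that("spheroid diameter is protrusion-robust and matches disks", {
  cfg <- defaultConfig()
  disk <- simulateSpheroidSeries(100, 0, c(256, 256), seed = 1)[[1]]
  m <- measureSpheroid(disk$mask, cfg)
  expect_lt(abs(m$diameter_px - 100), 2)
  expect_gt(m$circularity, 0.9)

  spur <- simulateSpheroidSeries(100, 8, c(256, 256), seed = 2)[[1]]
  m8 <- measureSpheroid(spur$mask, cfg)
  expect_lt(abs(m8$diameter_px - 100) / 100, 0.05)

  expect_error(measureSpheroid(RegionMask(matrix(FALSE, 32, 32)), cfg),
               "empty")
})

test_that("mean Feret of a square matches the projection oracle", {
  # oracle: a 100 px square spans 99*(|cos t|+|sin t|)+1 along direction t;
  # brute-force average over the same 36 directions
  th <- seq(0, pi, length.out = 37)[1:36]
  oracle <- mean(99 * (abs(cos(th)) + abs(sin(th))) + 1)
  sq <- matrix(FALSE, 200, 200)
  sq[51:150, 51:150] <- TRUE
  m <- measureSpheroid(RegionMask(sq),
                       defaultConfig(spheroid_opening_radius_px = 0))
  expect_equal(m$diameter_px, oracle, tolerance = 1e-6)
})

test_that("spheroid measurement is rotation-invariant within 2%", {
  cfg <- defaultConfig()
  H <- 256
  mkEllipse <- function(deg) {
    th <- deg * pi / 180
    g <- expand.grid(r = 1:H, c = 1:H)
    x <- (g$c - 128) * cos(th) + (g$r - 128) * sin(th)
    y <- -(g$c - 128) * sin(th) + (g$r - 128) * cos(th)
    RegionMask(matrix((x / 60)^2 + (y / 35)^2 <= 1, H, H))
  }
  d0 <- measureSpheroid(mkEllipse(0), cfg)$diameter_px
  for (deg in c(30, 60, 115))
    expect_lt(abs(measureSpheroid(mkEllipse(deg), cfg)$diameter_px - d0) / d0,
              0.02)
})

test_that("growth tables report fold change and sort unordered timepoints", {
  cfg <- defaultConfig()
  series <- simulateSpheroidSeries(c(100, 80, 60), 0, c(256, 256), seed = 3)
  ms <- lapply(seq_along(series), function(i)
    measureSpheroid(series[[i]]$mask, cfg, timepoint = i))
  g <- trackGrowth(ms)
  expect_equal(g$fold_change, g$diameter_px / g$diameter_px[1])
  expect_equal(g$fold_change, c(1, 0.8, 0.6), tolerance = 0.03)

  const <- trackGrowth(list(ms[[1]], ms[[1]], ms[[1]]))
  expect_identical(const$fold_change, c(1, 1, 1))

  shuffled <- list(ms[[3]], ms[[1]], ms[[2]])
  shuffled[[1]]$timepoint <- 3; shuffled[[2]]$timepoint <- 1
  shuffled[[3]]$timepoint <- 2
  expect_warning(gs <- trackGrowth(shuffled), "unordered")
  expect_identical(gs$timepoint, c(1, 2, 3))

  expect_error(trackGrowth(ms[1]), "at least 2")
})

test_that("vessel counting is exact on noise-free synthetic fields", {
  cfg <- defaultConfig()
  expect_identical(
    countVessels(simulateVesselField(0, image_hw = c(128, 128),
                                     seed = 1)$image, cfg)$vessel_count, 0L)

  v35 <- simulateVesselField(35, c(8, 14), c(768, 768), seed = 3)
  expect_identical(countVessels(v35$image, cfg)$vessel_count, 35L)

  v4 <- simulateVesselField(4, c(8, 14), c(256, 256), seed = 4)
  st <- countVessels(v4$image, cfg)
  expect_identical(st$vessel_count, 4L)
  expect_true(all(abs(sort(st$lumen_areas_px) - sort(v4$truth$lumens$area_px)) /
                  sort(v4$truth$lumens$area_px) < 0.05))
})
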