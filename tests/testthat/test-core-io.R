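test_that("image IO rescales by bit depth and round-trips within quantization", {
  # full-scale and zero 8-bit values map to 1 and 0
  a <- array(0, c(32, 32, 3))
  a[1, 1, ] <- 1
  f8 <- tempfile(fileext = ".png")
  png::writePNG(a, f8)  # 8-bit
  img <- readRasterImage(f8, "IHC")
  expect_identical(pixelArray(img)[1, 1, 1], 1)
  expect_identical(pixelArray(img)[2, 2, 1], 0)

  # 16-bit TIFF round trip through the package writer
  set.seed(42)
  b <- array(runif(64 * 64 * 3), c(64, 64, 3))
  f16 <- tempfile(fileext = ".tif")
  writeRasterImage(RasterImage(b, modality = "PSR"), f16)
  back <- readRasterImage(f16, "PSR")
  expect_lt(max(abs(pixelArray(back) - b)), 1 / 65535 + 1e-12)

  # grayscale is promoted to three identical channels
  g <- matrix(runif(32 * 32), 32, 32)
  fg <- tempfile(fileext = ".png")
  png::writePNG(g, fg)
  gi <- readRasterImage(fg, "HE")
  expect_equal(dim(pixelArray(gi))[3], 3)
  expect_identical(pixelArray(gi)[, , 1], pixelArray(gi)[, , 3])
})

test_that("unreadable or unsupported image files fail with the path named", {
  expect_error(readRasterImage("/nonexistent/file.tif", "PSR"),
               "no such file")
  bad <- tempfile(fileext = ".txt")
  writeLines("not an image", bad)
  expect_error(readRasterImage(bad, "PSR"), "unsupported image format")
})

test_that("RasterImage enforces its invariants", {
  expect_error(RasterImage(array(2, c(32, 32, 3))), "\\[0, 1\\]")
  expect_error(RasterImage(array(0.5, c(8, 8, 3))), "16")
  expect_error(RasterImage(array(0.5, c(32, 32, 3)), modality = "XRAY"),
               "modality")
})

test_that("result CSVs keep precision, order and determinism", {
  df <- data.frame(id = 1:10, value = c(pi, exp(1), sqrt(2), 1.123456789,
                                        5:10 + 0.25))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  writeResultsCsv(df, f1)
  writeResultsCsv(df, f2)
  back <- utils::read.csv(f1)
  expect_equal(back$value, df$value, tolerance = 1e-10)
  expect_identical(back$id, df$id)
  expect_identical(readBin(f1, "raw", 1e5), readBin(f2, "raw", 1e5))

  # empty table -> header-only CSV
  fe <- tempfile(fileext = ".csv")
  writeResultsCsv(df[0, ], fe)
  expect_identical(length(readLines(fe)), 1L)
})

test_that("configuration defaults, validation and YAML round trip", {
  cfg <- defaultConfig()
  expect_s4_class(cfg, "AnalysisConfig")
  expect_identical(cfgParam(cfg, "min_fiber_length"), 15)
  expect_identical(odThreshold(cfg, "Ki67"), 0.15)

  # empty file -> all defaults
  fe <- tempfile(fileext = ".yaml")
  writeLines("", fe)
  expect_identical(loadConfig(fe)@params, cfg@params)
  expect_identical(loadConfig(fe)@hueBins, cfg@hueBins)

  # save/load reproduces the structure exactly (idempotence)
  fy <- tempfile(fileext = ".yaml")
  saveConfig(cfg, fy)
  cfg2 <- loadConfig(fy)
  expect_identical(cfg2@params, cfg@params)
  expect_identical(cfg2@odThresholds, cfg@odThresholds)
  expect_equal(cfg2@stainVectors@vectors, cfg@stainVectors@vectors)

  # overlapping hue bins are rejected with the bins named
  hb <- data.frame(bin = c("low", "high"), lo = c(10, 40), hi = c(50, 80))
  expect_error(defaultConfig(hueBins = hb), "overlap.*low.*high")

  # negative thresholds are rejected
  expect_error(defaultConfig(odThresholds = c(Ki67 = -0.1)), "non-negative")
  expect_error(defaultConfig(gap_max = -2), "non-negative")
})
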