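test_that("birefringence segmentation isolates bright saturated signal", {
  cfg <- defaultConfig()
  # all-black image -> empty mask with warning
  black <- RasterImage(array(0, c(64, 64, 3)), modality = "PSR")
  expect_warning(m0 <- segmentBirefringent(black, cfg), "empty mask")
  expect_identical(sum(maskMatrix(m0)), 0L)

  # a single capsule's mask matches its analytic area L*w + pi*(w/2)^2
  f1 <- simulateFiberField(capsuleFieldSpec(width = 6, angle = 30))
  m1 <- segmentBirefringent(f1$image, cfg)
  expect_equal(sum(maskMatrix(m1)), 100 * 6 + pi * 9, tolerance = 0.15)

  # degenerate thresholds keep the full frame (minus nothing: one component)
  cfg0 <- defaultConfig(birefringence_value_min = 0,
                        birefringence_saturation_min = 0)
  mfull <- segmentBirefringent(f1$image, cfg0)
  expect_identical(sum(maskMatrix(mfull)), 196L * 196L)

  # non-PSR input is refused
  expect_error(segmentBirefringent(
    RasterImage(array(0.5, c(64, 64, 3)), modality = "IHC"), cfg), "PSR")
})

test_that("single capsules are recovered across widths and orientations", {
  cfg <- defaultConfig()
  for (w in c(4, 6, 10)) {
    for (ang in c(0, 30, 120)) {
      f <- simulateFiberField(capsuleFieldSpec(width = w, angle = ang))
      fs <- extractFibers(segmentBirefringent(f$image, cfg), cfg)
      fm <- fiberMeasurements(fs)
      expect_identical(nrow(fm), 1L)
      expect_lt(abs(fm$length_px - 100), 8)
      expect_lt(abs(fm$width_px - w), 1.5)
      d <- abs(fm$angle_deg - ang) %% 180
      expect_lt(min(d, 180 - d), 3)
    }
  }
})

test_that("disjoint capsules yield separate fibers; empty masks yield none", {
  cfg <- defaultConfig()
  H <- 128; W <- 196
  px <- array(0, c(H, W, 3))
  for (r0 in c(40, 90)) {
    cap <- histoquant:::.capsuleCoverage(r0, 98, 0, 100, 6, H, W)
    for (ch in 1:2) {  # yellow-ish fiber
      pl <- px[, , ch]
      pl[cap$idx] <- pmax(pl[cap$idx], cap$cov)
      px[, , ch] <- pl
    }
  }
  img <- RasterImage(px, modality = "PSR")
  fs <- extractFibers(segmentBirefringent(img, cfg), cfg)
  expect_identical(nFibers(fs), 2L)

  empty <- RegionMask(matrix(FALSE, 64, 64))
  expect_identical(nFibers(extractFibers(empty, cfg)), 0L)
})

test_that("fiber extraction is deterministic for a fixed mask", {
  cfg <- defaultConfig()
  f <- simulateFiberField(fiberFieldSpec(n_fibers = 40,
                                         image_hw = c(384, 384), seed = 31))
  m <- segmentBirefringent(f$image, cfg)
  a <- extractFibers(m, cfg)
  b <- extractFibers(m, cfg)
  expect_identical(a@fibers, b@fibers)
  expect_identical(a@polylines, b@polylines)
})

test_that("axial circular statistics behave at the degenerate extremes", {
  aligned <- angularStatistics(rep(45, 10))
  expect_equal(aligned$circular_mean_deg, 45, tolerance = 1e-9)
  expect_equal(aligned$circular_resultant_R, 1, tolerance = 1e-12)

  # orthogonal axial pair cancels after angle doubling
  expect_lt(angularStatistics(c(0, 90))$circular_resultant_R, 1e-12)

  # uniform axial data: R is near zero (Monte-Carlo bound)
  set.seed(19)
  expect_lt(angularStatistics(runif(1000, 0, 180))$circular_resultant_R,
            0.08)

  expect_error(angularStatistics(numeric(0)), "empty")
})

test_that("distribution summaries use Tukey box-whisker conventions", {
  s <- summarizeDistribution(c(1, 2, 3, 4, 5))
  expect_identical(s$median, 3)
  expect_identical(s$q1, 2)
  expect_identical(s$q3, 4)
  expect_identical(length(s$outliers), 0L)

  # fence at q3 + 1.5 IQR = 4 + 1.5*2 = 7, so 100 is an outlier and the
  # upper whisker clips to the largest point inside the fence
  s2 <- summarizeDistribution(c(1, 2, 3, 4, 100))
  expect_identical(s2$outliers, 100)
  expect_identical(s2$whisker_hi, 4)
  expect_true(all(s2$outliers < s2$whisker_lo | s2$outliers > s2$whisker_hi))

  s3 <- summarizeDistribution(7)
  expect_identical(s3$median, 7)
  expect_identical(s3$mean, 7)
  expect_identical(s3$sem, 0)
  expect_identical(s3$flag, "single_value")

  expect_error(summarizeDistribution(numeric(0)), "empty")
})

test_that("pooling concatenates fibers and preserves source labels", {
  mk <- function(n, smp) FiberSet(data.frame(
    id = seq_len(n), angle_deg = runif(n, 0, 179), length_px = runif(n, 20, 80),
    width_px = runif(n, 2, 8), sample = smp, region = "crypt",
    condition = "healthy", stringsAsFactors = FALSE),
    polylines = replicate(n, cbind(1:2, 1:2), simplify = FALSE))
  set.seed(3)
  pooled <- poolFiberSets(mk(7, "p1"), mk(5, "p2"))
  expect_true(pooled@pooled)
  expect_identical(nFibers(pooled), 12L)
  expect_identical(sum(pooled@fibers$sample == "p1"), 7L)
  expect_identical(summarizeDistribution(pooled@fibers$length_px)$n, 12L)
})

test_that("KS comparison matches ECDF extremes and guards small samples", {
  x <- c(1, 2, 3, 4, 5, 6)
  same <- compareDistributions(x, x)
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)

  disjoint <- compareDistributions(rep(0, 10), rep(1, 10))
  expect_identical(disjoint$statistic, 1)

  expect_error(compareDistributions(1:3, 1:10), "at least 5")
})
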