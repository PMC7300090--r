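test_that("optical-density conversion is the exact Beer-Lambert inverse", {
  expect_identical(rgbToOD(array(1, c(16, 16, 3)))[1, 1, 1], 0)
  expect_equal(rgbToOD(array(exp(-1), c(16, 16, 3)))[1, 1, 1], 1)
  set.seed(8)
  od <- array(runif(16 * 16 * 3, 0, 2), c(16, 16, 3))
  expect_lt(max(abs(rgbToOD(odToRgb(od)) - od)), 1e-9)
})

test_that("stain deconvolution inverts the forward model exactly", {
  sv <- defaultStainVectors()
  V <- stainVectors(sv)

  # pure DAB density 0.8 everywhere
  od <- array(rep(0.8 * V["dab", ], each = 24 * 24), c(24, 24, 3))
  d <- deconvolveStains(od, sv)
  expect_lt(max(abs(d$dab - 0.8)), 1e-6)
  expect_lt(max(abs(d$hematoxylin)), 1e-6)
  expect_lt(max(abs(d$vector_red)), 1e-6)

  # white image -> all densities zero
  dw <- deconvolveStains(rgbToOD(array(1, c(16, 16, 3))), sv)
  expect_identical(max(dw$dab, dw$hematoxylin, dw$vector_red), 0)

  # mixed two-stain field, noise-free, per-pixel recovery
  set.seed(5)
  h <- matrix(runif(32 * 32, 0, 0.8), 32, 32)
  vr <- matrix(runif(32 * 32, 0, 0.8), 32, 32)
  od2 <- array(0, c(32, 32, 3))
  for (ch in 1:3) od2[, , ch] <- h * V[1, ch] + vr * V[3, ch]
  d2 <- deconvolveStains(od2, sv)
  expect_lt(max(abs(d2$hematoxylin - h)), 1e-6)
  expect_lt(max(abs(d2$vector_red - vr)), 1e-6)

  # nearly collinear bases are rejected at construction
  expect_error(StainVectorSet(rbind(c(1, 0, 0), c(1, 1e-5, 0), c(0, 0, 1))),
               "condition")
})

test_that("cell segmentation finds isolated and touching nuclei", {
  cfg <- defaultConfig()
  f <- simulateIhcField(ihcFieldSpec(n_cells = 50, tumor_fraction = 0.5,
                                     seed = 21))
  dens <- deconvolveStains(rgbToOD(f$image), defaultStainVectors())
  cells <- segmentCells(dens, cfg)
  expect_lte(abs(nrow(cellTable(cells)) - 50), 1)

  # compartments are disjoint and contained in the cell mask
  nm <- labelMap(cells, "nucleus"); rg <- labelMap(cells, "ring")
  cy <- labelMap(cells, "cytoplasm"); cl <- labelMap(cells, "cell")
  expect_false(any(nm > 0 & rg > 0))
  expect_false(any(nm > 0 & cy > 0))
  expect_false(any(rg > 0 & cy > 0))
  expect_true(all(cl[nm > 0 | rg > 0 | cy > 0] > 0))

  # empty field
  z <- matrix(0, 64, 64)
  expect_warning(
    e <- segmentCells(list(hematoxylin = z, dab = z, vector_red = z), cfg),
    "no nuclei")
  expect_identical(nrow(cellTable(e)), 0L)

  # two touching nuclei split by the watershed
  hema <- matrix(0, 64, 64)
  for (ctr in list(c(32, 28), c(32, 39)))
    hema[histoquant:::.diskCoords(ctr[1], ctr[2], 5, 64, 64)] <- 0.65
  touch <- segmentCells(list(hematoxylin = hema, dab = z, vector_red = z),
                        cfg)
  expect_identical(nrow(cellTable(touch)), 2L)
})

test_that("tumor gating by Vector Red matches generator labels", {
  cfg <- defaultConfig()
  f <- simulateIhcField(ihcFieldSpec(n_cells = 100, tumor_fraction = 0.6,
                                     positive_fraction = 0, seed = 33))
  dens <- deconvolveStains(rgbToOD(f$image), defaultStainVectors())
  cells <- gateTumorCells(segmentCells(dens, cfg), dens$vector_red, cfg)
  gated <- mean(cellTable(cells)$is_tumor)
  expect_lt(abs(gated - 0.6), 0.05)

  # degenerate thresholds
  hi <- gateTumorCells(cells, dens$vector_red,
                       defaultConfig(ck18_threshold = Inf))
  expect_identical(sum(cellTable(hi)$is_tumor), 0L)
  lo <- gateTumorCells(cells, dens$vector_red,
                       defaultConfig(ck18_threshold = 0))
  expect_identical(sum(cellTable(lo)$is_tumor), nrow(cellTable(lo)))
})

test_that("marker scoring recovers generated fractions and edge cases", {
  cfg <- defaultConfig()
  # nuclear rule
  ki <- runIhcPipeline(ihcFieldSpec(n_cells = 200, tumor_fraction = 0.7,
                                    marker = "Ki67", positive_fraction = 0.3,
                                    seed = 42))
  expect_lt(abs(positiveFraction(ki$score) - 0.3), 0.04)
  # gate consistency: every gated tumor cell is scored
  expect_identical(ki$score@nCellsConsidered,
                   sum(cellTable(ki$cells)$is_tumor))

  # threshold 0 -> all positive; all-negative field -> 0
  sc0 <- scoreNuclear(ki$cells, ki$densities$dab, "Ki67",
                      defaultConfig(odThresholds = c(Ki67 = 0)))
  expect_identical(positiveFraction(sc0), 1)
  neg <- runIhcPipeline(ihcFieldSpec(n_cells = 100, tumor_fraction = 0.7,
                                     marker = "Ki67", positive_fraction = 0,
                                     seed = 43))
  expect_identical(positiveFraction(neg$score), 0)

  # complete-membrane rule with 50%-arc negatives
  ec <- runIhcPipeline(ihcFieldSpec(n_cells = 200, tumor_fraction = 0.7,
                                    marker = "ECadherin",
                                    positive_fraction = 0.4, seed = 17))
  expect_lt(abs(positiveFraction(ec$score) - 0.4), 0.04)

  # with completeness_min 0 every tumor cell with any ring signal scores
  # positive, including the partial-ring negatives
  all0 <- scoreMembrane(ec$cells, ec$densities$dab, "ECadherin",
                        defaultConfig(membrane_completeness_min = 0))
  expect_identical(positiveFraction(all0), 1)

  # N-cadherin nuclear branch: positives carry only nuclear signal
  nc <- runIhcPipeline(ihcFieldSpec(n_cells = 200, tumor_fraction = 0.7,
                                    marker = "NCadherin",
                                    positive_fraction = 0.4,
                                    ncad_nuclear_fraction = 1, seed = 18))
  expect_lt(abs(positiveFraction(nc$score) - 0.4), 0.04)

  # membrane + cytoplasm rule (Caspase 3)
  cp <- runIhcPipeline(ihcFieldSpec(n_cells = 200, tumor_fraction = 0.7,
                                    marker = "Caspase3",
                                    positive_fraction = 0.5, seed = 19))
  expect_lt(abs(positiveFraction(cp$score) - 0.5), 0.05)

  # scoring before gating is refused
  raw <- segmentCells(ki$densities, cfg)
  expect_error(scoreNuclear(raw, ki$densities$dab, "Ki67", cfg), "gated")
})

test_that("area-fraction scoring matches a constructed painted mask", {
  cfg <- defaultConfig()
  tumor <- matrix(FALSE, 64, 64)
  tumor[, 1:32] <- TRUE                      # 2048 tumor pixels
  dab <- matrix(0.001, 64, 64)               # faint positive everywhere
  dab[1:16, 1:32] <- 0.7                     # exactly 25% painted strongly
  sc <- scoreAreaFraction(RegionMask(tumor), dab, cfg)
  expect_identical(positiveFraction(sc), 0.25)

  expect_identical(
    positiveFraction(scoreAreaFraction(RegionMask(tumor),
                                       matrix(0, 64, 64), cfg)), 0)
  # any positive density counts when the threshold is zero
  expect_identical(
    positiveFraction(scoreAreaFraction(
      RegionMask(tumor), dab, defaultConfig(odThresholds = c(FAK = 0)))), 1)
  expect_error(scoreAreaFraction(RegionMask(matrix(FALSE, 16, 16)),
                                 matrix(0, 16, 16), cfg), "empty")
})

test_that("raising the OD threshold never raises a positive fraction", {
  cfg <- defaultConfig()
  set.seed(71)
  thresholds <- sort(runif(20, 0, 0.8))
  for (mk in c("Ki67", "ECadherin", "Caspase3")) {
    pl <- runIhcPipeline(ihcFieldSpec(n_cells = 100, tumor_fraction = 0.7,
                                      marker = mk, positive_fraction = 0.5,
                                      seed = 50 + nchar(mk)))
    fr <- vapply(thresholds, function(th) {
      positiveFraction(scoreMarker(pl$cells, pl$densities, mk,
                                   defaultConfig(odThresholds =
                                     stats::setNames(th, mk))))
    }, numeric(1))
    expect_true(all(diff(fr) <= 0))
  }
})
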