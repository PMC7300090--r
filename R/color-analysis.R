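#' @include AllClasses.R config.R
NULL

#' Hue-bin profile of birefringent collagen signal
#'
#' Converts every masked pixel to HSV and assigns its hue (degrees) to the
#' configured bins — by default red `[0,25) U [335,360)`, orange `[25,45)`,
#' yellow `[45,70)` and green `[70,160)`. Red and orange signal indicates
#' thick, bundled (mature) collagen; yellow and green indicates thin,
#' reticular fibers. Hues outside every bin (the cyan-magenta range, which
#' does not occur in PSR birefringence) are counted in `excludedPx` and
#' left out of the fractions, so the four fractions sum to 1 whenever any
#' pixel was binned.
#'
#' @param image a [RasterImage-class] with modality `"PSR"`.
#' @param mask a [RegionMask-class] from [segmentBirefringent()].
#' @param config an [AnalysisConfig-class] supplying the hue bins.
#' @return A [HueProfile-class]. An empty mask yields an all-zero profile
#'   flagged `empty`.
#' @export
hueProfile <- function(image, mask, config = defaultConfig()) {
  stopifnot(is(image, "RasterImage"), is(mask, "RegionMask"))
  if (imageModality(image) != "PSR")
    .stopf("hueProfile expects a PSR image, got %s", imageModality(image))
  mm <- maskMatrix(mask)
  if (!all(dim(mm) == dim(pixelArray(image))[1:2]))
    .stopf("mask dimensions do not match the image")
  bins <- config@hueBins
  binNames <- unique(bins$bin)
  counts <- stats::setNames(integer(length(binNames)), binNames)
  total <- sum(mm)
  if (total == 0) {
    return(new("HueProfile", counts = counts,
               fractions = stats::setNames(numeric(length(binNames)),
                                           binNames),
               totalBirefringentPx = 0L, excludedPx = 0L, empty = TRUE))
  }
  hsv <- .rgb2hsvDeg(pixelArray(image))
  hue <- hsv$h[mm]
  assigned <- rep(FALSE, length(hue))
  for (i in seq_len(nrow(bins))) {
    inBin <- !assigned & hue >= bins$lo[i] & hue < bins$hi[i]
    counts[bins$bin[i]] <- counts[bins$bin[i]] + sum(inBin)
    assigned <- assigned | inBin
  }
  excluded <- sum(!assigned)
  binned <- sum(counts)
  fractions <- if (binned > 0) counts / binned else
    stats::setNames(numeric(length(binNames)), binNames)
  new("HueProfile", counts = counts, fractions = fractions,
      totalBirefringentPx = as.integer(total),
      excludedPx = as.integer(excluded), empty = FALSE)
}

#' Blue/red pixel ratios of a Masson's trichrome image
#'
#' Classifies pixels of a trichrome-stained brightfield image: tissue
#' pixels are non-white (HSV value below `trichrome_white_value_min` or
#' saturation above `trichrome_tissue_saturation_min`); among tissue,
#' aniline-blue collagen is hue in `[trichrome_blue_hue_lo,
#' trichrome_blue_hue_hi)` and Biebrich-scarlet cytoplasm/muscle is hue in
#' the red window (wrapping through 0), both requiring saturation above
#' `trichrome_color_saturation_min`. Fractions are colored pixels over
#' total tissue pixels.
#'
#' @param image a [RasterImage-class] with modality `"TRICHROME"`.
#' @param config an [AnalysisConfig-class].
#' @return A [TrichromeRatio-class]. When no tissue pixel is found the
#'   result is all-zero and flagged `empty`.
#' @export
trichromeRatio <- function(image, config = defaultConfig()) {
  stopifnot(is(image, "RasterImage"))
  if (imageModality(image) != "TRICHROME")
    .stopf("trichromeRatio expects a TRICHROME image, got %s",
           imageModality(image))
  hsv <- .rgb2hsvDeg(pixelArray(image))
  tissue <- hsv$v < cfgParam(config, "trichrome_white_value_min") |
            hsv$s > cfgParam(config, "trichrome_tissue_saturation_min")
  nTissue <- sum(tissue)
  if (nTissue == 0) {
    .warnf("no tissue pixels found; returning an empty trichrome ratio")
    return(new("TrichromeRatio", bluePx = 0L, redPx = 0L, tissuePx = 0L,
               blueFraction = 0, redFraction = 0, empty = TRUE))
  }
  satMin <- cfgParam(config, "trichrome_color_saturation_min")
  h <- hsv$h
  colored <- tissue & hsv$s > satMin
  blue <- colored & h >= cfgParam(config, "trichrome_blue_hue_lo") &
          h < cfgParam(config, "trichrome_blue_hue_hi")
  redLo <- cfgParam(config, "trichrome_red_hue_lo")
  redHi <- cfgParam(config, "trichrome_red_hue_hi")
  red <- colored & (h >= redLo | h < redHi)
  nBlue <- sum(blue); nRed <- sum(red)
  new("TrichromeRatio", bluePx = as.integer(nBlue), redPx = as.integer(nRed),
      tissuePx = as.integer(nTissue),
      blueFraction = nBlue / nTissue, redFraction = nRed / nTissue,
      empty = FALSE)
}
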