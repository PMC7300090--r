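#' @include AllClasses.R config.R
NULL

#' Measure spheroid size from a binary mask
#'
#' The mask is first morphologically opened with a disk of radius
#' `spheroid_opening_radius_px` to suppress the thin radial protrusions of
#' migrating cells, which would otherwise inflate the size of the spheroid
#' body. The average diameter is the mean Feret diameter (projection
#' extent) of the largest remaining component over `feret_directions`
#' equally spaced directions; area and circularity (`4 pi A / P^2`) are
#' reported from the same component.
#'
#' @param mask a [RegionMask-class] of the spheroid.
#' @param config an [AnalysisConfig-class].
#' @param timepoint optional label (e.g. day) carried into growth tables.
#' @return A list of class `SpheroidMeasurement` with `timepoint`,
#'   `diameter_px`, `diameter_um`, `area_px`, `circularity` and `flag`
#'   (`"multiple_components"` when more than one component passed the
#'   minimum area and the largest was used).
#' @export
measureSpheroid <- function(mask, config = defaultConfig(), timepoint = NA) {
  stopifnot(is(mask, "RegionMask"))
  mm <- maskMatrix(mask)
  if (!any(mm)) .stopf("cannot measure an empty spheroid mask")
  r <- cfgParam(config, "spheroid_opening_radius_px")
  opened <- if (r > 0) {
    brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
    EBImage::opening(matrix(as.numeric(mm), nrow(mm), ncol(mm)), brush) > 0
  } else mm
  if (!any(opened)) .stopf("mask vanished after opening; no spheroid body")
  lab <- .label8(opened)
  sizes <- tabulate(lab)
  minArea <- cfgParam(config, "spheroid_min_area_px")
  flag <- if (sum(sizes >= minArea) > 1) "multiple_components" else ""
  keep <- which.max(sizes)
  comp <- lab == keep
  coords <- which(comp, arr.ind = TRUE)
  ndir <- cfgParam(config, "feret_directions")
  theta <- seq(0, pi, length.out = ndir + 1)[seq_len(ndir)]
  feret <- vapply(theta, function(th) {
    p <- coords[, 2] * cos(th) + coords[, 1] * sin(th)
    max(p) - min(p) + 1
  }, numeric(1))
  area <- sum(comp)
  per <- EBImage::computeFeatures.shape(
    matrix(as.integer(comp), nrow(comp), ncol(comp)))[1, "s.perimeter"]
  circ <- min(4 * pi * area / per^2, 1.05)
  pxUm <- cfgParam(config, "pixel_size_um")
  structure(list(timepoint = timepoint, diameter_px = mean(feret),
                 diameter_um = mean(feret) * pxUm, area_px = area,
                 circularity = circ, flag = flag),
            class = "SpheroidMeasurement")
}

#' Tabulate spheroid growth over time
#'
#' @param series list of `SpheroidMeasurement` results from
#'   [measureSpheroid()], at least two timepoints.
#' @return A data.frame with `timepoint`, `diameter_px`, `diameter_um`,
#'   `area_px` and `fold_change` relative to the first timepoint. Unordered
#'   timepoints are sorted with a warning.
#' @export
trackGrowth <- function(series) {
  if (length(series) < 2)
    .stopf("growth tracking requires at least 2 timepoints")
  tab <- data.frame(
    timepoint = vapply(series, function(s) as.numeric(s$timepoint),
                       numeric(1)),
    diameter_px = vapply(series, `[[`, numeric(1), "diameter_px"),
    diameter_um = vapply(series, `[[`, numeric(1), "diameter_um"),
    area_px = vapply(series, `[[`, numeric(1), "area_px"))
  if (!all(is.na(tab$timepoint)) && is.unsorted(tab$timepoint)) {
    .warnf("timepoints were unordered; sorting")
    tab <- tab[order(tab$timepoint), ]
  }
  tab$fold_change <- tab$diameter_px / tab$diameter_px[1]
  rownames(tab) <- NULL
  tab
}

#' Count vessel lumens and measure their areas
#'
#' Candidate lumens are bright connected components (HSV value above
#' `lumen_value_min`) whose area lies within
#' `[lumen_area_min_px, lumen_area_max_fraction * H * W]` and whose outer
#' boundary is at least `lumen_boundary_stained_min` adjacent to stained
#' (non-bright) pixels — the signature of a lumen enclosed by a vessel
#' wall.
#'
#' @param image a [RasterImage-class] (H&E or synthetic vessel field).
#' @param config an [AnalysisConfig-class].
#' @return A list of class `VesselStats` with `vessel_count` and
#'   `lumen_areas_px` (pixel counts, one per vessel); zero vessels gives an
#'   empty area list.
#' @export
countVessels <- function(image, config = defaultConfig()) {
  stopifnot(is(image, "RasterImage"))
  px <- pixelArray(image)
  v <- pmax(px[, , 1], px[, , 2], px[, , 3])
  bright <- v > cfgParam(config, "lumen_value_min")
  H <- nrow(v); W <- ncol(v)
  areas <- numeric(0)
  if (any(bright)) {
    lab <- .label8(bright)
    sizes <- tabulate(lab)
    aMin <- cfgParam(config, "lumen_area_min_px")
    aMax <- cfgParam(config, "lumen_area_max_fraction") * H * W
    minStained <- cfgParam(config, "lumen_boundary_stained_min")
    for (i in which(sizes >= aMin & sizes <= aMax)) {
      idx <- which(lab == i)
      rows <- (idx - 1L) %% H + 1L
      cols <- (idx - 1L) %/% H + 1L
      r0 <- max(1L, min(rows) - 2L); r1 <- min(H, max(rows) + 2L)
      c0 <- max(1L, min(cols) - 2L); c1 <- min(W, max(cols) + 2L)
      own <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
      own[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
      ring <- EBImage::dilate(own, EBImage::makeBrush(3, "box")) & !own
      ringStained <- !bright[r0:r1, c0:c1][ring]
      if (mean(ringStained) >= minStained)
        areas <- c(areas, sizes[i])
    }
  }
  structure(list(vessel_count = length(areas), lumen_areas_px = areas),
            class = "VesselStats")
}
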