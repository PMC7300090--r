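#' @include AllClasses.R
NULL

#' Accessors for histoquant objects
#'
#' `pixelArray()` returns the `H x W x 3` pixel array of a
#' [RasterImage-class] (or the logical matrix of a [RegionMask-class] via
#' `maskMatrix()`); `imageModality()` and `pixelSizeUm()` return the stain
#' modality and physical pixel size; `nFibers()` and `fiberMeasurements()`
#' access a [FiberSet-class]; `hueCounts()` / `hueFractions()` access a
#' [HueProfile-class]; `cellTable()` and `labelMap()` access a
#' [CellSet-class].
#'
#' @param x the object.
#' @param which for `labelMap`, one of `"cell"`, `"nucleus"`, `"ring"`,
#'   `"cytoplasm"`.
#' @return The underlying component (array, matrix, data.frame or scalar).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelArray", function(x) standardGeneric("pixelArray"))
#' @rdname accessors
#' @export
setGeneric("imageModality", function(x) standardGeneric("imageModality"))
#' @rdname accessors
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))
#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setGeneric("maskLabel", function(x) standardGeneric("maskLabel"))
#' @rdname accessors
#' @export
setGeneric("nFibers", function(x) standardGeneric("nFibers"))
#' @rdname accessors
#' @export
setGeneric("fiberMeasurements", function(x) standardGeneric("fiberMeasurements"))
#' @rdname accessors
#' @export
setGeneric("hueCounts", function(x) standardGeneric("hueCounts"))
#' @rdname accessors
#' @export
setGeneric("hueFractions", function(x) standardGeneric("hueFractions"))
#' @rdname accessors
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))
#' @rdname accessors
#' @export
setGeneric("labelMap", function(x, which = "cell") standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setGeneric("stainVectors", function(x) standardGeneric("stainVectors"))
#' @rdname accessors
#' @export
setGeneric("positiveFraction", function(x) standardGeneric("positiveFraction"))

#' @rdname accessors
setMethod("pixelArray", "RasterImage", function(x) x@pixels)
#' @rdname accessors
setMethod("imageModality", "RasterImage", function(x) x@modality)
#' @rdname accessors
setMethod("pixelSizeUm", "RasterImage", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSizeUm", "FiberSet", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("maskMatrix", "RegionMask", function(x) x@pixels)
#' @rdname accessors
setMethod("maskLabel", "RegionMask", function(x) x@label)
#' @rdname accessors
setMethod("nFibers", "FiberSet", function(x) nrow(x@fibers))
#' @rdname accessors
setMethod("fiberMeasurements", "FiberSet", function(x) {
  f <- x@fibers
  f$length_um <- f$length_px * x@pixelSizeUm
  f$width_um <- f$width_px * x@pixelSizeUm
  f
})
#' @rdname accessors
setMethod("hueCounts", "HueProfile", function(x) x@counts)
#' @rdname accessors
setMethod("hueFractions", "HueProfile", function(x) x@fractions)
#' @rdname accessors
setMethod("cellTable", "CellSet", function(x) x@cells)
#' @rdname accessors
setMethod("labelMap", "CellSet", function(x, which = "cell") {
  switch(match.arg(which, c("cell", "nucleus", "ring", "cytoplasm")),
         cell = x@cellMap, nucleus = x@nucleusMap,
         ring = x@ringMap, cytoplasm = x@cytoplasmMap)
})
#' @rdname accessors
setMethod("stainVectors", "StainVectorSet", function(x) x@vectors)
#' @rdname accessors
setMethod("stainVectors", "AnalysisConfig", function(x) x@stainVectors@vectors)
#' @rdname accessors
setMethod("positiveFraction", "MarkerScore", function(x) x@positiveFraction)

setMethod("show", "RasterImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RasterImage %d x %d px, modality %s, %.3g um/px\n",
              d[1], d[2], object@modality, object@pixelSizeUm))
  if (nzchar(object@sourcePath))
    cat(" source:", object@sourcePath, "\n")
})

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask %d x %d, %d foreground px%s\n",
              nrow(object@pixels), ncol(object@pixels), sum(object@pixels),
              if (nzchar(object@label))
                sprintf(", label '%s'", object@label) else ""))
})

setMethod("show", "FiberSet", function(object) {
  cat(sprintf("FiberSet with %d fiber(s)%s\n", nrow(object@fibers),
              if (object@pooled) " (pooled)" else ""))
  if (nrow(object@fibers) > 0) {
    f <- object@fibers
    cat(sprintf("  median length %.1f px, median width %.2f px\n",
                stats::median(f$length_px), stats::median(f$width_px)))
    ax <- .axialStats(f$angle_deg)
    cat(sprintf("  circular mean %.1f deg, resultant R = %.3f\n",
                ax$mean_deg, ax$R))
  }
})

setMethod("show", "HueProfile", function(object) {
  cat("HueProfile:", object@totalBirefringentPx, "birefringent px\n")
  if (!object@empty)
    print(round(object@fractions, 4))
})

setMethod("show", "TrichromeRatio", function(object) {
  cat(sprintf(
    "TrichromeRatio: blue %.3f, red %.3f of %d tissue px%s\n",
    object@blueFraction, object@redFraction, object@tissuePx,
    if (object@empty) " [no tissue]" else ""))
})

setMethod("show", "CellSet", function(object) {
  n <- nrow(object@cells)
  cat(sprintf("CellSet with %d cell(s), %d excluded\n", n, object@excluded))
  if (n > 0 && "is_tumor" %in% names(object@cells))
    cat(sprintf("  %d gated tumor cells\n", sum(object@cells$is_tumor)))
})

setMethod("show", "MarkerScore", function(object) {
  if (object@rule == "area_fraction") {
    cat(sprintf("MarkerScore %s (%s): area fraction %.3f\n",
                object@marker, object@rule, object@positiveFraction))
  } else {
    cat(sprintf("MarkerScore %s (%s): %d / %d positive (%.3f)%s\n",
                object@marker, object@rule, object@nPositive,
                object@nCellsConsidered, object@positiveFraction,
                if (object@excluded > 0)
                  sprintf(", %d excluded", object@excluded) else ""))
  }
})

setMethod("show", "StainVectorSet", function(object) {
  cat("StainVectorSet:\n")
  print(round(object@vectors, 4))
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n hue bins:\n")
  print(object@hueBins)
  cat(" OD thresholds:\n")
  print(object@odThresholds)
  cat(sprintf(" plus %d scalar parameters (see defaultConfig())\n",
              length(object@params)))
})
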