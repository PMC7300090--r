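#' @import methods
NULL

.MODALITIES <- c("PSR", "TRICHROME", "IHC", "HE")

#' RasterImage: an RGB micrograph with pixel-size metadata
#'
#' The universal image container of the package. Pixels are stored as an
#' `H x W x 3` numeric array of values in `[0, 1]` (converted from 8- or
#' 16-bit integer data on read), row-major with the origin at the top-left
#' corner and 0-based spatial semantics (row 1 of the array is image row 0).
#'
#' @slot pixels numeric array, `H x W x 3`, values in `[0, 1]`.
#' @slot pixelSizeUm physical size of one pixel in micrometres (default 1).
#' @slot sourcePath path the image was read from, or `""` if built in memory.
#' @slot modality one of `"PSR"`, `"TRICHROME"`, `"IHC"`, `"HE"`.
#'
#' @seealso [readRasterImage()], [RasterImage()]
#' @export
setClass("RasterImage",
  representation(pixels = "array", pixelSizeUm = "numeric",
                 sourcePath = "character", modality = "character"),
  prototype(pixelSizeUm = 1, sourcePath = "", modality = "PSR"))

setValidity("RasterImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3 || d[3] != 3)
    return("pixels must be an H x W x 3 array")
  if (d[1] < 16 || d[2] < 16)
    return("image must be at least 16 x 16 pixels")
  rng <- range(object@pixels)
  if (rng[1] < 0 || rng[2] > 1)
    return("pixel values must lie in [0, 1]")
  if (!object@modality %in% .MODALITIES)
    return(sprintf("modality must be one of %s",
                   paste(.MODALITIES, collapse = ", ")))
  if (length(object@pixelSizeUm) != 1 || object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a single positive number")
  TRUE
})

#' Construct a RasterImage from a pixel array
#'
#' @param pixels `H x W x 3` numeric array in `[0, 1]`, or an `H x W` matrix
#'   which is promoted to three identical channels.
#' @param modality imaging modality, one of `"PSR"`, `"TRICHROME"`, `"IHC"`,
#'   `"HE"`.
#' @param pixelSizeUm micrometres per pixel.
#' @param sourcePath provenance string recorded in the object.
#' @return A [RasterImage-class] object.
#' @examples
#' img <- RasterImage(array(0.5, c(32, 32, 3)), modality = "IHC")
#' dim(pixelArray(img))
#' @export
RasterImage <- function(pixels, modality = "PSR", pixelSizeUm = 1,
                        sourcePath = "") {
  if (is.matrix(pixels))
    pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  new("RasterImage", pixels = pixels, modality = modality,
      pixelSizeUm = pixelSizeUm, sourcePath = sourcePath)
}

#' RegionMask: a binary region of interest
#'
#' A logical `H x W` matrix paired with a free-text label naming the tissue
#' region it delineates (e.g. `"crypt"`, `"submucosa"`, `"tumor"`).
#'
#' @slot pixels logical matrix.
#' @slot label region label.
#' @export
setClass("RegionMask",
  representation(pixels = "matrix", label = "character"),
  prototype(label = ""))

setValidity("RegionMask", function(object) {
  if (!is.logical(object@pixels))
    return("mask pixels must be logical")
  TRUE
})

#' Construct a RegionMask
#'
#' @param pixels logical `H x W` matrix.
#' @param label region label.
#' @return A [RegionMask-class] object.
#' @export
RegionMask <- function(pixels, label = "") {
  new("RegionMask", pixels = pixels, label = label)
}

#' StainVectorSet: unit optical-density directions of the chromogens
#'
#' Each stain (hematoxylin, DAB, Vector Red) absorbs light with a
#' characteristic RGB optical-density direction; chromogen amounts add
#' linearly in OD (Beer-Lambert), so an invertible 3 x 3 matrix of unit
#' vectors permits per-pixel unmixing.
#'
#' @slot stains character vector of stain names.
#' @slot vectors 3 x 3 numeric matrix; row `i` is the unit-norm RGB OD
#'   direction of stain `i`.
#' @seealso [defaultStainVectors()], [deconvolveStains()]
#' @export
setClass("StainVectorSet",
  representation(stains = "character", vectors = "matrix"))

setValidity("StainVectorSet", function(object) {
  v <- object@vectors
  if (!all(dim(v) == c(3, 3)))
    return("vectors must be a 3 x 3 matrix (stains x RGB)")
  if (length(object@stains) != 3)
    return("exactly three stain names are required")
  norms <- sqrt(rowSums(v^2))
  if (any(abs(norms - 1) > 1e-6))
    return("each stain vector must have unit norm")
  kap <- kappa(v, exact = TRUE)
  if (!is.finite(kap) || kap >= 1e3)
    return(sprintf("stain matrix is ill-conditioned (condition number %.3g)",
                   kap))
  TRUE
})

#' Construct a StainVectorSet
#'
#' Vectors are renormalized to unit length.
#'
#' @param vectors 3 x 3 numeric matrix, one stain per row (RGB OD).
#' @param stains names of the three stains.
#' @return A [StainVectorSet-class] object.
#' @export
StainVectorSet <- function(vectors,
                           stains = c("hematoxylin", "dab", "vector_red")) {
  vectors <- vectors / sqrt(rowSums(vectors^2))
  rownames(vectors) <- stains
  colnames(vectors) <- c("r", "g", "b")
  new("StainVectorSet", stains = stains, vectors = vectors)
}

#' FiberSet: a collection of traced collagen fibers
#'
#' Holds one row per fiber with its axial orientation (degrees in
#' `[0, 180)`), arc length and mean width (pixels), together with the traced
#' centreline polylines and source labels. Sets from several regions or
#' samples can be pooled with [poolFiberSets()]; pooling concatenates fibers
#' and preserves per-fiber source labels.
#'
#' @slot fibers data.frame with columns `id`, `angle_deg`, `length_px`,
#'   `width_px`, `sample`, `region`, `condition`.
#' @slot polylines list of two-column (row, col) coordinate matrices, one per
#'   fiber, in the order of `fibers`.
#' @slot pixelSizeUm micrometres per pixel, used to derive micrometre
#'   measurements.
#' @slot pooled whether the set was produced by pooling.
#' @export
setClass("FiberSet",
  representation(fibers = "data.frame", polylines = "list",
                 pixelSizeUm = "numeric", pooled = "logical"),
  prototype(pixelSizeUm = 1, pooled = FALSE))

setValidity("FiberSet", function(object) {
  need <- c("id", "angle_deg", "length_px", "width_px",
            "sample", "region", "condition")
  if (!all(need %in% names(object@fibers)))
    return(sprintf("fibers table must have columns %s",
                   paste(need, collapse = ", ")))
  if (length(object@polylines) != nrow(object@fibers))
    return("one polyline per fiber is required")
  f <- object@fibers
  if (nrow(f) > 0) {
    if (any(f$angle_deg < 0 | f$angle_deg >= 180))
      return("angles must lie in [0, 180)")
    if (any(f$width_px <= 0))
      return("widths must be positive")
  }
  TRUE
})

.emptyFiberTable <- function() {
  data.frame(id = integer(0), angle_deg = numeric(0), length_px = numeric(0),
             width_px = numeric(0), sample = character(0),
             region = character(0), condition = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a FiberSet
#'
#' @param fibers per-fiber data.frame (see [FiberSet-class]); missing source
#'   label columns are filled with `""`.
#' @param polylines list of (row, col) coordinate matrices.
#' @param pixelSizeUm micrometres per pixel.
#' @param pooled whether the set results from pooling.
#' @return A [FiberSet-class] object.
#' @export
FiberSet <- function(fibers = .emptyFiberTable(), polylines = list(),
                     pixelSizeUm = 1, pooled = FALSE) {
  for (col in c("sample", "region", "condition"))
    if (is.null(fibers[[col]])) fibers[[col]] <- rep("", nrow(fibers))
  if (is.null(fibers$id)) fibers$id <- seq_len(nrow(fibers))
  new("FiberSet", fibers = fibers, polylines = polylines,
      pixelSizeUm = pixelSizeUm, pooled = pooled)
}

#' HueProfile: hue-bin composition of birefringent collagen signal
#'
#' Pixel counts and fractions of the picrosirius-red birefringent signal in
#' the red / orange / yellow / green hue bins. Hue encodes collagen
#' bundling: red and orange indicate thick, bundled (mature) fibers, yellow
#' and green thin, reticular (immature) ones. Hues in the cyan-magenta range
#' do not occur in PSR birefringence and are counted separately in
#' `excludedPx`, outside the fractions.
#'
#' @slot counts named integer vector of pixel counts per bin.
#' @slot fractions named numeric vector; sums to 1 when any pixel was binned.
#' @slot totalBirefringentPx number of masked pixels analyzed.
#' @slot excludedPx pixels whose hue fell outside all configured bins.
#' @slot empty TRUE when the mask contained no pixels.
#' @export
setClass("HueProfile",
  representation(counts = "integer", fractions = "numeric",
                 totalBirefringentPx = "integer", excludedPx = "integer",
                 empty = "logical"))

#' TrichromeRatio: blue/red pixel composition of a Masson's trichrome field
#'
#' Masson's trichrome renders collagen blue and cytoplasm/muscle red; the
#' ratios of colored pixels to total tissue pixels summarize collagen
#' content. Fractions are taken over tissue pixels (non-white).
#'
#' @slot bluePx,redPx,tissuePx pixel counts.
#' @slot blueFraction,redFraction fractions over tissue pixels.
#' @slot empty TRUE when no tissue pixel was found.
#' @export
setClass("TrichromeRatio",
  representation(bluePx = "integer", redPx = "integer", tissuePx = "integer",
                 blueFraction = "numeric", redFraction = "numeric",
                 empty = "logical"))

setValidity("TrichromeRatio", function(object) {
  if (object@bluePx + object@redPx > object@tissuePx)
    return("blue + red pixels cannot exceed tissue pixels")
  TRUE
})

#' CellSet: segmented cells with subcellular compartments
#'
#' One row per segmented cell, with centroid, per-compartment mean optical
#' densities for each stain, the tumor gate (cytokeratin-18 / Vector Red)
#' and room for marker calls. Compartment geometry is kept as label maps
#' (integer matrices; 0 = background, `i` = cell `i`): the full cell, its
#' nucleus, a membrane ring just inside the cell boundary, and the
#' cytoplasm (cell minus nucleus minus ring). Compartments of a cell are
#' disjoint and contained in its cell mask.
#'
#' @slot cells data.frame, one row per cell.
#' @slot cellMap,nucleusMap,ringMap,cytoplasmMap integer label matrices.
#' @slot excluded number of cells dropped for degenerate geometry (e.g.
#'   touching the frame edge).
#' @export
setClass("CellSet",
  representation(cells = "data.frame", cellMap = "matrix",
                 nucleusMap = "matrix", ringMap = "matrix",
                 cytoplasmMap = "matrix", excluded = "integer"),
  prototype(excluded = 0L))

#' MarkerScore: result of one per-marker scoring rule
#'
#' @slot marker marker name.
#' @slot rule one of `"nuclear"`, `"membrane_complete"`,
#'   `"membrane_or_nuclear"`, `"area_fraction"`, `"membrane_cytoplasmic"`.
#' @slot nCellsConsidered number of gated tumor cells scored (0 for
#'   area-fraction scoring).
#' @slot nPositive positive cells (NA for area-fraction scoring).
#' @slot positiveFraction fraction of scored cells called positive, or the
#'   stained area fraction for the area-fraction rule.
#' @slot excluded cells excluded for degenerate geometry.
#' @slot flag diagnostic string, `""` when clean.
#' @export
setClass("MarkerScore",
  representation(marker = "character", rule = "character",
                 nCellsConsidered = "integer", nPositive = "integer",
                 positiveFraction = "numeric", excluded = "integer",
                 flag = "character"),
  prototype(excluded = 0L, flag = ""))

setValidity("MarkerScore", function(object) {
  okRules <- c("nuclear", "membrane_complete", "membrane_or_nuclear",
               "area_fraction", "membrane_cytoplasmic")
  if (!object@rule %in% okRules)
    return(sprintf("rule must be one of %s", paste(okRules, collapse = ", ")))
  if (!is.na(object@positiveFraction) &&
      (object@positiveFraction < 0 || object@positiveFraction > 1))
    return("positiveFraction must lie in [0, 1]")
  TRUE
})

#' AnalysisConfig: all tunable parameters of the pipeline
#'
#' Validated container for the hue bins, segmentation thresholds, stain
#' vectors, per-marker OD positivity thresholds, cell geometry and
#' morphometry settings. Built by [defaultConfig()] and round-tripped
#' through YAML by [saveConfig()] / [loadConfig()].
#'
#' @slot hueBins data.frame with columns `bin`, `lo`, `hi` (degrees); bins
#'   must be disjoint over `[0, 360)` modulo wrap-around (a bin may appear
#'   in several rows, e.g. red spanning the 0-degree wrap).
#' @slot stainVectors a [StainVectorSet-class].
#' @slot odThresholds named numeric vector of per-marker OD positivity
#'   thresholds (all non-negative).
#' @slot params named list of scalar parameters; see [defaultConfig()] for
#'   the full catalogue and defaults.
#' @export
setClass("AnalysisConfig",
  representation(hueBins = "data.frame", stainVectors = "StainVectorSet",
                 odThresholds = "numeric", params = "list"))

setValidity("AnalysisConfig", function(object) {
  hb <- object@hueBins
  if (!all(c("bin", "lo", "hi") %in% names(hb)))
    return("hueBins must have columns bin, lo, hi")
  if (any(hb$lo < 0 | hb$hi > 360 | hb$lo >= hb$hi))
    return("each hue bin row must satisfy 0 <= lo < hi <= 360")
  # disjointness over [0,360): mark covered integer half-degrees
  cover <- rep("", 720)
  for (i in seq_len(nrow(hb))) {
    idx <- which(seq(0, 359.5, by = 0.5) >= hb$lo[i] &
                 seq(0, 359.5, by = 0.5) < hb$hi[i])
    clash <- cover[idx] != "" & cover[idx] != hb$bin[i]
    if (any(clash))
      return(sprintf("hue bins overlap: %s and %s",
                     cover[idx][clash][1], hb$bin[i]))
    dup <- cover[idx] == hb$bin[i]
    if (any(dup))
      return(sprintf("hue bin %s overlaps itself", hb$bin[i]))
    cover[idx] <- hb$bin[i]
  }
  if (any(object@odThresholds < 0))
    return("OD thresholds must be non-negative")
  p <- object@params
  num <- vapply(p, is.numeric, logical(1))
  if (any(unlist(p[num]) < 0))
    return("all threshold and geometry parameters must be non-negative")
  mc <- p$membrane_completeness_min
  if (!is.null(mc) && (mc < 0 || mc > 1))
    return("membrane_completeness_min must lie in [0, 1]")
  TRUE
})
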