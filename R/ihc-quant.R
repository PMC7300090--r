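#' @include AllClasses.R config.R
NULL

#' Beer-Lambert conversion between transmitted RGB and optical density
#'
#' `rgbToOD()` converts a brightfield image to per-channel optical density,
#' `OD = -log(I)` with intensities clipped below at 1/255 (so a fully
#' absorbed 8-bit pixel maps to a finite OD); `odToRgb()` is the inverse
#' `I = exp(-OD)`. Chromogen amounts add linearly in OD, which is what
#' makes stain deconvolution a linear unmixing problem.
#'
#' @param image a [RasterImage-class] (or a bare `H x W x 3` array in
#'   `[0, 1]`).
#' @param od an `H x W x 3` optical-density array.
#' @return `rgbToOD()`: an `H x W x 3` non-negative OD array; `odToRgb()`:
#'   an `H x W x 3` intensity array in `(0, 1]`.
#' @export
rgbToOD <- function(image) {
  px <- if (is(image, "RasterImage")) pixelArray(image) else image
  -log(pmax(px, 1 / 255))
}

#' @rdname rgbToOD
#' @export
odToRgb <- function(od) exp(-od)

#' Unmix chromogen densities from an optical-density image
#'
#' Projects each pixel's OD vector onto the stain basis (the inverse of the
#' 3 x 3 unit stain-vector matrix, which for three stains is the exact
#' least-squares solution), yielding one density map per chromogen.
#' Negative densities — which arise from noise since true chromogen amounts
#' are non-negative — are clipped to zero, and the clipped fraction of
#' total absolute density mass is reported.
#'
#' @param od an `H x W x 3` OD array from [rgbToOD()].
#' @param vectors a [StainVectorSet-class]; an ill-conditioned basis
#'   (condition number >= 1000) is rejected with an error naming the
#'   condition number.
#' @return A named list of `H x W` density maps (one per stain) with
#'   attribute `clipped_fraction`.
#' @examples
#' sv <- defaultStainVectors()
#' od <- array(0.8 * rep(stainVectors(sv)["dab", ], each = 16 * 16),
#'             c(16, 16, 3))
#' d <- deconvolveStains(od, sv)
#' range(d$dab)
#' @export
deconvolveStains <- function(od, vectors = defaultStainVectors()) {
  stopifnot(is(vectors, "StainVectorSet"))
  V <- vectors@vectors
  kap <- kappa(V, exact = TRUE)
  if (!is.finite(kap) || kap >= 1e3)
    .stopf("stain basis is ill-conditioned (condition number %.3g)", kap)
  d <- dim(od)
  flat <- matrix(od, d[1] * d[2], 3)
  dens <- flat %*% solve(V)
  neg <- dens < 0
  clipped <- if (any(neg)) sum(abs(dens[neg])) / sum(abs(dens)) else 0
  dens[neg] <- 0
  out <- stats::setNames(
    lapply(1:3, function(i) matrix(dens[, i], d[1], d[2])),
    vectors@stains)
  attr(out, "clipped_fraction") <- clipped
  out
}

#' Segment cells into nucleus, membrane ring and cytoplasm
#'
#' Nuclei are found by Otsu thresholding of the hematoxylin density map,
#' hole-filled, and split by watershed on the distance transform so that
#' touching nuclei separate. Each nucleus is expanded to the cell boundary
#' by Voronoi propagation inside a dilation of the nuclei (radius
#' `cell_radius_px - nucleus_radius_px`), so neighbouring cells cap each
#' other. The membrane ring is the band of `ring_thickness_px` px just
#' inside each cell boundary, and the cytoplasm is the remainder (cell
#' minus nucleus minus ring); the three compartments of a cell are
#' disjoint. Cells touching the frame edge have degenerate rings and are
#' excluded, counted in the `excluded` tally.
#'
#' @param densities named list of density maps from [deconvolveStains()]
#'   (at least `hematoxylin`).
#' @param config an [AnalysisConfig-class] supplying the cell geometry.
#' @return A [CellSet-class] with geometry only (no tumor gate or calls);
#'   empty, with a flagging warning, when no nucleus is found.
#' @export
segmentCells <- function(densities, config = defaultConfig()) {
  hema <- densities$hematoxylin
  H <- nrow(hema); W <- ncol(hema)
  rn <- cfgParam(config, "nucleus_radius_px")
  rc <- cfgParam(config, "cell_radius_px")
  rt <- cfgParam(config, "ring_thickness_px")
  emptySet <- function() {
    .warnf("no nuclei found; returning an empty cell set")
    z <- matrix(0L, H, W)
    new("CellSet", cells = data.frame(), cellMap = z, nucleusMap = z,
        ringMap = z, cytoplasmMap = z, excluded = 0L)
  }
  if (max(hema) < 0.05) return(emptySet())
  thr <- EBImage::otsu(EBImage::Image(hema), range = c(0, max(hema)))
  nucBin <- hema > thr
  nucBin <- EBImage::fillHull(nucBin)
  dm <- EBImage::distmap(EBImage::Image(matrix(as.numeric(nucBin), H, W)))
  nucLab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  nucLab <- matrix(as.integer(nucLab), H, W)
  # drop specks far smaller than a nucleus
  sizes <- tabulate(nucLab)
  tooSmall <- which(sizes < 0.3 * pi * rn^2)
  if (length(tooSmall) > 0) nucLab[nucLab %in% tooSmall] <- 0L
  if (!any(nucLab > 0)) return(emptySet())
  # relabel 1..n
  ids <- sort(unique(nucLab[nucLab > 0]))
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  nucLab[nucLab > 0] <- remap[nucLab[nucLab > 0]]
  n <- length(ids)
  # expand nuclei to cell bodies, capped by neighbours
  brush <- EBImage::makeBrush(2 * round(rc - rn) + 1, shape = "disc")
  allowed <- EBImage::dilate(nucLab > 0, brush)
  cellLab <- EBImage::propagate(EBImage::Image(hema * 0),
                                seeds = EBImage::Image(nucLab),
                                mask = allowed)
  cellLab <- matrix(as.integer(cellLab), H, W)
  # exclude cells touching the frame edge (degenerate ring)
  edgeIds <- unique(c(cellLab[1, ], cellLab[H, ], cellLab[, 1], cellLab[, W]))
  edgeIds <- edgeIds[edgeIds > 0]
  excluded <- length(edgeIds)
  if (excluded > 0) {
    cellLab[cellLab %in% edgeIds] <- 0L
    nucLab[nucLab %in% edgeIds] <- 0L
    keep <- setdiff(seq_len(n), edgeIds)
    remap2 <- integer(n); remap2[keep] <- seq_along(keep)
    cellLab[cellLab > 0] <- remap2[cellLab[cellLab > 0]]
    nucLab[nucLab > 0] <- remap2[nucLab[nucLab > 0]]
    n <- length(keep)
    if (n == 0) return(emptySet())
  }
  # ring and cytoplasm, per cell on cropped bounding boxes
  ringLab <- matrix(0L, H, W)
  cytoLab <- matrix(0L, H, W)
  idxByCell <- split(which(cellLab > 0), cellLab[cellLab > 0])
  nucIdxByCell <- split(which(nucLab > 0), nucLab[nucLab > 0])
  centroids <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    idx <- idxByCell[[as.character(i)]]
    rows <- (idx - 1L) %% H + 1L
    cols <- (idx - 1L) %/% H + 1L
    centroids[i, ] <- c(mean(rows), mean(cols))
    r0 <- min(rows) - 1L; r1 <- max(rows) + 1L
    c0 <- min(cols) - 1L; c1 <- max(cols) + 1L
    own <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    own[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
    dcrop <- as.matrix(EBImage::distmap(
      matrix(as.numeric(own), nrow(own), ncol(own))))
    isRing <- own & dcrop <= rt
    ringIdx <- idx[isRing[cbind(rows - r0 + 1L, cols - c0 + 1L)]]
    ringLab[ringIdx] <- i
    cytoIdx <- setdiff(idx, c(ringIdx, nucIdxByCell[[as.character(i)]]))
    cytoLab[cytoIdx] <- i
  }
  # nucleus pixels claimed by the ring band stay ring; keep compartments
  # disjoint by removing ring overlap from the nucleus map
  nucOut <- nucLab
  nucOut[ringLab > 0] <- 0L
  cells <- data.frame(cell_id = seq_len(n),
                      centroid_row = centroids[, 1],
                      centroid_col = centroids[, 2],
                      area_px = as.integer(lengths(idxByCell)),
                      is_tumor = NA,
                      stringsAsFactors = FALSE)
  new("CellSet", cells = cells, cellMap = cellLab, nucleusMap = nucOut,
      ringMap = ringLab, cytoplasmMap = cytoLab,
      excluded = as.integer(excluded))
}

# Mean of a density map per cell over a compartment label map.
.meanByLabel <- function(density, labMap, n) {
  sel <- labMap > 0
  if (!any(sel)) return(rep(NA_real_, n))
  sums <- rowsum(density[sel], labMap[sel])
  cnts <- rowsum(rep(1, sum(sel)), labMap[sel])
  out <- rep(NA_real_, n)
  out[as.integer(rownames(sums))] <- sums[, 1] / cnts[, 1]
  out
}

#' Gate tumor cells by cytokeratin-18 / Vector Red
#'
#' In co-cultures the tumor cells are specifically labelled by Vector Red
#' (CK-18), so a cell is gated as tumor when its mean Vector Red OD over
#' the whole cell mask exceeds `ck18_threshold`.
#'
#' @param cells a [CellSet-class] from [segmentCells()].
#' @param vrDensity Vector Red density map from [deconvolveStains()].
#' @param config an [AnalysisConfig-class].
#' @return The [CellSet-class] with `is_tumor` and `vr_mean_od` filled in.
#' @export
gateTumorCells <- function(cells, vrDensity, config = defaultConfig()) {
  stopifnot(is(cells, "CellSet"))
  n <- nrow(cells@cells)
  if (n == 0) return(cells)
  vr <- .meanByLabel(vrDensity, cells@cellMap, n)
  cells@cells$vr_mean_od <- vr
  cells@cells$is_tumor <- vr > cfgParam(config, "ck18_threshold")
  cells
}

.checkGated <- function(cells) {
  if (nrow(cells@cells) > 0 && any(is.na(cells@cells$is_tumor)))
    .stopf("cells must be gated with gateTumorCells() before scoring")
}

.newScore <- function(marker, rule, considered, positive, excluded = 0L,
                      flag = "") {
  frac <- if (considered > 0) positive / considered else NA_real_
  if (considered == 0 && flag == "") flag <- "no_tumor_cells"
  new("MarkerScore", marker = marker, rule = rule,
      nCellsConsidered = as.integer(considered),
      nPositive = as.integer(positive), positiveFraction = frac,
      excluded = as.integer(excluded), flag = flag)
}

#' Nuclear positivity scoring (Ki67, beta-catenin)
#'
#' Among gated tumor cells, a cell is positive when the mean DAB OD over
#' its nucleus exceeds the marker's OD threshold; nuclei are counted
#' positive or negative and reported as a fraction.
#'
#' @param cells a gated [CellSet-class].
#' @param dabDensity DAB density map.
#' @param marker `"Ki67"` or `"bCatenin"`.
#' @param config an [AnalysisConfig-class].
#' @return A [MarkerScore-class] with rule `"nuclear"`.
#' @export
scoreNuclear <- function(cells, dabDensity, marker = c("Ki67", "bCatenin"),
                         config = defaultConfig()) {
  marker <- match.arg(marker)
  .checkGated(cells)
  n <- nrow(cells@cells)
  tumor <- if (n > 0) which(cells@cells$is_tumor) else integer(0)
  if (length(tumor) == 0)
    return(.newScore(marker, "nuclear", 0L, 0L, cells@excluded))
  nucOD <- .meanByLabel(dabDensity, cells@nucleusMap, n)
  pos <- sum(nucOD[tumor] > odThreshold(config, marker), na.rm = TRUE)
  .newScore(marker, "nuclear", length(tumor), pos, cells@excluded)
}

# Sector completeness of ring DAB signal for every cell. Returns the
# fraction (of `nSectors` equal angular sectors around the cell centroid)
# whose mean OD exceeds `thr`.
.ringCompleteness <- function(cells, dabDensity, thr, nSectors) {
  n <- nrow(cells@cells)
  H <- nrow(cells@ringMap)
  sel <- which(cells@ringMap > 0)
  out <- rep(0, n)
  if (length(sel) == 0) return(out)
  id <- cells@ringMap[sel]
  rows <- (sel - 1L) %% H + 1L
  cols <- (sel - 1L) %/% H + 1L
  ang <- atan2(rows - cells@cells$centroid_row[id],
               cols - cells@cells$centroid_col[id])
  sector <- pmin(floor((ang + pi) / (2 * pi) * nSectors), nSectors - 1)
  key <- id * nSectors + sector
  sums <- rowsum(dabDensity[sel], key)
  cnts <- rowsum(rep(1, length(sel)), key)
  mu <- sums[, 1] / cnts[, 1]
  keyId <- as.numeric(rownames(sums)) %/% nSectors
  posSectors <- tapply(mu > thr, keyId, sum)
  out[as.integer(names(posSectors))] <- posSectors / nSectors
  out
}

#' Complete-membrane positivity scoring (E-cadherin, N-cadherin, CD44, CD133)
#'
#' The membrane ring of each gated tumor cell is divided into
#' `membrane_sectors` equal angular sectors around the cell centroid; a
#' sector is stained when its mean DAB OD exceeds the marker threshold, and
#' membrane completeness is the fraction of stained sectors. A cell is
#' positive when completeness reaches `membrane_completeness_min`
#' (default 0.95, operationalizing "complete membrane localization").
#' For N-cadherin a cell is additionally positive when the nuclear rule
#' fires, since nuclear signal indicates cytoplasmic marker not yet
#' localized to the membrane.
#'
#' @param cells a gated [CellSet-class].
#' @param dabDensity DAB density map.
#' @param marker one of `"ECadherin"`, `"NCadherin"`, `"CD44"`, `"CD133"`.
#' @param config an [AnalysisConfig-class].
#' @return A [MarkerScore-class] with rule `"membrane_complete"` (or
#'   `"membrane_or_nuclear"` for N-cadherin).
#' @export
scoreMembrane <- function(cells, dabDensity,
                          marker = c("ECadherin", "NCadherin", "CD44", "CD133"),
                          config = defaultConfig()) {
  marker <- match.arg(marker)
  .checkGated(cells)
  rule <- if (marker == "NCadherin") "membrane_or_nuclear" else
    "membrane_complete"
  n <- nrow(cells@cells)
  tumor <- if (n > 0) which(cells@cells$is_tumor) else integer(0)
  if (length(tumor) == 0)
    return(.newScore(marker, rule, 0L, 0L, cells@excluded))
  thr <- odThreshold(config, marker)
  comp <- .ringCompleteness(cells, dabDensity, thr,
                            cfgParam(config, "membrane_sectors"))
  posCell <- comp >= cfgParam(config, "membrane_completeness_min")
  if (marker == "NCadherin") {
    nucOD <- .meanByLabel(dabDensity, cells@nucleusMap, n)
    posCell <- posCell | (!is.na(nucOD) & nucOD > thr)
  }
  .newScore(marker, rule, length(tumor), sum(posCell[tumor]),
            cells@excluded)
}

#' Stained area-fraction scoring (FAK)
#'
#' The FAK readout is the ratio of positively stained tumor area to total
#' tumor area: the fraction of tumor-region pixels whose DAB OD exceeds
#' the FAK threshold.
#'
#' @param tumorMask a [RegionMask-class] of the tumor region (e.g. from
#'   [tumorRegionMask()]); must be non-empty.
#' @param dabDensity DAB density map.
#' @param config an [AnalysisConfig-class].
#' @return A [MarkerScore-class] with rule `"area_fraction"`.
#' @export
scoreAreaFraction <- function(tumorMask, dabDensity,
                              config = defaultConfig()) {
  stopifnot(is(tumorMask, "RegionMask"))
  mm <- maskMatrix(tumorMask)
  if (!any(mm))
    .stopf("area-fraction scoring is undefined for an empty tumor mask")
  frac <- sum(dabDensity[mm] > odThreshold(config, "FAK")) / sum(mm)
  new("MarkerScore", marker = "FAK", rule = "area_fraction",
      nCellsConsidered = 0L, nPositive = NA_integer_,
      positiveFraction = frac, excluded = 0L, flag = "")
}

#' Union of gated tumor-cell masks
#'
#' @param cells a gated [CellSet-class].
#' @return A [RegionMask-class] labelled `"tumor"`.
#' @export
tumorRegionMask <- function(cells) {
  .checkGated(cells)
  ids <- cells@cells$cell_id[cells@cells$is_tumor]
  RegionMask(matrix(cells@cellMap %in% ids,
                    nrow(cells@cellMap), ncol(cells@cellMap)),
             label = "tumor")
}

#' Apoptosis scoring by membrane plus cytoplasmic signal (Caspase 3)
#'
#' A gated tumor cell is positive when the mean DAB OD over the union of
#' its membrane ring and cytoplasm exceeds the Caspase3 threshold.
#'
#' @param cells a gated [CellSet-class].
#' @param dabDensity DAB density map.
#' @param config an [AnalysisConfig-class].
#' @return A [MarkerScore-class] with rule `"membrane_cytoplasmic"`.
#' @export
scoreCaspase <- function(cells, dabDensity, config = defaultConfig()) {
  .checkGated(cells)
  n <- nrow(cells@cells)
  tumor <- if (n > 0) which(cells@cells$is_tumor) else integer(0)
  if (length(tumor) == 0)
    return(.newScore("Caspase3", "membrane_cytoplasmic", 0L, 0L,
                     cells@excluded))
  both <- cells@ringMap
  both[both == 0L] <- cells@cytoplasmMap[both == 0L]
  od <- .meanByLabel(dabDensity, both, n)
  pos <- sum(od[tumor] > odThreshold(config, "Caspase3"), na.rm = TRUE)
  .newScore("Caspase3", "membrane_cytoplasmic", length(tumor), pos,
            cells@excluded)
}

#' Score any supported marker with its published rule
#'
#' Dispatches to the rule the marker calls for: nuclear counting for Ki67
#' and beta-catenin; complete-membrane counting for E-cadherin, CD44 and
#' CD133; membrane-or-nuclear for N-cadherin; stained area fraction of the
#' tumor region for FAK; membrane-plus-cytoplasm for Caspase 3.
#'
#' @param cells a gated [CellSet-class].
#' @param densities density-map list from [deconvolveStains()].
#' @param marker one of the eight supported markers.
#' @param config an [AnalysisConfig-class].
#' @return A [MarkerScore-class].
#' @export
scoreMarker <- function(cells, densities, marker, config = defaultConfig()) {
  stopifnot(marker %in% .MARKERS)
  dab <- densities$dab
  switch(marker,
    Ki67 = , bCatenin = scoreNuclear(cells, dab, marker, config),
    ECadherin = , NCadherin = , CD44 = , CD133 =
      scoreMembrane(cells, dab, marker, config),
    FAK = scoreAreaFraction(tumorRegionMask(cells), dab, config),
    Caspase3 = scoreCaspase(cells, dab, config))
}
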