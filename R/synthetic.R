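#' @include AllClasses.R config.R
NULL

# ---- shared rendering helpers -------------------------------------------

# Anti-aliased capsule (segment with round caps) coverage. Returns a list
# with linear pixel indices into an H x W matrix and per-pixel coverage in
# [0, 1]. Coordinates are (row, col); `angle_deg` is axial with y pointing
# up, so the column offset is +cos and the row offset is -sin.
.capsuleCoverage <- function(cr, cc, angle_deg, length_px, width_px, H, W) {
  th <- angle_deg * pi / 180
  dr <- -sin(th) * length_px / 2
  dc <- cos(th) * length_px / 2
  p1 <- c(cr - dr, cc - dc)
  p2 <- c(cr + dr, cc + dc)
  pad <- width_px / 2 + 1.5
  r0 <- max(1, floor(min(p1[1], p2[1]) - pad))
  r1 <- min(H, ceiling(max(p1[1], p2[1]) + pad))
  c0 <- max(1, floor(min(p1[2], p2[2]) - pad))
  c1 <- min(W, ceiling(max(p1[2], p2[2]) + pad))
  if (r0 > r1 || c0 > c1)
    return(list(idx = integer(0), cov = numeric(0)))
  rr <- r0:r1
  cc2 <- c0:c1
  gr <- rep(rr, times = length(cc2))
  gc <- rep(cc2, each = length(rr))
  # distance from each pixel centre to the segment p1-p2
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  L2 <- vx^2 + vy^2
  if (L2 < 1e-12) {
    d <- sqrt((gr - p1[1])^2 + (gc - p1[2])^2)
  } else {
    t <- pmin(1, pmax(0, ((gr - p1[1]) * vx + (gc - p1[2]) * vy) / L2))
    d <- sqrt((gr - p1[1] - t * vx)^2 + (gc - p1[2] - t * vy)^2)
  }
  cov <- pmin(1, pmax(0, width_px / 2 + 0.5 - d))
  keep <- cov > 0
  list(idx = (gc[keep] - 1L) * H + gr[keep], cov = cov[keep])
}

.diskIdx <- function(cr, cc, radius, H, W) {
  co <- .diskCoords(cr, cc, radius, H, W)
  (co[, 2] - 1L) * H + co[, 1]
}

# Annulus r in (inner, outer], as linear indices.
.annulusIdx <- function(cr, cc, inner, outer, H, W) {
  co <- .diskCoords(cr, cc, outer, H, W)
  d2 <- (co[, 1] - cr)^2 + (co[, 2] - cc)^2
  keep <- d2 > inner^2
  co <- co[keep, , drop = FALSE]
  (co[, 2] - 1L) * H + co[, 1]
}

# ---- fiber fields --------------------------------------------------------

#' Specification of a synthetic polarized-light fiber field
#'
#' Parameterizes a field of straight, anti-aliased collagen fiber capsules
#' on a dark background, emulating picrosirius-red birefringence under
#' crossed polarizers. Fiber hue encodes bundling: the drawn hue is
#' `160 - 150 * clip(bundling * (width - w_min) / (w_max - w_min), 0, 1)`
#' degrees, so thin fibers render green (160 deg) and thick ones red
#' (10 deg), an invertible stand-in for the bundling-hue relation of mature
#' versus immature collagen.
#'
#' @param n_fibers number of fibers (>= 0).
#' @param angle_model either `list(type = "uniform_axial")` or
#'   `list(type = "von_mises_axial", mu_deg = , kappa = )`; axial angles in
#'   `[0, 180)` degrees.
#' @param length_model,width_model lognormal models
#'   `list(mu_log = , sigma_log = )` in pixels.
#' @param bundling real in `[0, 1]` scaling the width-to-hue mapping.
#' @param background_noise_sd Gaussian RGB noise added to the composed frame.
#' @param image_hw integer `(H, W)`, both >= 64.
#' @param w_min,w_max width range anchoring the hue mapping.
#' @param seed RNG seed; equal specs produce bit-identical images.
#' @return A list of class `FiberFieldSpec`.
#' @seealso [simulateFiberField()]
#' @export
fiberFieldSpec <- function(n_fibers = 200,
                           angle_model = list(type = "uniform_axial"),
                           length_model = list(mu_log = log(60), sigma_log = 0.3),
                           width_model = list(mu_log = log(6), sigma_log = 0.25),
                           bundling = 0.5, background_noise_sd = 0.01,
                           image_hw = c(1024, 1024), w_min = 2, w_max = 12,
                           seed = 1) {
  stopifnot(n_fibers >= 0, image_hw[1] >= 64, image_hw[2] >= 64,
            bundling >= 0, bundling <= 1)
  if (angle_model$type == "von_mises_axial")
    stopifnot(angle_model$kappa >= 0)
  structure(list(n_fibers = as.integer(n_fibers), angle_model = angle_model,
                 length_model = length_model, width_model = width_model,
                 bundling = bundling,
                 background_noise_sd = background_noise_sd,
                 image_hw = as.integer(image_hw), w_min = w_min,
                 w_max = w_max, seed = as.integer(seed)),
            class = "FiberFieldSpec")
}

.sampleAxialAngles <- function(n, model) {
  if (model$type == "uniform_axial") {
    stats::runif(n, 0, 180)
  } else if (model$type == "von_mises_axial") {
    th <- .rvonmises(n, 2 * model$mu_deg * pi / 180, model$kappa)
    (th * 180 / pi / 2) %% 180
  } else .stopf("unknown angle model '%s'", model$type)
}

.bundlingHue <- function(width, bundling, w_min, w_max) {
  160 - 150 * pmin(1, pmax(0, bundling * (width - w_min) / (w_max - w_min)))
}

#' Render a synthetic polarized-light fiber field with ground truth
#'
#' Draws each fiber as an anti-aliased straight capsule whose HSV value is
#' the pixel coverage and whose hue follows the bundling-width mapping of
#' [fiberFieldSpec()]; overlaps keep the brighter contribution. Gaussian
#' background noise is added to the composed RGB frame. Fibers are sampled
#' with centres inside the frame; a fiber that would fall entirely outside
#' is resampled (at most 100 attempts).
#'
#' @param spec a [fiberFieldSpec()].
#' @return A list with elements `image` (a [RasterImage-class], modality
#'   PSR) and `truth`, itself a list with `fibers` (a [FiberSet-class] of
#'   the true angles/lengths/widths), `hues` (drawn hue per fiber, degrees)
#'   and `spec`.
#' @examples
#' ff <- simulateFiberField(fiberFieldSpec(n_fibers = 20,
#'   image_hw = c(256, 256), seed = 7))
#' nFibers(ff$truth$fibers)
#' @export
simulateFiberField <- function(spec) {
  stopifnot(inherits(spec, "FiberFieldSpec"))
  set.seed(spec$seed)
  H <- spec$image_hw[1]; W <- spec$image_hw[2]
  n <- spec$n_fibers
  vmap <- matrix(0, H, W)
  hmap <- matrix(0, H, W)
  ang <- len <- wid <- hue <- numeric(n)
  rows <- cols <- numeric(n)
  polylines <- vector("list", n)
  for (i in seq_len(n)) {
    for (attempt in seq_len(100)) {
      a <- .sampleAxialAngles(1, spec$angle_model)
      L <- stats::rlnorm(1, spec$length_model$mu_log, spec$length_model$sigma_log)
      w <- stats::rlnorm(1, spec$width_model$mu_log, spec$width_model$sigma_log)
      # keep the whole capsule inside the frame when it fits, so the
      # ground truth is exact; otherwise fall back to centre-inside
      th <- a * pi / 180
      mr <- abs(sin(th)) * L / 2 + w / 2 + 1
      mc <- abs(cos(th)) * L / 2 + w / 2 + 1
      cr <- if (H - mr > 1 + mr) stats::runif(1, 1 + mr, H - mr) else
        stats::runif(1, 1, H)
      cc <- if (W - mc > 1 + mc) stats::runif(1, 1 + mc, W - mc) else
        stats::runif(1, 1, W)
      cap <- .capsuleCoverage(cr, cc, a, L, w, H, W)
      if (length(cap$idx) > 0) break
      if (attempt == 100)
        .stopf("could not place fiber %d inside the frame", i)
    }
    hu <- .bundlingHue(w, spec$bundling, spec$w_min, spec$w_max)
    ang[i] <- a; len[i] <- L; wid[i] <- w; hue[i] <- hu
    rows[i] <- cr; cols[i] <- cc
    brighter <- cap$cov > vmap[cap$idx]
    vmap[cap$idx][brighter] <- cap$cov[brighter]
    hmap[cap$idx][brighter] <- hu
    th <- a * pi / 180
    polylines[[i]] <- cbind(
      row = c(cr + sin(th) * L / 2, cr - sin(th) * L / 2),
      col = c(cc - cos(th) * L / 2, cc + cos(th) * L / 2))
  }
  rgb <- .hsv2rgb(as.vector(hmap), 1, as.vector(vmap))
  px <- array(rgb, c(H, W, 3))
  if (spec$background_noise_sd > 0)
    px <- px + stats::rnorm(length(px), 0, spec$background_noise_sd)
  px <- array(pmin(1, pmax(0, px)), c(H, W, 3))
  fibers <- if (n == 0) FiberSet() else FiberSet(
    data.frame(id = seq_len(n), angle_deg = ang, length_px = len,
               width_px = wid, sample = "synthetic", region = "",
               condition = "", stringsAsFactors = FALSE),
    polylines = polylines)
  list(image = RasterImage(px, modality = "PSR"),
       truth = list(fibers = fibers, hues = hue, spec = spec))
}

# ---- IHC fields ----------------------------------------------------------

#' Specification of a synthetic dual-chromogen IHC field
#'
#' Cells are disks placed on a jittered grid with centre spacing strictly
#' greater than twice the cell radius (guaranteeing segmentability), each
#' with a nuclear disk, a membrane ring and cytoplasm. Hematoxylin stains
#' every nucleus; Vector Red stains the full cell body of tumor
#' (cytokeratin-18 positive) cells; DAB carries the marker signal in the
#' compartment dictated by the marker: nuclear for Ki67 and beta-catenin,
#' full membrane ring for E-cadherin/CD44/CD133, membrane ring or nucleus
#' for N-cadherin, diffuse cytoplasm plus membrane for Caspase3, and a
#' diffuse regional patch covering `positive_fraction` of the tumor area
#' for FAK. Marker-negative cells of the membrane rules receive at most
#' `membrane_completeness_of_negatives` of the ring (a partial arc). The
#' image is composed by the Beer-Lambert model: per-pixel OD is the sum of
#' stain densities times their OD vectors, Gaussian OD noise is added, and
#' transmitted RGB is `exp(-OD)` channel-wise.
#'
#' @param n_cells number of cells.
#' @param tumor_fraction fraction of cells that are tumor (Vector Red
#'   positive); non-tumor cells are never marker-positive.
#' @param marker one of `"Ki67"`, `"bCatenin"`, `"ECadherin"`,
#'   `"NCadherin"`, `"FAK"`, `"CD44"`, `"CD133"`, `"Caspase3"`.
#' @param positive_fraction fraction of tumor cells positive for the marker
#'   (for FAK: the stained fraction of the tumor area).
#' @param membrane_completeness_of_negatives ring arc fraction drawn on
#'   marker-negative cells, in `[0, 1)`.
#' @param ncad_nuclear_fraction fraction of N-cadherin-positive cells whose
#'   signal is nuclear rather than membranous.
#' @param nucleus_radius_px,cell_radius_px,ring_thickness_px cell geometry.
#' @param stain_vectors a [StainVectorSet-class].
#' @param density_hema,density_marker,density_vr stain densities (OD units)
#'   drawn into the respective compartments.
#' @param noise_sd_od Gaussian OD noise standard deviation.
#' @param image_hw integer `(H, W)`.
#' @param seed RNG seed.
#' @return A list of class `IhcFieldSpec`.
#' @seealso [simulateIhcField()]
#' @export
ihcFieldSpec <- function(n_cells = 100, tumor_fraction = 0.7,
                         marker = "Ki67", positive_fraction = 0.3,
                         membrane_completeness_of_negatives = 0.5,
                         ncad_nuclear_fraction = 0.5,
                         nucleus_radius_px = 5, cell_radius_px = 12,
                         ring_thickness_px = 3,
                         stain_vectors = defaultStainVectors(),
                         density_hema = 0.65, density_marker = 0.7,
                         density_vr = 0.5,
                         noise_sd_od = 0.02, image_hw = NULL, seed = 1) {
  stopifnot(marker %in% .MARKERS,
            nucleus_radius_px < cell_radius_px,
            tumor_fraction >= 0, tumor_fraction <= 1,
            positive_fraction >= 0, positive_fraction <= 1,
            membrane_completeness_of_negatives >= 0,
            membrane_completeness_of_negatives < 1)
  if (is.null(image_hw)) {
    # frame sized to hold n_cells on the placement grid with a margin
    s <- 2 * cell_radius_px + 4
    k <- ceiling(sqrt(n_cells))
    side <- k * s + 2 * cell_radius_px + 8
    image_hw <- c(side, side)
  }
  structure(list(n_cells = as.integer(n_cells),
                 tumor_fraction = tumor_fraction, marker = marker,
                 positive_fraction = positive_fraction,
                 membrane_completeness_of_negatives =
                   membrane_completeness_of_negatives,
                 ncad_nuclear_fraction = ncad_nuclear_fraction,
                 nucleus_radius_px = nucleus_radius_px,
                 cell_radius_px = cell_radius_px,
                 ring_thickness_px = ring_thickness_px,
                 stain_vectors = stain_vectors,
                 density_hema = density_hema,
                 density_marker = density_marker, density_vr = density_vr,
                 noise_sd_od = noise_sd_od,
                 image_hw = as.integer(image_hw), seed = as.integer(seed)),
            class = "IhcFieldSpec")
}

# Contiguous arc of the membrane ring covering `frac` of the angular range,
# starting at `start_deg`.
.ringArcIdx <- function(cr, cc, inner, outer, frac, start_deg, H, W) {
  co <- .diskCoords(cr, cc, outer, H, W)
  d2 <- (co[, 1] - cr)^2 + (co[, 2] - cc)^2
  co <- co[d2 > inner^2, , drop = FALSE]
  if (frac <= 0 || nrow(co) == 0) return(integer(0))
  ang <- (atan2(co[, 1] - cr, co[, 2] - cc) * 180 / pi - start_deg) %% 360
  keep <- ang < frac * 360
  (co[keep, 2] - 1L) * H + co[keep, 1]
}

#' Render a synthetic IHC field with per-cell ground truth
#'
#' @param spec an [ihcFieldSpec()].
#' @return A list with `image` (a [RasterImage-class], modality IHC),
#'   `densities` (list of noise-free `H x W` density maps `hematoxylin`,
#'   `dab`, `vector_red`) and `truth`: a data.frame `cells` (one row per
#'   cell: `cell_id`, `row`, `col`, `is_tumor`, `is_positive`,
#'   `compartment`), `fak_area_fraction` (exact painted fraction of the
#'   tumor area, FAK fields only) and `spec`.
#' @examples
#' f <- simulateIhcField(ihcFieldSpec(n_cells = 25, seed = 3))
#' table(f$truth$cells$is_tumor)
#' @export
simulateIhcField <- function(spec) {
  stopifnot(inherits(spec, "IhcFieldSpec"))
  set.seed(spec$seed)
  H <- spec$image_hw[1]; W <- spec$image_hw[2]
  n <- spec$n_cells
  rc <- spec$cell_radius_px; rn <- spec$nucleus_radius_px
  rt <- spec$ring_thickness_px
  s <- 2 * rc + 4
  margin <- rc + 4
  gr <- if (H - margin >= margin) seq(margin, H - margin, by = s) else numeric(0)
  gc <- if (W - margin >= margin) seq(margin, W - margin, by = s) else numeric(0)
  capacity <- length(gr) * length(gc)
  if (capacity < n)
    .stopf(paste("cannot place %d non-overlapping cells in a %d x %d frame;",
                 "use a larger frame"), n, H, W)
  slots <- expand.grid(row = gr, col = gc)
  pick <- sample.int(capacity, n)
  centers <- cbind(slots$row[pick] + stats::runif(n, -1, 1),
                   slots$col[pick] + stats::runif(n, -1, 1))
  nTumor <- round(spec$tumor_fraction * n)
  isTumor <- rep(FALSE, n)
  isTumor[sample.int(n, nTumor)] <- TRUE
  isPos <- rep(FALSE, n)
  tumorIdx <- which(isTumor)
  if (spec$marker != "FAK" && nTumor > 0) {
    nPos <- round(spec$positive_fraction * nTumor)
    isPos[tumorIdx[sample.int(nTumor, nPos)]] <- TRUE
  }
  dHema <- matrix(0, H, W)
  dDab <- matrix(0, H, W)
  dVr <- matrix(0, H, W)
  compartment <- rep("", n)
  ncadNuclear <- spec$marker == "NCadherin" &
    stats::runif(n) < spec$ncad_nuclear_fraction
  membraneRules <- c("ECadherin", "NCadherin", "CD44", "CD133")
  for (i in seq_len(n)) {
    cr <- centers[i, 1]; cc <- centers[i, 2]
    nucIdx <- .diskIdx(cr, cc, rn, H, W)
    dHema[nucIdx] <- spec$density_hema
    if (isTumor[i])
      dVr[.diskIdx(cr, cc, rc, H, W)] <- spec$density_vr
    if (spec$marker %in% c("Ki67", "bCatenin")) {
      if (isPos[i]) {
        dDab[nucIdx] <- spec$density_marker
        compartment[i] <- "nucleus"
      }
    } else if (spec$marker %in% membraneRules) {
      if (isPos[i]) {
        if (spec$marker == "NCadherin" && ncadNuclear[i]) {
          dDab[nucIdx] <- spec$density_marker
          compartment[i] <- "nucleus"
        } else {
          dDab[.annulusIdx(cr, cc, rc - rt, rc, H, W)] <- spec$density_marker
          compartment[i] <- "membrane"
        }
      } else if (isTumor[i] &&
                 spec$membrane_completeness_of_negatives > 0) {
        arc <- .ringArcIdx(cr, cc, rc - rt, rc,
                           spec$membrane_completeness_of_negatives,
                           stats::runif(1, 0, 360), H, W)
        dDab[arc] <- spec$density_marker
      }
    } else if (spec$marker == "Caspase3") {
      if (isPos[i]) {
        dDab[.annulusIdx(cr, cc, rn, rc, H, W)] <- spec$density_marker
        compartment[i] <- "membrane_cytoplasm"
      }
    }
  }
  fakFraction <- NA_real_
  if (spec$marker == "FAK" && nTumor > 0) {
    tumorMask <- matrix(FALSE, H, W)
    for (i in tumorIdx)
      tumorMask[.diskIdx(centers[i, 1], centers[i, 2], rc, H, W)] <- TRUE
    tpx <- which(tumorMask)
    field <- matrix(stats::rnorm(H * W), H, W)
    field <- as.matrix(EBImage::gblur(field, sigma = rc))
    nPaint <- round(spec$positive_fraction * length(tpx))
    paint <- tpx[order(field[tpx], decreasing = TRUE)[seq_len(nPaint)]]
    dDab[paint] <- spec$density_marker
    fakFraction <- nPaint / length(tpx)
  }
  V <- spec$stain_vectors@vectors
  od <- array(0, c(H, W, 3))
  for (ch in 1:3)
    od[, , ch] <- dHema * V[1, ch] + dDab * V[2, ch] + dVr * V[3, ch]
  if (spec$noise_sd_od > 0)
    od <- od + stats::rnorm(length(od), 0, spec$noise_sd_od)
  px <- array(pmin(1, pmax(0, exp(-od))), c(H, W, 3))
  cells <- data.frame(cell_id = seq_len(n), row = centers[, 1],
                      col = centers[, 2], is_tumor = isTumor,
                      is_positive = isPos, compartment = compartment,
                      stringsAsFactors = FALSE)
  list(image = RasterImage(px, modality = "IHC"),
       densities = list(hematoxylin = dHema, dab = dDab, vector_red = dVr),
       truth = list(cells = cells, fak_area_fraction = fakFraction,
                    spec = spec))
}

# ---- spheroids and vessels ----------------------------------------------

#' Render a series of synthetic spheroid frames
#'
#' Each frame holds one filled disk of the requested diameter, optionally
#' with thin radial spurs emulating the migratory protrusions of
#' mesenchymal-like spheroids; the ground-truth diameter is that of the
#' disk, spurs excluded.
#'
#' @param diameters_px disk diameters, each `< min(H, W)`.
#' @param protrusion_count number of radial spurs per frame.
#' @param image_hw integer `(H, W)`.
#' @param seed RNG seed (spur angles are jittered).
#' @param protrusion_length_px,protrusion_width_px spur geometry.
#' @return A list with one element per diameter, each holding `image` (an
#'   H&E-like [RasterImage-class]), `mask` (a [RegionMask-class] of the
#'   spheroid including spurs) and `truth`
#'   (`diameter_px`, `protrusions`).
#' @export
simulateSpheroidSeries <- function(diameters_px, protrusion_count = 0,
                                   image_hw = c(256, 256), seed = 1,
                                   protrusion_length_px = 15,
                                   protrusion_width_px = 2) {
  H <- image_hw[1]; W <- image_hw[2]
  stopifnot(all(diameters_px < min(H, W)), all(diameters_px > 0))
  set.seed(seed)
  lapply(diameters_px, function(d) {
    cr <- H / 2; cc <- W / 2
    mask <- matrix(FALSE, H, W)
    mask[.diskIdx(cr, cc, d / 2, H, W)] <- TRUE
    if (protrusion_count > 0) {
      angs <- seq(0, 360, length.out = protrusion_count + 1)[-1] +
        stats::runif(protrusion_count, -5, 5)
      for (a in angs) {
        th <- a * pi / 180
        mid_r <- d / 2 + protrusion_length_px / 2
        cap <- .capsuleCoverage(cr - sin(th) * mid_r, cc + cos(th) * mid_r,
                                a %% 180, protrusion_length_px,
                                protrusion_width_px, H, W)
        mask[cap$idx[cap$cov > 0.5]] <- TRUE
      }
    }
    px <- array(0.97, c(H, W, 3))
    for (ch in 1:3)
      px[, , ch][mask] <- c(0.85, 0.45, 0.60)[ch]
    list(image = RasterImage(px, modality = "HE"),
         mask = RegionMask(mask, label = "spheroid"),
         truth = list(diameter_px = d, protrusions = protrusion_count))
  })
}

#' Render a synthetic vessel field
#'
#' Vessels are drawn as stained annular walls with bright lumens on a pale
#' tissue background; lumens do not overlap. Ground truth records the
#' vessel count and per-lumen geometry.
#'
#' @param n_vessels number of vessels.
#' @param lumen_radius_range `(lo, hi)` lumen radii in px.
#' @param image_hw integer `(H, W)`.
#' @param seed RNG seed.
#' @param wall_thickness_px annular wall thickness.
#' @return A list with `image` (a [RasterImage-class], modality HE) and
#'   `truth`: `count`, and a data.frame `lumens` with `row`, `col`,
#'   `radius_px`, `area_px` (analytic `pi r^2`) and `area_px_rendered`
#'   (pixel count of the rendered lumen).
#' @export
simulateVesselField <- function(n_vessels, lumen_radius_range = c(8, 14),
                                image_hw = c(512, 512), seed = 1,
                                wall_thickness_px = 4) {
  set.seed(seed)
  H <- image_hw[1]; W <- image_hw[2]
  px <- array(0, c(H, W, 3))
  px[, , 1] <- 0.93; px[, , 2] <- 0.88; px[, , 3] <- 0.90
  centers <- matrix(0, 0, 2)
  radii <- numeric(0)
  for (i in seq_len(n_vessels)) {
    placed <- FALSE
    for (attempt in seq_len(2000)) {
      r <- stats::runif(1, lumen_radius_range[1], lumen_radius_range[2])
      rOut <- r + wall_thickness_px
      cr <- stats::runif(1, rOut + 2, H - rOut - 2)
      cc <- stats::runif(1, rOut + 2, W - rOut - 2)
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2) >
              radii + wall_thickness_px + rOut + 2)) {
        centers <- rbind(centers, c(cr, cc))
        radii <- c(radii, r)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      .stopf(paste("cannot place %d non-overlapping vessels in a %d x %d",
                   "frame; use a larger frame"), n_vessels, H, W)
  }
  lumenArea <- integer(length(radii))
  for (i in seq_along(radii)) {
    cr <- centers[i, 1]; cc <- centers[i, 2]; r <- radii[i]
    wallIdx <- .annulusIdx(cr, cc, r, r + wall_thickness_px, H, W)
    lumIdx <- .diskIdx(cr, cc, r, H, W)
    for (ch in 1:3) {
      pl <- px[, , ch]
      pl[wallIdx] <- c(0.45, 0.15, 0.30)[ch]
      pl[lumIdx] <- 1
      px[, , ch] <- pl
    }
    lumenArea[i] <- length(lumIdx)
  }
  lumens <- data.frame(row = centers[, 1], col = centers[, 2],
                       radius_px = radii, area_px = pi * radii^2,
                       area_px_rendered = lumenArea)
  if (n_vessels == 0)
    lumens <- lumens[0, ]
  list(image = RasterImage(px, modality = "HE"),
       truth = list(count = as.integer(n_vessels), lumens = lumens))
}

#' Render a synthetic Masson's trichrome field
#'
#' Assigns exact pixel counts `round(blue_fraction * H * W)` and
#' `round(red_fraction * H * W)` to pure aniline-blue-like and
#' Biebrich-scarlet-like colors, spatially clustered into blobs by ranking
#' a Gaussian-smoothed noise field; the remainder is a pale, unstained
#' near-white background (which still counts as tissue for ratio
#' quantification).
#'
#' @param blue_fraction,red_fraction pixel fractions with
#'   `blue_fraction + red_fraction <= 1`.
#' @param image_hw integer `(H, W)`.
#' @param seed RNG seed.
#' @return A list with `image` (a [RasterImage-class], modality TRICHROME)
#'   and `truth`: exact `blue_px`, `red_px`, `background_px` counts and the
#'   input fractions.
#' @export
simulateTrichromeField <- function(blue_fraction, red_fraction,
                                   image_hw = c(256, 256), seed = 1) {
  stopifnot(blue_fraction >= 0, red_fraction >= 0,
            blue_fraction + red_fraction <= 1)
  set.seed(seed)
  H <- image_hw[1]; W <- image_hw[2]
  N <- H * W
  nBlue <- round(blue_fraction * N)
  nRed <- min(round(red_fraction * N), N - nBlue)
  field <- matrix(stats::rnorm(N), H, W)
  field <- as.matrix(EBImage::gblur(field, sigma = 8))
  ord <- order(as.vector(field), decreasing = TRUE)
  blueIdx <- ord[seq_len(nBlue)]
  redIdx <- rev(ord)[seq_len(nRed)]
  px <- array(0.92, c(H, W, 3))
  for (ch in 1:3) {
    pl <- px[, , ch]
    pl[blueIdx] <- c(0.10, 0.10, 0.90)[ch]
    pl[redIdx] <- c(0.90, 0.10, 0.10)[ch]
    px[, , ch] <- pl
  }
  list(image = RasterImage(px, modality = "TRICHROME"),
       truth = list(blue_px = as.integer(nBlue), red_px = as.integer(nRed),
                    background_px = as.integer(N - nBlue - nRed),
                    blue_fraction = blue_fraction,
                    red_fraction = red_fraction))
}
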