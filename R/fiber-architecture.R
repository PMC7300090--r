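#' @include AllClasses.R config.R
NULL

#' Segment birefringent collagen signal in a polarized-light PSR image
#'
#' Under crossed polarizers, picrosirius-red-stained collagen is bright and
#' saturated on a near-black field. Foreground pixels are those with HSV
#' value at least `birefringence_value_min` and saturation at least
#' `birefringence_saturation_min`; connected components smaller than
#' `min_component_px` are then removed as shot noise.
#'
#' @param image a [RasterImage-class] with modality `"PSR"`.
#' @param config an [AnalysisConfig-class].
#' @return A [RegionMask-class] labelled `"birefringent"`. An empty mask is
#'   returned (with a warning) when no pixel passes; downstream operations
#'   accept it and return empty results.
#' @export
segmentBirefringent <- function(image, config = defaultConfig()) {
  stopifnot(is(image, "RasterImage"))
  if (imageModality(image) != "PSR")
    .stopf("segmentBirefringent expects a PSR image, got %s",
           imageModality(image))
  hsv <- .rgb2hsvDeg(pixelArray(image))
  mask <- hsv$v >= cfgParam(config, "birefringence_value_min") &
          hsv$s >= cfgParam(config, "birefringence_saturation_min")
  minPx <- cfgParam(config, "min_component_px")
  if (minPx > 1 && any(mask)) {
    lab <- .label8(mask)
    sizes <- tabulate(lab)
    mask <- mask & (sizes[pmax(lab, 1L)] >= minPx) & lab > 0
  }
  if (!any(mask))
    .warnf("no birefringent signal found; returning an empty mask")
  RegionMask(mask, label = "birefringent")
}

# Order the pixels of one 8-connected skeleton segment into a polyline.
# coords is an m x 2 (row, col) matrix; returns the coords reordered along
# the path (greedy walk from an endpoint; side twigs, if any, are dropped).
.traceSegment <- function(coords) {
  m <- nrow(coords)
  if (m <= 2) return(coords)
  S <- max(coords) + 2L
  key <- coords[, 1] + coords[, 2] * S
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  nb <- matrix(NA_integer_, m, 8)
  for (k in 1:8)
    nb[, k] <- match(coords[, 1] + offs[k, 1] +
                     (coords[, 2] + offs[k, 2]) * S, key)
  deg <- rowSums(!is.na(nb))
  start <- which(deg == 1)[1]
  if (is.na(start)) start <- 1L
  visited <- logical(m)
  path <- integer(m)
  cur <- start
  len <- 0L
  repeat {
    visited[cur] <- TRUE
    len <- len + 1L
    path[len] <- cur
    nxt <- nb[cur, ]
    nxt <- nxt[!is.na(nxt) & !visited[nxt]]
    if (length(nxt) == 0) break
    cur <- nxt[1]
  }
  coords[path[seq_len(len)], , drop = FALSE]
}

# Smoothed arc length of an ordered polyline: anchor every `step` pixels
# (plus the endpoint) and sum Euclidean inter-anchor distances, which
# removes the 8-connectivity staircase bias.
.polylineLength <- function(coords, step = 5) {
  m <- nrow(coords)
  if (m < 2) return(0)
  anchors <- unique(c(seq(1, m, by = step), m))
  a <- coords[anchors, , drop = FALSE]
  sum(sqrt(diff(a[, 1])^2 + diff(a[, 2])^2))
}

#' Extract individual fibers from a birefringence mask
#'
#' Functional replacement of curvelet-based fiber extraction, with the
#' algorithm fixed and open: (1) the mask is thinned to a one-pixel
#' skeleton; (2) the skeleton is split at branch points (pixels with three
#' or more skeleton neighbours); (3) segments shorter than
#' `min_fiber_length` are discarded; (4) segment pairs whose endpoints lie
#' within `gap_max` px of each other and whose axial orientations differ by
#' less than `merge_angle_max` degrees are merged (nearest pairs first,
#' each endpoint used at most once); (5) each retained fiber is measured:
#' arc length of the traced centreline, width as the mean over the skeleton
#' of twice the Euclidean distance transform of the original mask (minus a
#' one-pixel discretization correction), and axial angle of the
#' total-least-squares line through the centreline, folded into `[0, 180)`.
#'
#' Output is deterministic for a fixed mask, and no two fibers share
#' skeleton pixels.
#'
#' @param mask a [RegionMask-class] from [segmentBirefringent()] (or a
#'   ground-truth mask).
#' @param config an [AnalysisConfig-class] supplying `min_fiber_length`,
#'   `gap_max` and `merge_angle_max`.
#' @param sample,region,condition source labels stored per fiber.
#' @return A [FiberSet-class]; empty when the mask is empty.
#' @export
extractFibers <- function(mask, config = defaultConfig(),
                          sample = "", region = "", condition = "") {
  stopifnot(is(mask, "RegionMask"))
  mm <- maskMatrix(mask)
  pxSize <- cfgParam(config, "pixel_size_um")
  if (!any(mm)) return(FiberSet(pixelSizeUm = pxSize))
  skel <- .thinZhangSuen(mm)
  branch <- skel & .crossingNumber(skel) >= 3
  segs <- .label8(skel & !branch)
  nseg <- max(segs)
  if (nseg == 0) return(FiberSet(pixelSizeUm = pxSize))
  coordsAll <- which(segs > 0, arr.ind = TRUE)
  labs <- segs[segs > 0]
  polylines <- list()
  minLen <- cfgParam(config, "min_fiber_length")
  for (i in seq_len(nseg)) {
    co <- coordsAll[labs == i, , drop = FALSE]
    poly <- .traceSegment(co)
    if (.polylineLength(poly) >= minLen)
      polylines[[length(polylines) + 1]] <- poly
  }
  if (length(polylines) == 0) return(FiberSet(pixelSizeUm = pxSize))
  polylines <- .mergeSegments(polylines,
                              gapMax = cfgParam(config, "gap_max"),
                              angleMax = cfgParam(config, "merge_angle_max"))
  dmap <- as.matrix(EBImage::distmap(
    matrix(as.numeric(mm), nrow(mm), ncol(mm))))
  n <- length(polylines)
  ang <- len <- wid <- numeric(n)
  for (i in seq_len(n)) {
    poly <- polylines[[i]]
    ang[i] <- .tlsAngle(poly)
    len[i] <- .polylineLength(poly)
    wid[i] <- max(2 * mean(dmap[poly]) - 1, 0.5)
  }
  FiberSet(data.frame(id = seq_len(n), angle_deg = ang, length_px = len,
                      width_px = wid, sample = sample, region = region,
                      condition = condition, stringsAsFactors = FALSE),
           polylines = polylines, pixelSizeUm = pxSize)
}

# Merge polylines whose endpoints are close and whose axial orientations
# agree. Greedy nearest-pair-first with union-find cycle prevention; each
# endpoint participates in at most one link.
.mergeSegments <- function(polylines, gapMax, angleMax) {
  n <- length(polylines)
  if (n < 2 || gapMax <= 0) return(polylines)
  angles <- vapply(polylines, .tlsAngle, numeric(1))
  ends <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- polylines[[i]]
    rbind(c(i, 1, p[1, 1], p[1, 2]),
          c(i, 2, p[nrow(p), 1], p[nrow(p), 2]))
  }))
  ne <- nrow(ends)
  cand <- NULL
  for (a in seq_len(ne - 1)) {
    b <- (a + 1):ne
    b <- b[ends[b, 1] != ends[a, 1]]
    if (length(b) == 0) next
    d <- sqrt((ends[b, 3] - ends[a, 3])^2 + (ends[b, 4] - ends[a, 4])^2)
    ok <- d <= gapMax &
      .axialDiff(angles[ends[a, 1]], angles[ends[b, 1]]) < angleMax
    if (any(ok))
      cand <- rbind(cand, cbind(a, b[ok], d[ok]))
  }
  if (is.null(cand)) return(polylines)
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  endUsed <- logical(ne)
  links <- NULL
  for (k in seq_len(nrow(cand))) {
    a <- cand[k, 1]; b <- cand[k, 2]
    if (endUsed[a] || endUsed[b]) next
    fa <- find(ends[a, 1]); fb <- find(ends[b, 1])
    if (fa == fb) next
    parent[fa] <- fb
    endUsed[a] <- endUsed[b] <- TRUE
    links <- rbind(links, c(a, b))
  }
  if (is.null(links)) return(polylines)
  # chain assembly: fibers in a group form a path through the links
  linkOf <- rep(NA_integer_, ne)
  for (k in seq_len(nrow(links))) {
    linkOf[links[k, 1]] <- links[k, 2]
    linkOf[links[k, 2]] <- links[k, 1]
  }
  endId <- function(fib, side) (fib - 1L) * 2L + side
  merged <- list()
  done <- logical(n)
  for (i in seq_len(n)) {
    if (done[i]) next
    # find a chain start: follow links until a free end (or back to i)
    start <- i; startSide <- 1L
    guard <- 0
    repeat {
      eid <- endId(start, startSide)
      if (is.na(linkOf[eid])) break
      nxtEnd <- linkOf[eid]
      start <- as.integer(ends[nxtEnd, 1])
      startSide <- if (ends[nxtEnd, 2] == 1) 2L else 1L
      guard <- guard + 1
      if (guard > 2 * n) break
    }
    # walk from `start`, entering at startSide
    chain <- NULL
    cur <- start; enterSide <- startSide
    repeat {
      done[cur] <- TRUE
      p <- polylines[[cur]]
      if (enterSide == 2) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      chain <- rbind(chain, p)
      exitEid <- endId(cur, if (enterSide == 1) 2L else 1L)
      if (is.na(linkOf[exitEid])) break
      nxtEnd <- linkOf[exitEid]
      cur <- as.integer(ends[nxtEnd, 1])
      if (done[cur]) break
      enterSide <- as.integer(ends[nxtEnd, 2])
    }
    merged[[length(merged) + 1]] <- chain
  }
  merged
}

#' Pool fiber sets across regions or samples
#'
#' Concatenates the fibers of several [FiberSet-class] objects, preserving
#' each fiber's source labels.
#'
#' @param ... [FiberSet-class] objects (or a single list of them).
#' @return A pooled [FiberSet-class].
#' @export
poolFiberSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is(sets[[1]], "FiberSet"))
    sets <- sets[[1]]
  stopifnot(all(vapply(sets, is, logical(1), "FiberSet")))
  fibers <- do.call(rbind, lapply(sets, function(s) s@fibers))
  if (is.null(fibers)) fibers <- .emptyFiberTable()
  fibers$id <- seq_len(nrow(fibers))
  FiberSet(fibers, polylines = do.call(c, lapply(sets, function(s) s@polylines)),
           pixelSizeUm = if (length(sets)) sets[[1]]@pixelSizeUm else 1,
           pooled = TRUE)
}

#' Axial circular statistics of fiber orientations
#'
#' Fibers are undirected, so angles in `[0, 180)` are doubled onto the full
#' circle, vector-averaged, and the mean direction halved back. The
#' resultant length `R` lies in `[0, 1]`: near 0 for isotropic (random)
#' fields, near 1 for aligned ones; circular variance is `1 - R`.
#'
#' @param fibers a [FiberSet-class], or a numeric vector of angles in
#'   degrees.
#' @return A list with `circular_mean_deg`, `circular_resultant_R` and
#'   `circular_variance`.
#' @export
angularStatistics <- function(fibers) {
  angles <- if (is(fibers, "FiberSet")) fibers@fibers$angle_deg else fibers
  if (length(angles) == 0)
    .stopf("angular statistics are undefined for an empty fiber set")
  ax <- .axialStats(angles)
  list(circular_mean_deg = ax$mean_deg, circular_resultant_R = ax$R,
       circular_variance = ax$var)
}

#' Tukey box-plot summary of a distribution
#'
#' Quartiles use linear interpolation between order statistics (R quantile
#' type 7); whiskers extend to the most extreme data points within 1.5
#' interquartile ranges of the quartiles; points beyond the whiskers are
#' reported as outliers. The mean and its standard error (sd/sqrt(n)) are
#' included for mean + s.e.m. reporting.
#'
#' @param values numeric vector, `n >= 1`.
#' @return A list with `n`, `median`, `q1`, `q3`, `whisker_lo`,
#'   `whisker_hi`, `outliers`, `mean`, `sem` and `flag` (`"single_value"`
#'   when `n = 1`, in which case `sem` is reported as 0).
#' @export
summarizeDistribution <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0)
    .stopf("cannot summarize an empty distribution")
  n <- length(values)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  loFence <- q[1] - 1.5 * iqr
  hiFence <- q[3] + 1.5 * iqr
  whiskerLo <- min(values[values >= loFence])
  whiskerHi <- max(values[values <= hiFence])
  outliers <- values[values < whiskerLo | values > whiskerHi]
  flag <- if (n == 1) "single_value" else ""
  list(n = n, median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = whiskerLo, whisker_hi = whiskerHi,
       outliers = outliers, mean = mean(values),
       sem = if (n > 1) stats::sd(values) / sqrt(n) else 0,
       flag = flag)
}

#' Two-sample Kolmogorov-Smirnov comparison of fiber parameter distributions
#'
#' Computes the two-sample KS statistic `D = sup |ECDF_a - ECDF_b|` with the
#' asymptotic p-value, the non-parametric comparison used for pooled fiber
#' angle, length and width distributions.
#'
#' @param a,b numeric vectors, each with at least 5 values.
#' @return A list with `test`, `n_a`, `n_b`, `statistic` (D) and `p_value`.
#' @export
compareDistributions <- function(a, b) {
  if (length(a) < 5 || length(b) < 5)
    .stopf("at least 5 values per sample are required (got %d and %d)",
           length(a), length(b))
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(test = "two-sample Kolmogorov-Smirnov",
       n_a = length(a), n_b = length(b),
       statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}
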