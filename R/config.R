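#' @include AllClasses.R
NULL

#' Published optical-density vectors of the three chromogens
#'
#' Unit RGB optical-density directions for hematoxylin, DAB and Vector Red,
#' the standard values for these chromogens (renormalized to unit length).
#' They define the default unmixing basis for dual-chromogen IHC.
#'
#' @return A [StainVectorSet-class].
#' @examples
#' defaultStainVectors()
#' @export
defaultStainVectors <- function() {
  StainVectorSet(rbind(
    hematoxylin = c(0.650, 0.704, 0.286),
    dab         = c(0.269, 0.568, 0.778),
    vector_red  = c(0.095, 0.708, 0.700)))
}

.defaultHueBins <- function() {
  data.frame(
    bin = c("red", "orange", "yellow", "green", "red"),
    lo  = c(0,     25,       45,       70,      335),
    hi  = c(25,    45,       70,       160,     360),
    stringsAsFactors = FALSE)
}

.MARKERS <- c("Ki67", "bCatenin", "ECadherin", "NCadherin", "FAK",
              "CD44", "CD133", "Caspase3")

.defaultParams <- function() {
  list(
    # PSR birefringence segmentation (HSV thresholds on dark-field signal)
    birefringence_value_min = 0.3,
    birefringence_saturation_min = 0.2,
    min_component_px = 9,
    # fiber tracing
    min_fiber_length = 15,
    gap_max = 10,
    merge_angle_max = 20,
    # trichrome pixel classification
    trichrome_white_value_min = 0.95,
    trichrome_tissue_saturation_min = 0.1,
    trichrome_color_saturation_min = 0.2,
    trichrome_blue_hue_lo = 180, trichrome_blue_hue_hi = 260,
    trichrome_red_hue_lo = 300, trichrome_red_hue_hi = 20,
    # IHC cell geometry and gating
    cell_radius_px = 12,
    nucleus_radius_px = 5,
    ring_thickness_px = 3,
    membrane_sectors = 36,
    membrane_completeness_min = 0.95,
    ck18_threshold = 0.15,
    # morphometry
    spheroid_opening_radius_px = 3,
    spheroid_min_area_px = 100,
    feret_directions = 36,
    lumen_value_min = 0.95,
    lumen_area_min_px = 10,
    lumen_area_max_fraction = 0.25,
    lumen_boundary_stained_min = 0.7,
    # global
    pixel_size_um = 1.0,
    seed = 1)
}

#' Default analysis configuration
#'
#' Builds an [AnalysisConfig-class] with the package defaults: conventional
#' PSR hue bins (red `[0,25) U [335,360)`, orange `[25,45)`, yellow
#' `[45,70)`, green `[70,160)` degrees), the published chromogen OD vectors,
#' a single global OD positivity threshold of 0.15 per marker, and the
#' geometry/morphometry parameters documented in the package vignette.
#' Any element can be overridden by name.
#'
#' @param ... overrides: `hueBins` (data.frame), `stainVectors`
#'   ([StainVectorSet-class]), `odThresholds` (named numeric), or any scalar
#'   parameter by its name (e.g. `min_fiber_length = 20`).
#' @return An [AnalysisConfig-class].
#' @examples
#' cfg <- defaultConfig(min_fiber_length = 20)
#' cfgParam(cfg, "min_fiber_length")
#' @export
defaultConfig <- function(...) {
  over <- list(...)
  hueBins <- over$hueBins %||% .defaultHueBins()
  sv <- over$stainVectors %||% defaultStainVectors()
  od <- stats::setNames(rep(0.15, length(.MARKERS)), .MARKERS)
  if (!is.null(over$odThresholds)) {
    odo <- over$odThresholds
    od[names(odo)] <- odo
  }
  params <- .defaultParams()
  scalars <- setdiff(names(over), c("hueBins", "stainVectors", "odThresholds"))
  unknown <- setdiff(scalars, names(params))
  if (length(unknown) > 0)
    .stopf("unknown configuration parameter(s): %s",
           paste(unknown, collapse = ", "))
  params[scalars] <- over[scalars]
  new("AnalysisConfig", hueBins = hueBins, stainVectors = sv,
      odThresholds = od, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a scalar parameter from an AnalysisConfig
#'
#' @param config an [AnalysisConfig-class].
#' @param name parameter name (see [defaultConfig()]).
#' @return The parameter value.
#' @export
cfgParam <- function(config, name) {
  if (!name %in% names(config@params))
    .stopf("no configuration parameter named '%s'", name)
  config@params[[name]]
}

#' Per-marker OD positivity threshold
#'
#' @param config an [AnalysisConfig-class].
#' @param marker marker name.
#' @return The OD threshold for that marker.
#' @export
odThreshold <- function(config, marker) {
  if (!marker %in% names(config@odThresholds))
    .stopf("no OD threshold configured for marker '%s'", marker)
  unname(config@odThresholds[marker])
}

#' Save and load an analysis configuration as YAML
#'
#' `saveConfig()` writes an [AnalysisConfig-class] to a YAML file;
#' `loadConfig()` reads one back, filling keys missing from the file with
#' the documented defaults and validating the result (overlapping hue bins
#' or negative thresholds raise an error naming the offending entries).
#' Loading a saved default configuration reproduces the defaults.
#'
#' @param config an [AnalysisConfig-class].
#' @param path file path.
#' @return `loadConfig()` returns an [AnalysisConfig-class]; `saveConfig()`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' saveConfig(defaultConfig(), f)
#' cfg <- loadConfig(f)
#' @export
saveConfig <- function(config, path) {
  x <- list(
    hue_bins = lapply(seq_len(nrow(config@hueBins)), function(i)
      list(bin = config@hueBins$bin[i], lo = config@hueBins$lo[i],
           hi = config@hueBins$hi[i])),
    stain_vectors = stats::setNames(
      lapply(1:3, function(i) as.numeric(config@stainVectors@vectors[i, ])),
      config@stainVectors@stains),
    od_thresholds = as.list(config@odThresholds),
    params = config@params)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname saveConfig
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) .stopf("configuration file not found: %s", path)
  x <- yaml::read_yaml(path)
  if (is.null(x)) x <- list()
  hueBins <- if (is.null(x$hue_bins)) .defaultHueBins() else
    do.call(rbind, lapply(x$hue_bins, function(b)
      data.frame(bin = b$bin, lo = b$lo, hi = b$hi,
                 stringsAsFactors = FALSE)))
  sv <- if (is.null(x$stain_vectors)) defaultStainVectors() else
    StainVectorSet(do.call(rbind, x$stain_vectors),
                   stains = names(x$stain_vectors))
  od <- stats::setNames(rep(0.15, length(.MARKERS)), .MARKERS)
  if (!is.null(x$od_thresholds))
    od[names(x$od_thresholds)] <- unlist(x$od_thresholds)
  params <- .defaultParams()
  if (!is.null(x$params)) {
    known <- intersect(names(x$params), names(params))
    params[known] <- x$params[known]
  }
  new("AnalysisConfig", hueBins = hueBins, stainVectors = sv,
      odThresholds = od, params = params)
}
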