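#' @include AllClasses.R
NULL

#' Read a micrograph from TIFF or PNG
#'
#' Decodes an 8- or 16-bit RGB or grayscale image, rescales intensities to
#' `[0, 1]` by the bit-depth maximum, promotes grayscale to three identical
#' channels, drops any alpha channel, and wraps the result in a
#' [RasterImage-class].
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param modality imaging modality recorded in the object, one of `"PSR"`,
#'   `"TRICHROME"`, `"IHC"`, `"HE"`.
#' @param pixelSizeUm micrometres per pixel; image files carry no reliable
#'   magnification metadata, so this defaults to 1 and all micrometre
#'   outputs are `px * pixelSizeUm`.
#' @return A [RasterImage-class].
#' @seealso [writeRasterImage()], [readRegionMask()]
#' @export
readRasterImage <- function(path, modality = c("PSR", "TRICHROME", "IHC", "HE"),
                            pixelSizeUm = 1) {
  modality <- match.arg(modality)
  a <- .decodeImage(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] == 2) a <- array(rep(a[, , 1], 3), c(dim(a)[1:2], 3))
  if (dim(a)[3] >= 4) a <- a[, , 1:3, drop = FALSE]
  new("RasterImage", pixels = a, modality = modality,
      pixelSizeUm = pixelSizeUm, sourcePath = path)
}

.decodeImage <- function(path) {
  if (!file.exists(path)) .stopf("cannot read image: no such file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  a <- tryCatch(switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    .stopf("unsupported image format '.%s' (TIFF or PNG required): %s",
           ext, path)),
    error = function(e) .stopf("failed to decode '%s': %s", path,
                               conditionMessage(e)))
  if (is.list(a)) a <- a[[1]]
  if (min(a) < 0 || max(a) > 1)
    .stopf("unsupported bit depth or sample format in '%s'", path)
  a
}

#' Write a RasterImage to disk
#'
#' Writes 16-bit TIFF or PNG depending on the file extension, so a
#' write/read round trip preserves pixel values within 1/65535.
#'
#' @param image a [RasterImage-class].
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
writeRasterImage <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  px <- pixelArray(image)
  ok <- switch(ext,
    tif = , tiff = tiff::writeTIFF(px, path, bits.per.sample = 16),
    png = png::writePNG(px, path),
    .stopf("unsupported output format '.%s' (TIFF or PNG required)", ext))
  invisible(path)
}

#' Read a single-channel mask image as a RegionMask
#'
#' Any strictly positive pixel is foreground.
#'
#' @param path path to a single-channel TIFF or PNG.
#' @param label region label stored in the mask.
#' @return A [RegionMask-class].
#' @export
readRegionMask <- function(path, label = "") {
  a <- .decodeImage(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  RegionMask(a > 0, label = label)
}

#' Write result rows to CSV
#'
#' Writes a header row and the rows in input order; numeric columns keep
#' full precision (at least 6 significant digits), so regenerating a report
#' from the same inputs yields a byte-identical file.
#'
#' @param records a data.frame of result rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResultsCsv <- function(records, path) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  ok <- tryCatch(
    utils::write.csv(records, path, row.names = FALSE, quote = FALSE),
    error = function(e) .stopf("cannot write results to '%s': %s", path,
                               conditionMessage(e)))
  invisible(path)
}
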