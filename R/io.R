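# Reading and writing slices, labels, contours and parameter presets.

#' Read a grayscale image (PNG or TIFF)
#'
#' Returns an 8-bit-scaled numeric matrix (0..255). Multi-channel images
#' are reduced to their first channel with a warning.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return numeric matrix, gray values in 0..255.
#' @export
readGrayImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    .stopInvalid(sprintf("unsupported image extension '%s'", ext)))
  if (length(dim(img)) == 3L) {
    warning("multi-channel image; using the first channel")
    img <- img[, , 1L]
  }
  img * 255
}

#' Read a binary label image
#'
#' Like \code{\link{readGrayImage}} but warns when pixel values other than
#' 0 and 255 occur; any nonzero value is foreground.
#'
#' @inheritParams readGrayImage
#' @return numeric matrix with values 0 and 255.
#' @export
readLabelImage <- function(path) {
  img <- readGrayImage(path)
  vals <- unique(round(as.vector(img)))
  if (!all(vals %in% c(0, 255)))
    warning("label image has values other than {0, 255}; thresholding at > 0")
  ifelse(img > 0, 255, 0)
}

#' Write a mask or gray image (PNG or TIFF), values 0..255
#'
#' @param image numeric/integer matrix with values in 0..255.
#' @param path output path ending in .png, .tif or .tiff.
#' @export
writeGrayImage <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(image / 255, 0), 1)
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    .stopInvalid(sprintf("unsupported image extension '%s'", ext)))
  invisible(path)
}

#' @rdname writeGrayImage
#' @param mask matrix, any value > 0 is written as 255.
#' @export
writeMask <- function(mask, path) {
  writeGrayImage(ifelse(mask > 0, 255, 0), path)
}

#' Export / import control or dense contours as CSV
#'
#' The exchange format has the header \code{slice,index,x,y}; coordinates
#' are continuous 0-based pixel coordinates.
#'
#' @param polygon a \linkS4class{ControlPolygon} or n x 2 matrix.
#' @param path CSV path.
#' @param slice slice number stored in the first column.
#' @export
writeContourCSV <- function(polygon, path, slice = 1L) {
  pts <- if (is(polygon, "ControlPolygon")) controlPoints(polygon) else as.matrix(polygon)
  utils::write.csv(data.frame(slice = slice, index = seq_len(nrow(pts)),
                              x = pts[, 1L], y = pts[, 2L]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeContourCSV
#' @return for the reader, a \linkS4class{ControlPolygon}.
#' @export
readContourCSV <- function(path) {
  d <- utils::read.csv(path)
  ControlPolygon(cbind(d$x, d$y))
}

#' Shipped parameter presets
#'
#' Named evolution parameter sets recorded for the cytoarchitectural and
#' MRI/CT use cases: \code{cent2gr} and \code{cent2mo} (w=100, h=200, r=60),
#' \code{mobmi} (w=100, h=200, r=10), \code{outline} (w=50, h=25, r=10) and
#' \code{mri_ct} (w=10, h=5, r=3). These record the settings appropriate for
#' dense granular layers, thin cell layers, whole-organ outlines and
#' homogeneous MRI/CT targets respectively; the phantom presets live in
#' \code{\link{modelPresets}}.
#'
#' @param name preset name; NULL lists all presets.
#' @return an \linkS4class{EvolutionParams}, or a named list of them.
#' @export
presetParams <- function(name = NULL) {
  p <- yaml::read_yaml(system.file("extdata", "presets.yaml", package = "ccseg"))
  build <- function(x) EvolutionParams(x$w, x$h, x$r, x$alpha, x$beta)
  if (is.null(name)) return(lapply(p, build))
  if (!name %in% names(p))
    .stopInvalid(sprintf("unknown preset '%s'; available: %s", name,
                         paste(names(p), collapse = ", ")))
  build(p[[name]])
}
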