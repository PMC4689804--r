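#' Raster section image
#'
#' Lightweight container for a digitalized section: a numeric matrix
#' (grayscale) or height x width x 3 array (RGB) on the 8-bit scale 0-255,
#' with the physical pixel size in micrometers. The native slide-scanner
#' resolution is 0.23 um/px at 40X; down-sampling to 20X/10X/5X multiplies
#' the pixel size by 2/4/8.
#'
#' @param pixels numeric matrix (grayscale) or H x W x 3 array (RGB),
#'   intensities in \[0, 255\]
#' @param pixel_size_um physical pixel edge length in micrometers (> 0)
#' @param magnification_label free-text magnification tag, e.g. "10X"
#' @return an object of class `raster_image`
#' @export
raster_image <- function(pixels, pixel_size_um = 0.23,
                         magnification_label = "40X") {
  if (is.matrix(pixels)) {
    h <- nrow(pixels); w <- ncol(pixels)
  } else if (is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3) {
    h <- dim(pixels)[1]; w <- dim(pixels)[2]
  } else {
    stop("pixels must be a matrix or an H x W x 3 array")
  }
  if (h < 2 || w < 2) stop("image must be at least 2 x 2 pixels")
  if (!all(is.finite(pixels))) stop("image contains non-finite pixel values")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("intensities must lie within [0, 255]")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         magnification_label = magnification_label),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  ch <- if (length(d) == 3) d[3] else 1L
  cat(sprintf("<raster_image> %d x %d px, %d channel(s), %.3g um/px (%s)\n",
              d[1], d[2], ch, x$pixel_size_um, x$magnification_label))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

n_channels <- function(img) {
  d <- dim(img$pixels)
  if (length(d) == 3) d[3] else 1L
}

#' Read a section image from disk
#'
#' Reads a TIFF, PNG or JPEG raster into a [raster_image()] on the 8-bit
#' scale. The format is chosen by file extension. Images with an alpha
#' channel are stripped to RGB; single-channel files come back as matrices.
#'
#' @param path path to a .tif/.tiff, .png, .jpg or .jpeg file
#' @param pixel_size_um pixel size to record; defaults to the native 40X
#'   scanning resolution of 0.23 um
#' @param magnification_label magnification tag to record
#' @return a [raster_image()]
#' @export
read_image <- function(path, pixel_size_um = 0.23, magnification_label = "40X") {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(
    switch(ext,
      "png"  = png::readPNG(path),
      "tif"  = ,
      "tiff" = tiff::readTIFF(path),
      "jpg"  = ,
      "jpeg" = jpeg::readJPEG(path),
      stop("unsupported image format '", ext, "'")
    ),
    error = function(e) stop("failed to decode image '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(dim(px)) == 3) {
    if (dim(px)[3] >= 3) px <- px[, , 1:3, drop = FALSE] else px <- px[, , 1]
  }
  if (length(dim(px)) == 3 && dim(px)[3] == 1) px <- px[, , 1]
  if (prod(dim(px)[1:2]) == 0) stop("zero-area image: ", path)
  if (any(dim(px)[1:2] < 16)) stop("section images must be at least 16 x 16 px: ", path)
  raster_image(px * 255, pixel_size_um = pixel_size_um,
               magnification_label = magnification_label)
}

#' Write a raster image to disk
#'
#' Writes an 8-bit PNG or TIFF (by extension). Grayscale matrices and RGB
#' arrays are both supported.
#'
#' @param img a [raster_image()] or plain matrix/array on the 0-255 scale
#' @param path output path ending in .png, .tif or .tiff
#' @return `path`, invisibly
#' @export
write_image <- function(img, path) {
  px <- if (inherits(img, "raster_image")) img$pixels else img
  px01 <- clamp(px, 0, 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "png"  = png::writePNG(px01, target = path),
    "tif"  = ,
    "tiff" = tiff::writeTIFF(px01, where = path, bits.per.sample = 8L),
    stop("unsupported output format '", ext, "'")
  )
  invisible(path)
}

## single-precision float NIfTI for scalar maps (orientation, coherency,
## fa2d, phantom truth); x = column, y = row, matching the tensor export
write_float_map <- function(values, path) {
  img <- RNifti::asNifti(t(values))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

read_float_map <- function(path) {
  t(as.array(RNifti::readNifti(path)))
}
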