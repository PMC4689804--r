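#' Preprocessing configuration
#'
#' Options for the section preprocessing chain. Two dialects of the chain
#' are used in practice and are both supported by [prep_image()]:
#' grayscale conversion + inversion (feeding the HSB orientation render),
#' and red-channel extraction + contrast-limited adaptive histogram
#' equalization + range normalization (feeding the tractography path).
#'
#' @param channel which channel to keep: "red", "green", "blue" or
#'   "luminance" (Rec. 601 weights 0.299/0.587/0.114)
#' @param invert whether to invert intensities (bright fibers on dark
#'   background after inversion of a bright-field stain)
#' @param equalize whether to apply CLAHE before normalization
#' @param clip_limit normalized CLAHE clip limit (> 0); passed to the
#'   equalizer as `limit = clip_limit * bins` with 256 bins
#' @param tile_grid integer pair: CLAHE tile grid (columns, rows)
#' @param out_range length-2 numeric: output intensity range after the final
#'   linear rescale. The nominal "0-256" 8-bit range is represented as
#'   \[0, 255\], the largest value an 8-bit sample can hold.
#' @param downsample_factor integer block-mean down-sampling factor applied
#'   by [prep_image()] before analysis (1 = native resolution)
#' @return a list of class `prep_config`
#' @export
prep_config <- function(channel = c("red", "green", "blue", "luminance"),
                        invert = TRUE, equalize = TRUE,
                        clip_limit = 0.01, tile_grid = c(8L, 8L),
                        out_range = c(0, 255), downsample_factor = 1L) {
  channel <- match.arg(channel)
  stopifnot(clip_limit > 0, length(tile_grid) == 2, all(tile_grid >= 1),
            length(out_range) == 2, out_range[1] < out_range[2],
            downsample_factor >= 1)
  structure(list(channel = channel, invert = invert, equalize = equalize,
                 clip_limit = clip_limit, tile_grid = as.integer(tile_grid),
                 out_range = out_range,
                 downsample_factor = as.integer(downsample_factor)),
            class = "prep_config")
}

#' Extract a single channel as 8-bit grayscale
#'
#' @param img a [raster_image()]
#' @param cfg a [prep_config()]; only `cfg$channel` is consulted
#' @return a single-channel [raster_image()]
#' @export
extract_grayscale <- function(img, cfg = prep_config()) {
  stopifnot(inherits(img, "raster_image"))
  if (n_channels(img) == 1L) {
    warning("input is already single-channel; channel extraction is a no-op")
    return(img)
  }
  px <- img$pixels
  out <- switch(cfg$channel,
    red       = px[, , 1],
    green     = px[, , 2],
    blue      = px[, , 3],
    luminance = 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  )
  raster_image(out, img$pixel_size_um, img$magnification_label)
}

#' Invert an 8-bit grayscale image
#'
#' `out = 255 - in`, element-wise. Involutive.
#' @param img single-channel [raster_image()]
#' @return inverted [raster_image()]
#' @export
invert_image <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  if (n_channels(img) != 1L) stop("invert_image() expects a single-channel image")
  raster_image(255 - img$pixels, img$pixel_size_um, img$magnification_label)
}

#' Down-sample an image by block averaging
#'
#' Non-overlapping `factor` x `factor` block means with edge truncation,
#' emulating the reduction of 40X whole-slide scans to 20X/10X/5X working
#' magnifications (factors 2/4/8). The recorded pixel size is scaled by
#' `factor`.
#'
#' @param img a [raster_image()]
#' @param factor integer >= 1
#' @return down-sampled [raster_image()]
#' @export
downsample_image <- function(img, factor) {
  stopifnot(inherits(img, "raster_image"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("down-sampling factor must be >= 1")
  if (factor == 1L) return(img)
  px <- img$pixels
  out <- if (is.matrix(px)) {
    block_mean(px, factor)
  } else {
    ch <- lapply(1:3, function(k) block_mean(px[, , k], factor))
    array(unlist(ch), dim = c(dim(ch[[1]]), 3))
  }
  raster_image(out, img$pixel_size_um * factor, img$magnification_label)
}

#' Contrast-limited adaptive histogram equalization and range normalization
#'
#' Applies CLAHE (when `cfg$equalize` is TRUE) with the configured clip
#' limit and tile grid, then rescales linearly so the minimum maps to
#' `cfg$out_range[1]` and the maximum to `cfg$out_range[2]`. Constant images
#' pass through unchanged with a warning, since the rescale is undefined.
#'
#' @param img single-channel [raster_image()]
#' @param cfg a [prep_config()]
#' @return equalized and normalized [raster_image()]
#' @export
equalize_normalize <- function(img, cfg = prep_config()) {
  stopifnot(inherits(img, "raster_image"))
  if (n_channels(img) != 1L) stop("equalize_normalize() expects a single-channel image")
  px <- img$pixels
  if (max(px) == min(px)) {
    warning("constant image: equalization/normalization skipped")
    return(img)
  }
  if (isTRUE(cfg$equalize)) {
    bins <- 256L
    ## the tiled equalizer needs at least a 2 x 2 tile grid; smaller grids
    ## mean global histogram equalization
    eq <- if (prod(cfg$tile_grid) >= 4) {
      EBImage::clahe(px / 255, nx = cfg$tile_grid[1], ny = cfg$tile_grid[2],
                     bins = bins, limit = cfg$clip_limit * bins)
    } else {
      EBImage::equalize(EBImage::Image(px / 255), range = c(0, 1),
                        levels = bins)
    }
    px <- as.numeric(eq)
    dim(px) <- dim(img$pixels)
  }
  lo <- cfg$out_range[1]; hi <- cfg$out_range[2]
  px <- (px - min(px)) / (max(px) - min(px)) * (hi - lo) + lo
  raster_image(px, img$pixel_size_um, img$magnification_label)
}

#' Run a full preprocessing dialect
#'
#' Chains the preprocessing steps for one of the two dialects used on
#' stained sections:
#' \describe{
#'   \item{"hsb"}{grayscale conversion (luminance) then inversion - the
#'     chain feeding structure-tensor HSB orientation rendering.}
#'   \item{"tract"}{red-channel extraction, optional inversion, CLAHE and
#'     normalization to `out_range` - the chain feeding tractography.}
#' }
#' For the tract dialect the order of channel extraction and inversion is
#' selectable via `invert_first` (the upstream processing order is not
#' fixed by convention; both orders commute with CLAHE up to contrast sign).
#'
#' @param img a [raster_image()]
#' @param dialect "hsb" or "tract"
#' @param cfg a [prep_config()]
#' @param invert_first if TRUE, inversion precedes equalization (tract
#'   dialect only; inversion always follows grayscale extraction)
#' @return preprocessed single-channel [raster_image()]
#' @export
prep_image <- function(img, dialect = c("tract", "hsb"), cfg = NULL,
                       invert_first = TRUE) {
  dialect <- match.arg(dialect)
  if (is.null(cfg)) {
    cfg <- if (dialect == "hsb") {
      prep_config(channel = "luminance", invert = TRUE, equalize = FALSE)
    } else {
      prep_config(channel = "red", invert = TRUE, equalize = TRUE)
    }
  }
  out <- if (n_channels(img) > 1L) extract_grayscale(img, cfg) else img
  if (cfg$downsample_factor > 1L) out <- downsample_image(out, cfg$downsample_factor)
  if (dialect == "hsb") {
    if (isTRUE(cfg$invert)) out <- invert_image(out)
    return(out)
  }
  if (isTRUE(cfg$invert) && invert_first) out <- invert_image(out)
  out <- equalize_normalize(out, cfg)
  if (isTRUE(cfg$invert) && !invert_first) out <- invert_image(out)
  out
}
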