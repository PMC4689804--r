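#' Pseudo-3D diffusion tensor volume
#'
#' A single-slice tensor field with six unique components per voxel in the
#' order (dxx, dxy, dxz, dyy, dyz, dzz). The z row/column is identically
#' zero: the 2D structure tensor is generalized to three dimensions by
#' replacing the z components with zeros, so standard diffusion-tractography
#' machinery can run on 2D histology.
#'
#' @param d H x W x 6 numeric array of tensor components
#' @param voxel_size physical voxel edge length (same in x and y; the single
#'   z slice is given the in-plane thickness)
#' @param provenance free-form list recording the source image and factors
#' @return an object of class `tensor_volume`
#' @export
tensor_volume <- function(d, voxel_size = 1, provenance = list()) {
  stopifnot(is.array(d), length(dim(d)) == 3, dim(d)[3] == 6)
  if (any(d[, , c(3, 5, 6)] != 0)) {
    stop("z components (dxz, dyz, dzz) of a pseudo tensor must be zero")
  }
  structure(list(d = d, voxel_size = voxel_size, provenance = provenance),
            class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat(sprintf("<tensor_volume> %d x %d x 1 voxels, 6 components, voxel %g\n",
              nrow(x$d), ncol(x$d), x$voxel_size))
  invisible(x)
}

#' @export
dim.tensor_volume <- function(x) dim(x$d)

#' Embed a 2D structure tensor field as a pseudo-3D diffusion tensor
#'
#' With `track_convention = TRUE` (default) the in-plane 2x2 block is the
#' eigen-swapped tensor `T = (lambda1 + lambda2) I - G`: same eigenvectors
#' as the structure tensor `G` but with the eigenvalues exchanged, so the
#' *principal* eigenvector of every exported tensor points along fibers -
#' the direction a deterministic tracker follows. With
#' `track_convention = FALSE` the raw structure tensor is embedded
#' literally (its principal eigenvector points across fibers). The z
#' components are zero either way.
#'
#' @param st an `st_field`
#' @param track_convention logical; see Details
#' @param voxel_size physical voxel size to record
#' @return a [tensor_volume()]
#' @export
embed_pseudo_tensor <- function(st, track_convention = TRUE, voxel_size = 1) {
  stopifnot(inherits(st, "st_field"))
  h <- nrow(st$gxx); w <- ncol(st$gxx)
  if (track_convention) {
    dxx <- st$gyy; dxy <- -st$gxy; dyy <- st$gxx
  } else {
    dxx <- st$gxx; dxy <- st$gxy; dyy <- st$gyy
  }
  z <- matrix(0, h, w)
  tensor_volume(array(c(dxx, dxy, z, dyy, z, z), dim = c(h, w, 6)),
                voxel_size = voxel_size,
                provenance = list(track_convention = track_convention,
                                  sigma_window = st$sigma_window,
                                  gradient_kernel = st$gradient_kernel))
}

## eigen-decompose the in-plane block of a tensor volume; returns an
## eigen_field-compatible structure (used for FA recomputation and tracking
## direction checks). The in-plane block shares eigenvectors with the
## structure tensor; under the tracking convention the PRINCIPAL eigenvector
## runs along fibers.
tv_inplane_eigen <- function(tv) {
  h <- dim(tv$d)[1]; w <- dim(tv$d)[2]
  dxx <- matrix(tv$d[, , 1], h, w)
  dxy <- matrix(tv$d[, , 2], h, w)
  dyy <- matrix(tv$d[, , 4], h, w)
  st <- structure(list(gxx = dxx, gxy = dxy, gyy = dyy,
                       sigma_window = NA_real_, gradient_kernel = "none"),
                  class = "st_field")
  eigen_decompose(st)
}

#' Down-sample a tensor volume (and recompute FA)
#'
#' Tensor components average linearly, so each of the six components is
#' block-mean down-sampled; the fractional anisotropy of the coarse grid is
#' then *recomputed from the averaged tensors* rather than averaged
#' directly, which would be biased wherever orientations mix within a block.
#'
#' @param tv a [tensor_volume()]
#' @param factor integer >= 1 block size (4 reduces a 10X field to the
#'   resolution used for tracking)
#' @param fa_denominator passed to [fa2d()] for the recomputation
#' @return list with elements `tv` (coarse [tensor_volume()]) and `fa`
#'   (coarse `scalar_map`)
#' @export
downsample_tensor <- function(tv, factor, fa_denominator = "quadratic") {
  stopifnot(inherits(tv, "tensor_volume"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("down-sampling factor must be >= 1")
  comp <- lapply(1:6, function(k) block_mean(tv$d[, , k], factor))
  dc <- array(unlist(comp), dim = c(dim(comp[[1]]), 6))
  out <- tensor_volume(dc, voxel_size = tv$voxel_size * factor,
                       provenance = c(tv$provenance,
                                      list(downsample_factor = factor)))
  ef <- tv_inplane_eigen(out)
  list(tv = out, fa = fa2d(ef, denominator = fa_denominator))
}

## ---- masks ---------------------------------------------------------------

new_mask <- function(values, kind) {
  structure(list(values = values, kind = kind), class = "mask_image")
}

#' @export
print.mask_image <- function(x, ...) {
  cat(sprintf("<mask_image> %s: %d / %d pixels\n", x$kind,
              sum(x$values), length(x$values)))
  invisible(x)
}

#' Build a brain (tissue) mask from a preprocessed section image
#'
#' Separates tissue foreground from slide background: Otsu threshold,
#' morphological closing with a disc, hole filling, and retention of the
#' largest connected component. Each step can be toggled; the recipe
#' assumes bright tissue on a dark background (i.e. an inverted stain).
#'
#' @param img single-channel [raster_image()] or matrix on the 0-255 scale
#' @param close_radius disc radius in pixels for morphological closing
#'   (0 disables)
#' @param fill_holes logical; fill enclosed background holes
#' @param largest_only logical; keep only the largest connected component
#' @return a `mask_image` of kind "brain"
#' @export
build_brain_mask <- function(img, close_radius = 5L, fill_holes = TRUE,
                             largest_only = TRUE) {
  m <- if (inherits(img, "raster_image")) img$pixels else img
  stopifnot(is.matrix(m))
  x <- EBImage::Image(clamp(m, 0, 255) / 255)
  thr <- EBImage::otsu(x, range = c(0, 1))
  bw <- x > thr
  if (sum(bw) == 0) stop("no tissue detected")
  if (close_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(close_radius) + 1L, "disc")
    bw <- EBImage::closing(bw, brush)
  }
  if (fill_holes) bw <- EBImage::fillHull(bw)
  if (largest_only) {
    lab <- EBImage::bwlabel(bw)
    tab <- tabulate(as.integer(lab))
    if (length(tab) == 0 || max(tab) == 0) stop("no tissue detected")
    bw <- lab == which.max(tab)
  }
  v <- as.logical(EBImage::imageData(bw) > 0)
  dim(v) <- dim(m)
  if (!any(v)) stop("no tissue detected")
  new_mask(v, "brain")
}

#' Build the tractography seed mask from an FA map
#'
#' Computes the nearest-rank `percentile`-th percentile of FA over the
#' brain mask and keeps pixels at or above it: the default 95 seeds from
#' the top 5 percent most anisotropic tissue, the putative white matter.
#'
#' @param fa a `scalar_map` (kind "fa2d") or numeric matrix
#' @param brain a `mask_image` of matching dimensions
#' @param percentile percentile cut in \[0, 100\] (default 95)
#' @return a `mask_image` of kind "seed"; attribute `threshold` records the
#'   FA cut value
#' @export
build_seed_mask <- function(fa, brain, percentile = 95) {
  fv <- if (inherits(fa, "scalar_map")) fa$values else fa
  stopifnot(inherits(brain, "mask_image"),
            identical(dim(fv), dim(brain$values)),
            percentile >= 0, percentile <= 100)
  inside <- fv[brain$values]
  if (length(inside) == 0) stop("empty brain mask")
  thr <- percentile_nearest_rank(inside, percentile)
  v <- brain$values & (fv >= thr)
  out <- new_mask(v, "seed")
  attr(out, "threshold") <- thr
  out
}

#' Down-sample a mask to the coarse tracking grid
#'
#' Block-mean of the indicator, thresholded at 0.5 (majority vote with
#' ties counted in).
#'
#' @param mask a `mask_image`
#' @param factor integer >= 1
#' @return a coarse `mask_image` of the same kind
#' @export
downsample_mask <- function(mask, factor) {
  stopifnot(inherits(mask, "mask_image"))
  new_mask(block_mean(mask$values * 1, factor) >= 0.5, mask$kind)
}

#' Write a mask as 8-bit PNG (255 inside, 0 outside)
#' @param mask a `mask_image`
#' @param path output .png path
#' @return `path`, invisibly
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "mask_image"))
  png::writePNG(mask$values * 1, target = path)
  invisible(path)
}

## ---- NIfTI export --------------------------------------------------------

#' Write a tensor volume as a 4D NIfTI file
#'
#' Writes a NIfTI-1 volume of dimension \[X, Y, 1, 6\] holding the six
#' unique upper-triangle components (dxx, dxy, dxz, dyy, dyz, dzz) as six
#' scalar images, with the voxel size in pixdim and an identity-scaled
#' affine with origin at the image corner (x = column, y = row). Written in
#' double precision so a read-back round-trips bit-exactly.
#'
#' @param tv a [tensor_volume()]
#' @param path output .nii or .nii.gz path
#' @return `path`, invisibly
#' @export
write_nifti_tensor <- function(tv, path) {
  stopifnot(inherits(tv, "tensor_volume"))
  h <- dim(tv$d)[1]; w <- dim(tv$d)[2]
  ## NIfTI x = column, y = row: transpose each component plane
  arr <- array(0, dim = c(w, h, 1, 6))
  for (k in 1:6) arr[, , 1, k] <- t(tv$d[, , k])
  img <- RNifti::asNifti(arr)
  vs <- tv$voxel_size
  img$pixdim <- c(1, vs, vs, vs, 1, 1, 1, 1)
  RNifti::sform(img) <- structure(diag(c(vs, vs, vs, 1)), code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a tensor volume written by [write_nifti_tensor()]
#'
#' @param path .nii/.nii.gz path with dims \[X, Y, 1, 6\]
#' @return a [tensor_volume()]
#' @export
read_nifti_tensor <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4 || d[3] != 1 || d[4] != 6) {
    stop("expected a [X, Y, 1, 6] tensor NIfTI, got dims ",
         paste(d, collapse = " x "))
  }
  a <- array(0, dim = c(d[2], d[1], 6))
  for (k in 1:6) a[, , k] <- t(img[, , 1, k])
  tensor_volume(a, voxel_size = RNifti::pixdim(img)[1],
                provenance = list(source = path))
}
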