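#' Compute the 2D structure tensor field of a section image
#'
#' For every pixel, the structure tensor is the Gaussian-windowed outer
#' product of the intensity gradient,
#' \deqn{G = w_\sigma \star (\nabla I \, \nabla I^T),}
#' i.e. `gxx = w * (Ix^2)`, `gxy = w * (Ix Iy)`, `gyy = w * (Iy^2)`, with
#' mirror-reflection boundary handling. Gradients are estimated either from
#' the cubic-spline interpolant of the image (default, exact for locally
#' cubic intensity profiles) or by central differences. Components are
#' stored in the display frame (x right, y up), so eigenvectors can be read
#' directly as on-screen directions.
#'
#' @param img a single-channel [raster_image()] or numeric matrix
#' @param sigma_window Gaussian window scale in pixels (default 5, the
#'   standard window for orientation analysis of stained sections)
#' @param gradient_kernel "cubic_spline" or "central_difference"
#' @return an object of class `st_field` with matrices `gxx`, `gxy`, `gyy`
#' @export
compute_structure_tensor <- function(img, sigma_window = 5,
                                     gradient_kernel = c("cubic_spline",
                                                         "central_difference")) {
  gradient_kernel <- match.arg(gradient_kernel)
  m <- if (inherits(img, "raster_image")) img$pixels else img
  if (!is.matrix(m)) stop("expected a single-channel image")
  if (!all(is.finite(m))) stop("image contains non-finite pixels")
  stopifnot(sigma_window > 0)
  g <- image_gradients(m, gradient_kernel)
  ix <- g$gx
  iy <- -g$gy_row # display frame: y points up
  structure(list(
    gxx = gaussian_smooth(ix * ix, sigma_window),
    gxy = gaussian_smooth(ix * iy, sigma_window),
    gyy = gaussian_smooth(iy * iy, sigma_window),
    sigma_window = sigma_window,
    gradient_kernel = gradient_kernel
  ), class = "st_field")
}

#' @export
print.st_field <- function(x, ...) {
  cat(sprintf("<st_field> %d x %d, sigma = %g px, %s gradient\n",
              nrow(x$gxx), ncol(x$gxx), x$sigma_window, x$gradient_kernel))
  invisible(x)
}

## relative tolerance used to call a tensor isotropic
.tie_eps <- 1e-12

#' Eigen-decompose a structure tensor field
#'
#' Closed-form eigen-solution of the symmetric 2x2 tensor at every pixel.
#' `lambda1 >= lambda2`; `e1` is the major eigenvector (the direction of
#' strongest intensity variation, i.e. across fibers) and `e2` the minor
#' eigenvector, which runs along fibers. The reported fiber orientation
#' `theta_fiber` is the display-frame angle of `e2` in degrees, reduced to
#' \[-90, 90). Isotropic pixels (eigenvalue gap below 1e-12 x trace) get the
#' conventional orientation 0 with `e2 = (1, 0)`.
#'
#' @param st an `st_field` from [compute_structure_tensor()]
#' @return an object of class `eigen_field` with matrices `lambda1`,
#'   `lambda2`, `theta_fiber` and H x W x 2 eigenvector arrays `e1`, `e2`
#' @export
eigen_decompose <- function(st) {
  stopifnot(inherits(st, "st_field"))
  gxx <- st$gxx; gxy <- st$gxy; gyy <- st$gyy
  tr <- gxx + gyy
  disc <- sqrt((gxx - gyy)^2 + 4 * gxy^2)
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  iso <- (l1 - l2) <= .tie_eps * pmax(tr, 0)
  phi1 <- 0.5 * atan2(2 * gxy + 0, gxx - gyy) # major eigenvector angle (+ 0 canonicalizes -0)
  theta <- wrap_orientation(phi1 * 180 / pi + 90) # minor eigenvector
  c1 <- cos(phi1); s1 <- sin(phi1)
  ## tie-break at isotropic pixels: fiber orientation 0, e2 along +x
  theta[iso] <- 0
  c1[iso] <- 0; s1[iso] <- 1
  h <- nrow(gxx); w <- ncol(gxx)
  e1 <- array(c(c1, s1), dim = c(h, w, 2))
  e2 <- array(c(-s1, c1), dim = c(h, w, 2))
  structure(list(lambda1 = l1, lambda2 = l2, theta_fiber = theta,
                 e1 = e1, e2 = e2), class = "eigen_field")
}

new_scalar_map <- function(values, kind) {
  structure(list(values = values, kind = kind), class = "scalar_map")
}

#' Coherency (anisotropy) map
#'
#' `C = (lambda1 - lambda2) / (lambda1 + lambda2)` where the trace is
#' positive, 0 elsewhere. 0 for isotropic texture, 1 for perfectly oriented
#' texture.
#'
#' @param ef an `eigen_field`
#' @return a `scalar_map` of kind "coherency" with values in \[0, 1\]
#' @export
coherency <- function(ef) {
  stopifnot(inherits(ef, "eigen_field"))
  tr <- ef$lambda1 + ef$lambda2
  v <- ifelse(tr > 0, (ef$lambda1 - ef$lambda2) / tr, 0)
  new_scalar_map(clamp(v, 0, 1), "coherency")
}

#' Two-dimensional fractional anisotropy
#'
#' \deqn{FA_{2d} = \sqrt{\frac{(\lambda_1-\bar\lambda)^2 +
#'   (\lambda_2-\bar\lambda)^2}{\lambda_1^2 + \lambda_2^2}}, \quad
#'   \bar\lambda = (\lambda_1+\lambda_2)/2,}
#' which ranges from 0 (isotropic) to \eqn{1/\sqrt 2} (rank-1 tensor).
#' `denominator = "sum"` selects the variant normalized by
#' \eqn{(\lambda_1+\lambda_2)} instead of \eqn{\sqrt{\lambda_1^2+\lambda_2^2}};
#' the two are monotone transforms of each other, so thresholded behavior
#' is unchanged up to the cut value.
#'
#' @param ef an `eigen_field`
#' @param denominator "quadratic" (default) or "sum"
#' @return a `scalar_map` of kind "fa2d"
#' @export
fa2d <- function(ef, denominator = c("quadratic", "sum")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(ef, "eigen_field"))
  l1 <- ef$lambda1; l2 <- pmax(ef$lambda2, 0)
  num <- sqrt((l1 - l2)^2 / 2) # sqrt((l1-lbar)^2 + (l2-lbar)^2)
  den <- if (denominator == "quadratic") sqrt(l1^2 + l2^2) else l1 + l2
  v <- ifelse(den > 0, num / den, 0)
  new_scalar_map(v, "fa2d")
}

#' Energy map (tensor trace)
#'
#' @param st an `st_field`
#' @return a `scalar_map` of kind "energy"
#' @export
tensor_energy <- function(st) {
  stopifnot(inherits(st, "st_field"))
  new_scalar_map(st$gxx + st$gyy, "energy")
}

## ---- HSB orientation rendering ------------------------------------------

## hue byte on the orientation wheel: -90 deg -> 0, +90 deg -> 255
orientation_hue_byte <- function(theta_deg) {
  round_half_up((wrap_orientation(theta_deg) + 90) / 180 * 255)
}

## vectorized HSV -> RGB, all channels as bytes
hsb_bytes_to_rgb <- function(hue, sat, bright) {
  h6 <- (hue / 255) * 6
  h6[h6 >= 6] <- 0
  i <- floor(h6)
  f <- h6 - i
  s <- sat / 255
  v <- bright / 255
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = round_half_up(r * 255), g = round_half_up(g * 255),
       b = round_half_up(b * 255))
}

#' Hue-saturation-brightness orientation render
#'
#' Encodes fiber orientation as hue (the \[-90, 90) degree wheel mapped to
#' bytes 0-255), coherency as saturation, and staining intensity as
#' brightness, plus the RGB conversion for PNG export. Zero-coherency pixels
#' come out gray regardless of orientation.
#'
#' @param ef an `eigen_field`
#' @param intensity a `scalar_map` or matrix of staining intensities on the
#'   0-255 scale (typically the preprocessed image)
#' @param coherency_map optional precomputed coherency `scalar_map`
#' @return an object of class `hsb_render` with byte matrices `hue`,
#'   `saturation`, `brightness` and an H x W x 3 `rgb` byte array
#' @export
render_hsb <- function(ef, intensity, coherency_map = NULL) {
  stopifnot(inherits(ef, "eigen_field"))
  iv <- if (inherits(intensity, "scalar_map")) intensity$values
        else if (inherits(intensity, "raster_image")) intensity$pixels
        else intensity
  if (!identical(dim(iv), dim(ef$theta_fiber))) {
    stop("intensity map dimensions do not match the eigen field")
  }
  cm <- if (is.null(coherency_map)) coherency(ef) else coherency_map
  if (!identical(dim(cm$values), dim(ef$theta_fiber))) {
    stop("coherency map dimensions do not match the eigen field")
  }
  hue <- orientation_hue_byte(ef$theta_fiber)
  sat <- round_half_up(clamp(cm$values, 0, 1) * 255)
  bri <- round_half_up(clamp(iv, 0, 255))
  rgb <- hsb_bytes_to_rgb(hue, sat, bri)
  h <- nrow(hue); w <- ncol(hue)
  structure(list(hue = hue, saturation = sat, brightness = bri,
                 rgb = array(c(rgb$r, rgb$g, rgb$b), dim = c(h, w, 3))),
            class = "hsb_render")
}

#' Write a scalar map as a 32-bit float NIfTI image
#'
#' Orientation, coherency and FA maps are real-valued (orientation is in
#' signed degrees), so they are stored as single-precision scalar NIfTI
#' images, the format used for downstream tensor processing.
#' @param map a `scalar_map`
#' @param path output .nii or .nii.gz path
#' @return `path`, invisibly
#' @export
write_scalar_map <- function(map, path) {
  stopifnot(inherits(map, "scalar_map"))
  write_float_map(map$values, path)
}

#' Write an HSB render as 8-bit RGB PNG
#' @param render an `hsb_render`
#' @param path output .png path
#' @return `path`, invisibly
#' @export
write_hsb_png <- function(render, path) {
  stopifnot(inherits(render, "hsb_render"))
  png::writePNG(render$rgb / 255, target = path)
  invisible(path)
}
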