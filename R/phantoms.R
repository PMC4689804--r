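## Synthetic section-like phantoms with orientation ground truth.
##
## All textures are band-limited (sinusoidal stripes) rather than binary so
## gradient estimators stay well-behaved down to the minimum stripe period
## of 4 px. Every phantom is bit-reproducible under its seed and carries
## its own truth (orientation field, label map, tissue mask), so tests can
## compare against construction parameters instead of magic numbers.

phantom_truth <- function(orientation, labels, tissue) {
  structure(list(orientation = orientation, labels = labels, tissue = tissue),
            class = "phantom_truth")
}

new_phantom <- function(pixels, truth, spec) {
  list(image = raster_image(clamp(pixels, 0, 255), pixel_size_um = 0.92,
                            magnification_label = "10X"),
       truth = truth, spec = spec)
}

## evaluate expr with a locally seeded RNG, restoring the caller's stream
with_phantom_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

## display coordinates of every pixel of a size x size canvas
canvas_coords <- function(size) {
  r <- matrix(seq_len(size), size, size)         # row index
  c <- matrix(seq_len(size), size, size, byrow = TRUE)
  list(x = c, y = size + 1 - r)                  # y up
}

## sinusoidal stripe field whose FIBER orientation is theta (display
## degrees): intensity varies along the normal to the fibers
stripe_field <- function(x, y, theta_deg, period) {
  th <- theta_deg * pi / 180
  phase <- -sin(th) * x + cos(th) * y
  sin(2 * pi * phase / period)
}

#' Stripe phantom: parallel fibers at a known orientation
#'
#' Sinusoidal stripes whose wavefronts are normal to the fiber direction,
#' so the true fiber orientation equals `theta_deg` everywhere, plus
#' optional additive Gaussian noise (clipped to 0-255).
#'
#' @param theta_deg fiber orientation in display degrees, \[-90, 90)
#' @param size canvas edge length in pixels
#' @param period stripe period in pixels (>= 4 for clean gradients)
#' @param noise_sd Gaussian noise standard deviation in intensity units
#' @param seed RNG seed (the generator restores the caller's RNG state)
#' @param mean_level,contrast sinusoid mean and amplitude
#' @return list with `image` ([raster_image()]), `truth` (orientation,
#'   labels, tissue mask) and `spec` (the generating parameters)
#' @export
make_stripe_phantom <- function(theta_deg, size = 128, period = 8,
                                noise_sd = 0, seed = 1,
                                mean_level = 140, contrast = 90) {
  stopifnot(period >= 4)
  cc <- canvas_coords(size)
  px <- mean_level + contrast * stripe_field(cc$x, cc$y, theta_deg, period)
  if (noise_sd > 0) {
    px <- with_phantom_seed(seed, px + rnorm(length(px), sd = noise_sd))
  }
  truth <- phantom_truth(matrix(wrap_orientation(theta_deg), size, size),
                         matrix("stripe", size, size),
                         matrix(TRUE, size, size))
  new_phantom(px, truth, list(kind = "stripe", theta_deg = theta_deg,
                              size = size, period = period,
                              noise_sd = noise_sd, seed = seed))
}

#' Arc phantom: a C-shaped tangential fiber bundle
#'
#' An annular band of tangentially oriented stripe texture (fiber
#' direction perpendicular to the radius) wrapped around a dark central
#' "ventricle" disk, emulating thick bundles arching around the lateral
#' ventricle. Truth orientation inside the band is the local tangent
#' angle; elsewhere it is undefined.
#'
#' @param size canvas edge length
#' @param center length-2 display-frame `c(x, y)` center (default canvas
#'   middle)
#' @param r_inner,r_outer annulus radii in pixels (`r_inner < r_outer`,
#'   annulus must fit the canvas)
#' @param period radial stripe period in pixels
#' @param noise_sd,seed,mean_level,contrast as in [make_stripe_phantom()]
#' @param background intensity outside the band (slide background and
#'   ventricle)
#' @return phantom list (image, truth, spec)
#' @export
make_arc_phantom <- function(size = 288, center = NULL,
                             r_inner = 56, r_outer = 112,
                             period = 8, noise_sd = 0, seed = 1,
                             mean_level = 140, contrast = 90,
                             background = 5) {
  if (is.null(center)) center <- c((size + 1) / 2, (size + 1) / 2)
  stopifnot(r_inner < r_outer)
  if (center[1] + r_outer > size || center[1] - r_outer < 1 ||
      center[2] + r_outer > size || center[2] - r_outer < 1) {
    stop("annulus does not fit the canvas")
  }
  cc <- canvas_coords(size)
  dx <- cc$x - center[1]; dy <- cc$y - center[2]
  rad <- sqrt(dx^2 + dy^2)
  in_band <- rad >= r_inner & rad <= r_outer
  px <- matrix(background, size, size)
  px[in_band] <- mean_level + contrast * sin(2 * pi * rad[in_band] / period)
  if (noise_sd > 0) {
    px <- with_phantom_seed(seed, px + rnorm(length(px), sd = noise_sd))
  }
  tangent <- wrap_orientation(atan2(dy, dx) * 180 / pi + 90)
  orient <- matrix(NA_real_, size, size)
  orient[in_band] <- tangent[in_band]
  labels <- matrix("background", size, size)
  labels[in_band] <- "bundle"
  labels[rad < r_inner] <- "ventricle"
  truth <- phantom_truth(orient, labels, in_band)
  new_phantom(px, truth, list(kind = "arc", size = size, center = center,
                              r_inner = r_inner, r_outer = r_outer,
                              period = period, noise_sd = noise_sd,
                              seed = seed))
}

#' Laminar wall phantom: the transient fetal layers
#'
#' Four horizontal laminae stacked from the ventricular surface (bottom)
#' to the pial surface (top), with the characteristic anisotropy
#' signatures of the fetal telencephalic wall:
#' \describe{
#'   \item{VZ}{ventricular zone - dim, directionally unorganized noise.}
#'   \item{IZ}{intermediate zone - bright tangential (horizontal) stripes
#'     with a configurable fraction of radially oriented crossing texture,
#'     mimicking discrete tangential bundles on a radial background.}
#'   \item{SP}{subplate - low-contrast diffuse crossing texture.}
#'   \item{CP}{cortical plate - strong radial (vertical) stripes.}
#' }
#'
#' @param size canvas edge length
#' @param layer_fractions named numeric (VZ, IZ, SP, CP) summing to 1:
#'   fraction of the wall thickness per layer, ventricle first
#' @param iz_crossing_fraction mixing weight of the radial crossing
#'   component inside the IZ, in \[0, 0.5)
#' @param period stripe period
#' @param noise_sd,seed additive noise and seed
#' @return phantom list (image, truth, spec); labels are "VZ", "IZ",
#'   "SP", "CP"
#' @export
make_layered_wall_phantom <- function(size = 192,
                                      layer_fractions = c(VZ = 0.2, IZ = 0.35,
                                                          SP = 0.25, CP = 0.2),
                                      iz_crossing_fraction = 0.25,
                                      period = 8, noise_sd = 5, seed = 1) {
  stopifnot(abs(sum(layer_fractions) - 1) < 1e-9,
            all(c("VZ", "IZ", "SP", "CP") %in% names(layer_fractions)),
            iz_crossing_fraction >= 0, iz_crossing_fraction < 0.5)
  cc <- canvas_coords(size)
  ## bottom rows (small y) = VZ; boundaries as cumulative fractions of y
  bounds <- cumsum(layer_fractions[c("VZ", "IZ", "SP", "CP")]) * size
  layer <- matrix("CP", size, size)
  layer[cc$y <= bounds[3]] <- "SP"
  layer[cc$y <= bounds[2]] <- "IZ"
  layer[cc$y <= bounds[1]] <- "VZ"
  px <- matrix(0, size, size)
  orient <- matrix(NA_real_, size, size)
  f <- iz_crossing_fraction
  tang <- stripe_field(cc$x, cc$y, 0, period)     # horizontal fibers
  radl <- stripe_field(cc$x, cc$y, -90, period * 1.25) # vertical fibers
  vz <- layer == "VZ"; iz <- layer == "IZ"; sp <- layer == "SP"; cp <- layer == "CP"
  px[vz] <- 60
  px[iz] <- 150 + 80 * ((1 - f) * tang[iz] + f * radl[iz])
  px[sp] <- 120 + 15 * (0.5 * tang[sp] + 0.5 * radl[sp])
  px[cp] <- 150 + 80 * radl[cp]
  orient[iz] <- 0
  orient[cp] <- -90
  px <- with_phantom_seed(seed, {
    px[vz] <- px[vz] + rnorm(sum(vz), sd = 15) # unorganized texture
    if (noise_sd > 0) px <- px + rnorm(length(px), sd = noise_sd)
    px
  })
  truth <- phantom_truth(orient, layer, matrix(TRUE, size, size))
  new_phantom(px, truth, list(kind = "layered_wall", size = size,
                              layer_fractions = as.list(layer_fractions),
                              iz_crossing_fraction = iz_crossing_fraction,
                              period = period, noise_sd = noise_sd,
                              seed = seed))
}

## dart-throwing Poisson-disk sampler on a rectangle (display coords)
poisson_disk <- function(n_target, xlim, ylim, min_dist, max_attempts = 30L) {
  pts <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  while (nrow(pts) < n_target && attempts < max_attempts * n_target) {
    attempts <- attempts + 1L
    cand <- c(runif(1, xlim[1], xlim[2]), runif(1, ylim[1], ylim[2]))
    if (nrow(pts) == 0 ||
        min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= min_dist^2) {
      pts <- rbind(pts, cand)
    }
  }
  pts
}

#' Perpendicular-fiber phantom: punctate texture next to in-plane stripes
#'
#' The left portion of the tissue carries horizontal in-plane stripes; the
#' right portion carries a punctate dot field - the in-plane appearance of
#' axon bundles cut across the section plane (as in the center of a Probst
#' bundle). Dots are bright isotropic blobs at Poisson-disk positions, so
#' the region has high intensity but near-zero in-plane coherency. A dark
#' margin surrounds the tissue so foreground masking is unambiguous.
#'
#' @param size canvas edge length
#' @param split fraction of the tissue width given to the stripe region
#' @param dot_density expected dot count per pixel of punctate area,
#'   in (0, 1)
#' @param dot_radius dot radius in pixels
#' @param period stripe period
#' @param noise_sd,seed additive noise and seed
#' @param margin dark border width in pixels
#' @return phantom list; labels are "stripes", "punctate", "background"
#' @export
make_perpendicular_phantom <- function(size = 192, split = 0.5,
                                       dot_density = 0.02, dot_radius = 1.5,
                                       period = 8, noise_sd = 3, seed = 1,
                                       margin = 6) {
  stopifnot(dot_density > 0, dot_density < 1, split > 0, split < 1)
  cc <- canvas_coords(size)
  inner <- cc$x > margin & cc$x <= size - margin &
           cc$y > margin & cc$y <= size - margin
  xsplit <- margin + split * (size - 2 * margin)
  stripes <- inner & cc$x <= xsplit
  dots_rg <- inner & cc$x > xsplit
  px <- matrix(5, size, size)
  px[stripes] <- 140 + 90 * stripe_field(cc$x, cc$y, 0, period)[stripes]
  px[dots_rg] <- 110
  px <- with_phantom_seed(seed, {
    area <- sum(dots_rg)
    n_dots <- max(1L, round(dot_density * area))
    ctr <- poisson_disk(n_dots, c(xsplit, size - margin),
                        c(margin + 1, size - margin),
                        min_dist = 2.5 * dot_radius)
    for (i in seq_len(nrow(ctr))) {
      d2 <- (cc$x - ctr[i, 1])^2 + (cc$y - ctr[i, 2])^2
      hit <- dots_rg & d2 <= dot_radius^2
      px[hit] <- 235
    }
    if (noise_sd > 0) px <- px + rnorm(length(px), sd = noise_sd)
    px
  })
  orient <- matrix(NA_real_, size, size)
  orient[stripes] <- 0
  labels <- matrix("background", size, size)
  labels[stripes] <- "stripes"
  labels[dots_rg] <- "punctate"
  truth <- phantom_truth(orient, labels, inner)
  new_phantom(px, truth, list(kind = "perpendicular", size = size,
                              split = split, dot_density = dot_density,
                              dot_radius = dot_radius, period = period,
                              noise_sd = noise_sd, seed = seed,
                              margin = margin))
}

#' Crossing-fiber phantom: two superimposed stripe populations
#'
#' Superimposes two sinusoidal stripe fields at different orientations
#' (equal periods, so both populations contribute equally strong
#' gradients), mixed by
#' `mix_fraction`: 0 gives pure `theta1`, 0.5 an equal mix, 1 pure
#' `theta2`. Truth records both angles and the dominant one; an equal mix
#' of orthogonal fields averages to a near-isotropic tensor, the crossing
#' ambiguity that single-tensor tracking cannot resolve.
#'
#' @param theta1,theta2 the two fiber orientations (degrees, distinct
#'   mod 180)
#' @param mix_fraction weight of the second population in \[0, 1\]
#' @param size,period,noise_sd,seed,mean_level,contrast texture parameters
#' @return phantom list; `truth$orientation` holds the dominant angle
#'   (NA when the mix is exactly equal)
#' @export
make_crossing_phantom <- function(theta1, theta2, mix_fraction = 0.5,
                                  size = 128, period = 8, noise_sd = 0,
                                  seed = 1, mean_level = 140, contrast = 90) {
  if (orientation_distance(theta1, theta2) < 1e-9) {
    stop("theta1 and theta2 must differ (mod 180)")
  }
  cc <- canvas_coords(size)
  f <- mix_fraction
  px <- mean_level + contrast *
    ((1 - f) * stripe_field(cc$x, cc$y, theta1, period) +
     f * stripe_field(cc$x, cc$y, theta2, period))
  if (noise_sd > 0) {
    px <- with_phantom_seed(seed, px + rnorm(length(px), sd = noise_sd))
  }
  dominant <- if (abs(f - 0.5) < 1e-12) NA_real_
              else wrap_orientation(if (f < 0.5) theta1 else theta2)
  truth <- phantom_truth(matrix(dominant, size, size),
                         matrix("crossing", size, size),
                         matrix(TRUE, size, size))
  new_phantom(px, truth, list(kind = "crossing", theta1 = theta1,
                              theta2 = theta2, mix_fraction = mix_fraction,
                              size = size, period = period,
                              noise_sd = noise_sd, seed = seed))
}

#' Write a phantom to a directory
#'
#' Writes the image as 8-bit PNG, the truth orientation as 32-bit float
#' NIfTI (NA encoded as -999), the label map as an indexed 8-bit PNG, and
#' the generating parameters as JSON.
#'
#' @param phantom a phantom list from one of the `make_*_phantom()`
#'   generators
#' @param dir output directory (created if missing)
#' @param name base filename (defaults to the phantom kind)
#' @return the directory, invisibly
#' @export
write_phantom <- function(phantom, dir, name = phantom$spec$kind) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(phantom$image, file.path(dir, paste0(name, ".png")))
  ori <- phantom$truth$orientation
  ori[is.na(ori)] <- -999
  write_float_map(ori, file.path(dir, paste0(name, "_orientation.nii.gz")))
  labs <- phantom$truth$labels
  lev <- sort(unique(as.vector(labs)))
  idx <- matrix(match(labs, lev) - 1L, nrow(labs))
  png::writePNG(idx / 255, target = file.path(dir, paste0(name, "_labels.png")))
  spec <- c(phantom$spec, list(label_levels = lev))
  jsonlite::write_json(spec, file.path(dir, paste0(name, "_spec.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
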