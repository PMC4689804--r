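## streamline tractography on the pseudo-tensor grid

.term_reasons <- c("mask_exit", "low_fa", "high_curvature", "max_steps",
                   "zero_tensor")

term_reason_label <- function(code) {
  ifelse(is.na(code), NA_character_, .term_reasons[code])
}

#' Tracking configuration
#'
#' Parameters of the deterministic RK4 tracker. The defaults are the
#' standard histology-tractography settings: 10 stochastic repetitions per
#' seed voxel, steps of 2 pixels, a 75 degree curve threshold, and tracking
#' constrained to FA values above 0.1.
#'
#' @param step_px step length in coarse-grid pixels (> 0)
#' @param curve_threshold_deg maximum turning angle in degrees (0, 180);
#'   a turn at or above this angle terminates the streamline
#' @param fa_min FA stopping floor in \[0, 1); tracking stops when the FA of
#'   the interpolated voxel drops to this value or below
#' @param iterations_per_seed stochastic tracking repetitions per seed
#'   (they differ only through the probabilistic interpolation draws)
#' @param max_steps hard cap on RK4 steps per launch
#' @param min_points streamlines with fewer points are discarded
#' @param bidirectional launch antiparallel pairs from each seed and
#'   concatenate (default), or track one way only
#' @return a list of class `tracking_config`
#' @export
tracking_config <- function(step_px = 2, curve_threshold_deg = 75,
                            fa_min = 0.1, iterations_per_seed = 10L,
                            max_steps = 2000L, min_points = 5L,
                            bidirectional = TRUE) {
  stopifnot(step_px > 0,
            curve_threshold_deg > 0, curve_threshold_deg < 180,
            fa_min >= 0, fa_min < 1,
            iterations_per_seed >= 1, max_steps >= 1, min_points >= 1)
  structure(list(step_px = step_px,
                 curve_threshold_deg = curve_threshold_deg,
                 fa_min = fa_min,
                 iterations_per_seed = as.integer(iterations_per_seed),
                 max_steps = as.integer(max_steps),
                 min_points = as.integer(min_points),
                 bidirectional = isTRUE(bidirectional)),
            class = "tracking_config")
}

tv_component_matrices <- function(tv) {
  h <- dim(tv$d)[1]; w <- dim(tv$d)[2]
  list(dxx = matrix(tv$d[, , 1], h, w),
       dxy = matrix(tv$d[, , 2], h, w),
       dyy = matrix(tv$d[, , 4], h, w))
}

## position (x, y) display frame <-> matrix (row, col)
pos_to_rowcol <- function(pos, nr) c(nr + 1 - round(pos[2]), round(pos[1]))
rowcol_to_pos <- function(row, col, nr) cbind(x = col, y = nr + 1 - row)

#' Probabilistic nearest-neighbor tensor interpolation
#'
#' Selects one of the (up to four) grid voxels surrounding a continuous
#' position with probability equal to its bilinear weight and returns that
#' voxel's tensor. Consumes exactly one draw from R's RNG stream per call,
#' so runs are reproducible under [set.seed()].
#'
#' @param tv a [tensor_volume()]
#' @param pos length-2 continuous position `c(x, y)` in display-frame grid
#'   coordinates (voxel centers at integers, y up)
#' @return a list with `ok`; when `ok`, also `row`, `col` and the in-plane
#'   tensor components `dxx`, `dxy`, `dyy`. `ok = FALSE` signals an
#'   out-of-domain position.
#' @export
interpolate_tensor <- function(tv, pos) {
  stopifnot(inherits(tv, "tensor_volume"), length(pos) == 2)
  cm <- tv_component_matrices(tv)
  .interp_select_cpp(cm$dxx, cm$dxy, cm$dyy, pos[1], pos[2])
}

#' In-plane principal eigenvector of a pseudo tensor
#'
#' Returns the unit eigenvector of the larger eigenvalue of the in-plane
#' 2x2 block, sign-aligned to `prev_dir` (positive dot product) when given,
#' otherwise pointed toward +x (ties toward +y). Isotropic or
#' zero/non-positive tensors yield a `zero_tensor` signal.
#'
#' @param tensor length-3 numeric `c(dxx, dxy, dyy)`, a 2x2 matrix, or a
#'   list with components `dxx`, `dxy`, `dyy`
#' @param prev_dir optional unit 2-vector
#' @return list with `status` ("ok" or "zero_tensor") and, when ok, the
#'   unit vector `dir`
#' @export
principal_direction <- function(tensor, prev_dir = NULL) {
  if (is.list(tensor)) tensor <- c(tensor$dxx, tensor$dxy, tensor$dyy)
  if (is.matrix(tensor)) tensor <- c(tensor[1, 1], tensor[1, 2], tensor[2, 2])
  dxx <- tensor[1]; dxy <- tensor[2]; dyy <- tensor[3]
  tr <- dxx + dyy
  disc <- sqrt((dxx - dyy)^2 + 4 * dxy^2)
  if (tr <= 0 || disc <= 1e-12 * tr) return(list(status = "zero_tensor"))
  phi <- 0.5 * atan2(2 * dxy + 0, dxx - dyy) # + 0 canonicalizes -0
  v <- c(cos(phi), sin(phi))
  d <- if (!is.null(prev_dir)) sum(v * prev_dir) else if (v[1] != 0) v[1] else v[2]
  if (d < 0) v <- -v
  list(status = "ok", dir = v)
}

#' One RK4 tracking step
#'
#' Advances a position by one classical fourth-order Runge-Kutta step of
#' length `cfg$step_px` through the direction field defined by the
#' principal eigenvector of the probabilistically interpolated tensor.
#' Every stage direction is sign-aligned to the incoming direction; the
#' averaged step direction is normalized so consecutive points are exactly
#' `step_px` apart. A stage that leaves the grid, meets an isotropic
#' tensor, or turns by at least the curve threshold terminates the step.
#'
#' @param tv a [tensor_volume()]
#' @param pos length-2 position `c(x, y)`
#' @param dir unit 2-vector, the incoming direction
#' @param cfg a [tracking_config()]
#' @return list with `status` ("ok", "mask_exit", "high_curvature",
#'   "zero_tensor") and, when ok, `pos` (next position) and `dir` (the step
#'   direction)
#' @export
rk4_step <- function(tv, pos, dir, cfg = tracking_config()) {
  stopifnot(inherits(tv, "tensor_volume"))
  cm <- tv_component_matrices(tv)
  res <- .rk4_step_cpp(cm$dxx, cm$dxy, cm$dyy, pos[1], pos[2],
                       dir[1], dir[2], cfg$step_px, cfg$curve_threshold_deg)
  status <- if (res$status == 0) "ok" else term_reason_label(res$status)
  out <- list(status = status)
  if (res$status == 0) { out$pos <- res$pos; out$dir <- res$dir }
  out
}

#' Generic RK4 advance through an explicit direction field
#'
#' The integration scheme used by the tracker, exposed over an arbitrary
#' direction function for validation against analytic fields: stages are
#' sign-aligned to the incoming direction and the averaged direction is
#' normalized to give an exact step length.
#'
#' @param pos length-2 position
#' @param dir unit 2-vector, incoming direction
#' @param step step length
#' @param field function(pos) returning a direction vector (need not be
#'   unit length; it is normalized)
#' @return list(pos, dir)
#' @export
rk4_advance <- function(pos, dir, step, field) {
  frac <- c(0, 0.5, 0.5, 1)
  ks <- matrix(0, 4, 2)
  for (s in 1:4) {
    p <- if (s == 1) pos else pos + step * frac[s] * ks[s - 1, ]
    v <- field(p)
    v <- v / sqrt(sum(v^2))
    if (sum(v * dir) < 0) v <- -v
    ks[s, ] <- v
  }
  v <- (ks[1, ] + 2 * ks[2, ] + 2 * ks[3, ] + ks[4, ]) / 6
  v <- v / sqrt(sum(v^2))
  list(pos = pos + step * v, dir = v)
}

#' Track all streamlines from a seed voxel
#'
#' Runs `cfg$iterations_per_seed` stochastic tracking repetitions from the
#' center of one seed voxel. Each repetition launches bidirectionally (two
#' antiparallel launches concatenated) unless `cfg$bidirectional` is FALSE.
#' Termination: brain-mask exit, FA at or below `cfg$fa_min`, turning angle
#' at or above `cfg$curve_threshold_deg`, step count at `cfg$max_steps`, or
#' an isotropic tensor. Streamlines shorter than `cfg$min_points` are
#' discarded.
#'
#' @param tv coarse [tensor_volume()]
#' @param fa coarse FA `scalar_map` (or matrix) on the same grid
#' @param brain coarse brain `mask_image`
#' @param seed_pos length-2 `c(x, y)` voxel-center position (integers)
#' @param cfg a [tracking_config()]
#' @return list of streamlines; each has `points` (n x 2 matrix),
#'   `termination` (character of length 2: start and end reasons),
#'   `iteration`
#' @export
track_seed <- function(tv, fa, brain, seed_pos, cfg = tracking_config()) {
  stopifnot(inherits(tv, "tensor_volume"), inherits(brain, "mask_image"))
  fv <- if (inherits(fa, "scalar_map")) fa$values else fa
  nr <- nrow(tv$d)
  rc <- pos_to_rowcol(seed_pos, nr)
  if (rc[1] < 1 || rc[1] > nr || rc[2] < 1 || rc[2] > ncol(tv$d) ||
      !brain$values[rc[1], rc[2]]) {
    stop("seed position is outside the brain mask")
  }
  cm <- tv_component_matrices(tv)
  raw <- .track_seed_cpp(cm$dxx, cm$dxy, cm$dyy, fv,
                         matrix(as.integer(brain$values), nr),
                         seed_pos[1], seed_pos[2],
                         cfg$iterations_per_seed, cfg$bidirectional,
                         cfg$step_px, cfg$curve_threshold_deg,
                         cfg$fa_min, cfg$max_steps, cfg$min_points)
  lapply(raw, function(s) {
    list(points = s$points,
         termination = c(term_reason_label(s$reason_start),
                         term_reason_label(s$reason_end)),
         iteration = s$iteration)
  })
}

## per-seed RNG substream so parallel schedules cannot change results;
## kept below 2^31 - 1 for R's 32-bit integer seeds
substream_seed <- function(run_seed, seed_index) {
  as.integer((as.double(run_seed) %% 2147483647 * 1009 +
              seed_index * 7919) %% 2147483647)
}

#' Track streamlines from every seed in a seed mask
#'
#' Iterates over seed voxels in column-major order; each seed gets its own
#' RNG substream derived from `(run_seed, seed index)`, so results are
#' independent of execution order. Per-point colors encode the local
#' streamline direction on the same orientation hue wheel as the HSB
#' render.
#'
#' @param tv coarse [tensor_volume()]
#' @param fa coarse FA `scalar_map` or matrix
#' @param brain coarse brain `mask_image`
#' @param seeds a seed `mask_image` (from [build_seed_mask()]) or an n x 2
#'   matrix of `(x, y)` voxel-center positions
#' @param cfg a [tracking_config()]
#' @param run_seed integer master seed for the run
#' @return an object of class `streamline_set`: list of streamlines (each
#'   with `points`, `colors`, `termination`, `seed_index`, `iteration`),
#'   plus the config and seed table
#' @export
track_streamlines <- function(tv, fa, brain, seeds, cfg = tracking_config(),
                              run_seed = 1L) {
  nr <- nrow(tv$d)
  seed_xy <- if (inherits(seeds, "mask_image")) {
    idx <- which(seeds$values, arr.ind = TRUE)
    rowcol_to_pos(idx[, 1], idx[, 2], nr)
  } else {
    stopifnot(is.matrix(seeds), ncol(seeds) == 2)
    seeds
  }
  streamlines <- list()
  if (nrow(seed_xy) > 0) {
    for (i in seq_len(nrow(seed_xy))) {
      set.seed(substream_seed(run_seed, i))
      sl <- track_seed(tv, fa, brain, seed_xy[i, ], cfg)
      for (s in sl) {
        s$seed_index <- i
        s$colors <- streamline_colors(s$points)
        streamlines[[length(streamlines) + 1L]] <- s
      }
    }
  }
  structure(list(streamlines = streamlines, config = cfg,
                 seeds = seed_xy, run_seed = run_seed,
                 grid_dim = dim(tv$d)[1:2]),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d streamlines from %d seeds (seed %d)\n",
              length(x$streamlines), nrow(x$seeds), x$run_seed))
  invisible(x)
}

## per-point RGB bytes from local segment orientation (hue wheel shared
## with render_hsb, full saturation and brightness)
streamline_colors <- function(points) {
  n <- nrow(points)
  if (n < 2) return(matrix(255L, n, 3))
  seg <- diff(points)
  th <- atan2(seg[, 2], seg[, 1]) * 180 / pi
  th <- wrap_orientation(th)
  th <- c(th, th[n - 1]) # last point inherits the last segment
  hue <- orientation_hue_byte(th)
  rgb <- hsb_bytes_to_rgb(hue, rep(255, n), rep(255, n))
  matrix(as.integer(cbind(rgb$r, rgb$g, rgb$b)), ncol = 3)
}

#' Summarize a streamline set
#'
#' @param ss a `streamline_set`
#' @return list with `n_streamlines`, `n_seeds`, `mean_length_px`,
#'   `mean_points`, `termination` (named count vector over both ends) and a
#'   config echo
#' @export
streamline_summary <- function(ss) {
  stopifnot(inherits(ss, "streamline_set"))
  lens <- vapply(ss$streamlines, function(s) {
    sum(sqrt(rowSums(diff(s$points)^2)))
  }, numeric(1))
  npts <- vapply(ss$streamlines, function(s) nrow(s$points), numeric(1))
  term <- unlist(lapply(ss$streamlines, function(s) s$termination))
  term <- term[!is.na(term)]
  counts <- table(factor(term, levels = .term_reasons))
  list(n_streamlines = length(ss$streamlines),
       n_seeds = nrow(ss$seeds),
       mean_length_px = if (length(lens)) mean(lens) else 0,
       mean_points = if (length(npts)) mean(npts) else 0,
       termination = as.list(as.integer(counts)) |>
         stats::setNames(.term_reasons),
       config = unclass(ss$config),
       run_seed = ss$run_seed)
}

#' Streamline point density inside a region
#'
#' Number of streamline points whose nearest voxel falls in the region,
#' divided by the region area in voxels.
#'
#' @param ss a `streamline_set`
#' @param region logical matrix (coarse grid) or `mask_image`
#' @return points per voxel (numeric)
#' @export
streamline_density <- function(ss, region) {
  rv <- if (inherits(region, "mask_image")) region$values else region
  nr <- nrow(rv); nc <- ncol(rv)
  area <- sum(rv)
  if (area == 0) return(NA_real_)
  count <- 0L
  for (s in ss$streamlines) {
    row <- nr + 1 - round(s$points[, 2])
    col <- round(s$points[, 1])
    ok <- row >= 1 & row <= nr & col >= 1 & col <= nc
    count <- count + sum(rv[cbind(row[ok], col[ok])])
  }
  count / area
}

#' Arc subtended by a streamline around a center
#'
#' Total angular extent (degrees) swept by the streamline's points around
#' `center`, from unwrapped polar angles. Used to quantify how far
#' streamlines follow a curved (C-shaped) bundle.
#'
#' @param points n x 2 matrix of `(x, y)` positions
#' @param center length-2 `c(x, y)`
#' @return swept angle in degrees
#' @export
streamline_subtended_angle <- function(points, center) {
  a <- atan2(points[, 2] - center[2], points[, 1] - center[1])
  if (length(a) < 2) return(0)
  d <- diff(a)
  d <- (d + pi) %% (2 * pi) - pi # unwrap
  abs(sum(d)) * 180 / pi # net sweep, so radial jitter does not inflate it
}
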