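## small shared numeric helpers

#' Round half away from zero
#'
#' Byte quantization in the HSB render uses conventional round-half-up,
#' not the banker's rounding of base [round()].
#' @param x numeric
#' @return numeric of the same shape
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Block-mean down-sampling of a matrix
#'
#' Averages non-overlapping `factor` x `factor` blocks; trailing partial
#' blocks at the right/bottom edge are averaged over the pixels present
#' (edge truncation), so output dimensions are `ceiling(dim / factor)`.
#' @param m numeric matrix
#' @param factor integer >= 1
#' @return matrix of dimension `ceiling(dim(m) / factor)`
#' @keywords internal
block_mean <- function(m, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("down-sampling factor must be >= 1")
  if (factor == 1L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  ri <- rep(seq_len(ceiling(nr / factor)), each = factor, length.out = nr)
  ci <- rep(seq_len(ceiling(nc / factor)), each = factor, length.out = nc)
  ## row-collapse then column-collapse; rowsum() groups rows by index
  s <- rowsum(m, ri)
  s <- t(rowsum(t(s), ci))
  cnt <- outer(tabulate(ri), tabulate(ci))
  out <- s / cnt
  dimnames(out) <- NULL
  out
}

## nearest-rank percentile: smallest value v such that at least p% of the
## sample is <= v (threshold used for the FA seed cut)
percentile_nearest_rank <- function(x, p) {
  stopifnot(p >= 0, p <= 100, length(x) > 0)
  v <- sort(x)
  k <- max(1L, as.integer(ceiling(p / 100 * length(v))))
  v[k]
}

#' Reduce angles to the orientation interval
#'
#' Maps angles in degrees onto the half-open fiber-orientation interval
#' \[-90, 90) (orientations are axial: theta and theta + 180 are the same
#' fiber direction).
#' @param theta numeric angles in degrees
#' @return angles in \[-90, 90)
#' @export
wrap_orientation <- function(theta) {
  t <- (theta + 90) %% 180
  t - 90
}

#' Angular distance between two orientations
#'
#' Absolute axial (mod-180) distance in degrees; 0 for parallel fibers,
#' at most 90 for perpendicular ones.
#' @param a,b orientations in degrees
#' @return distances in \[0, 90\]
#' @export
orientation_distance <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}
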