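# Independent brute-force oracles used across the suite.
# These deliberately avoid the package's vectorized/compiled code paths.

# whole-sample mirror reflection of an index onto 1..n
oracle_reflect <- function(j, n) {
  while (j < 1 || j > n) {
    if (j < 1) j <- 2 - j
    if (j > n) j <- 2 * n - j
  }
  j
}

# explicit-loop structure tensor with central-difference gradients and a
# Gaussian window of radius ceiling(3 sigma), display-frame components
oracle_structure_tensor <- function(m, sigma) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- matrix(0, nr, nc); iy <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      gx[r, c] <- (m[r, oracle_reflect(c + 1, nc)] -
                   m[r, oracle_reflect(c - 1, nc)]) / 2
      iy[r, c] <- -(m[oracle_reflect(r + 1, nr), c] -
                    m[oracle_reflect(r - 1, nr), c]) / 2
    }
  }
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  k1 <- exp(-(-rad:rad)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  gxx <- matrix(0, nr, nc); gxy <- matrix(0, nr, nc); gyy <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      sxx <- 0; sxy <- 0; syy <- 0
      for (dr in -rad:rad) {
        for (dc in -rad:rad) {
          rr <- oracle_reflect(r + dr, nr)
          cc <- oracle_reflect(c + dc, nc)
          w <- k2[dr + rad + 1, dc + rad + 1]
          sxx <- sxx + w * gx[rr, cc]^2
          sxy <- sxy + w * gx[rr, cc] * iy[rr, cc]
          syy <- syy + w * iy[rr, cc]^2
        }
      }
      gxx[r, c] <- sxx; gxy[r, c] <- sxy; gyy[r, c] <- syy
    }
  }
  list(gxx = gxx, gxy = gxy, gyy = gyy)
}

# explicit-loop block mean with edge truncation
oracle_block_mean <- function(m, f) {
  nro <- ceiling(nrow(m) / f); nco <- ceiling(ncol(m) / f)
  out <- matrix(0, nro, nco)
  for (i in seq_len(nro)) {
    for (j in seq_len(nco)) {
      rows <- ((i - 1) * f + 1):min(i * f, nrow(m))
      cols <- ((j - 1) * f + 1):min(j * f, ncol(m))
      out[i, j] <- mean(m[rows, cols])
    }
  }
  out
}

# nearest-rank percentile by sorted brute force
oracle_percentile <- function(x, p) {
  v <- sort(x)
  v[max(1, ceiling(p / 100 * length(v)))]
}

# ---- R mirror of the compiled tracking primitives -------------------------
# Consumes R's RNG stream exactly like the C++ code (one uniform draw per
# interpolation call, drawn before the domain check), so under an identical
# seed the two implementations must agree bit for bit.

mirror_interp <- function(dxx, dxy, dyy, x, y) {
  u <- runif(1)
  nr <- nrow(dxx); nc <- ncol(dxx)
  if (x < 1 || x > nc || y < 1 || y > nr) return(NULL)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  wts <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  xs <- c(x0, x0 + 1, x0, x0 + 1); ys <- c(y0, y0, y0 + 1, y0 + 1)
  cum <- 0; chosen <- NA
  for (k in 1:4) {
    if (wts[k] <= 0) next
    if (xs[k] < 1 || xs[k] > nc || ys[k] < 1 || ys[k] > nr) return(NULL)
    cum <- cum + wts[k]
    if (is.na(chosen) && u < cum) chosen <- k
  }
  if (is.na(chosen)) chosen <- max(which(wts > 0))
  row <- nr + 1 - ys[chosen]
  c(dxx[row, xs[chosen]], dxy[row, xs[chosen]], dyy[row, xs[chosen]])
}

mirror_principal <- function(tn, dir) {
  tr <- tn[1] + tn[3]
  disc <- sqrt((tn[1] - tn[3])^2 + 4 * tn[2]^2)
  if (tr <= 0 || disc <= 1e-12 * tr) return(NULL)
  phi <- 0.5 * atan2(2 * tn[2] + 0, tn[1] - tn[3])
  v <- c(cos(phi), sin(phi))
  if (sum(v * dir) < 0) v <- -v
  v
}

mirror_rk4_step <- function(dxx, dxy, dyy, pos, dir, step, curve_deg) {
  costh <- cos(curve_deg * pi / 180)
  frac <- c(0, 0.5, 0.5, 1)
  ks <- matrix(0, 4, 2)
  for (s in 1:4) {
    p <- if (s == 1) pos else pos + step * frac[s] * ks[s - 1, ]
    tn <- mirror_interp(dxx, dxy, dyy, p[1], p[2])
    if (is.null(tn)) return(list(status = "mask_exit"))
    v <- mirror_principal(tn, dir)
    if (is.null(v)) return(list(status = "zero_tensor"))
    if (sum(v * dir) <= costh + 1e-12) return(list(status = "high_curvature"))
    ks[s, ] <- v
  }
  v <- (ks[1, ] + 2 * ks[2, ] + 2 * ks[3, ] + ks[4, ]) / 6
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(list(status = "zero_tensor"))
  v <- v / n
  list(status = "ok", pos = pos + step * v, dir = v)
}

# ---- synthetic tensor-volume builders for tracking tests ------------------

# rank-1 unit-trace tensor with principal direction at theta (display deg)
unit_tensor <- function(theta_deg) {
  t <- theta_deg * pi / 180
  c(dxx = cos(t)^2, dxy = cos(t) * sin(t), dyy = sin(t)^2)
}

# uniform-orientation tensor volume with constant FA and an all-TRUE brain
make_uniform_field <- function(nr, nc, theta_deg, fa_value = 0.7) {
  tn <- unit_tensor(theta_deg)
  z <- matrix(0, nr, nc)
  d <- array(c(matrix(tn[1], nr, nc), matrix(tn[2], nr, nc), z,
               matrix(tn[3], nr, nc), z, z), dim = c(nr, nc, 6))
  list(tv = tensor_volume(d),
       fa = matrix(fa_value, nr, nc),
       brain = histotract:::new_mask(matrix(TRUE, nr, nc), "brain"))
}

# two vertical bands with different orientations, split at column `split_col`
make_two_region_field <- function(nr, nc, theta_left, theta_right, split_col,
                                  fa_value = 0.7) {
  f <- make_uniform_field(nr, nc, theta_left, fa_value)
  tn <- unit_tensor(theta_right)
  cols <- (split_col + 1):nc
  f$tv$d[, cols, 1] <- tn[1]
  f$tv$d[, cols, 2] <- tn[2]
  f$tv$d[, cols, 4] <- tn[3]
  f
}
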