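## Separable image filtering with whole-sample mirror boundary handling.
##
## Filters are applied as dense operator matrices: out = R %*% X %*% t(C),
## which is fast for section tiles up to ~1k pixels a side and makes the
## reflection boundary exact and easy to reason about.

reflect_index <- function(j, n) {
  if (n == 1L) return(rep(1L, length(j)))
  ## whole-sample mirror: ... 3 2 | 1 2 3 ... n | n-1 n-2 ...
  p <- (j - 1L) %% (2L * (n - 1L))
  ifelse(p >= n, 2L * (n - 1L) - p, p) + 1L
}

## correlation operator: out[i] = sum_t k[t] * in[reflect(i + t)], t = -r..r
conv_operator <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  i <- seq_len(n)
  for (t in seq(-r, r)) {
    j <- reflect_index(i + t, n)
    idx <- cbind(i, j)
    M[idx] <- M[idx] + kernel[t + r + 1L]
  }
  M
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

## 2D Gaussian smoothing (separable, mirror boundary)
gaussian_smooth <- function(m, sigma) {
  k <- gaussian_kernel(sigma)
  conv_operator(nrow(m), k) %*% m %*% t(conv_operator(ncol(m), k))
}

## ---- cubic B-spline interpolation coefficients (Unser's recursive filter)

## prefilter along the first dimension, vectorized over columns
bspline_prefilter <- function(X) {
  z <- sqrt(3) - 2
  n <- nrow(X)
  if (n < 3L) return(6 / (1 + 4 + 1) * X * (6 / 6)) # degenerate; unused in practice
  cp <- matrix(0, n, ncol(X))
  horizon <- min(n, as.integer(ceiling(log(1e-12) / log(abs(z)))))
  zk <- z^(0:(horizon - 1L))
  cp[1L, ] <- colSums(X[seq_len(horizon), , drop = FALSE] * zk)
  for (k in 2:n) cp[k, ] <- X[k, ] + z * cp[k - 1L, ]
  cm <- matrix(0, n, ncol(X))
  cm[n, ] <- (z / (z * z - 1)) * (cp[n, ] + z * cp[n - 1L, ])
  for (k in (n - 1L):1L) cm[k, ] <- z * (cm[k + 1L, ] - cp[k, ])
  6 * cm
}

## image gradients on the pixel grid; returns d/dx (columns, rightward)
## and d/dy in ROW direction (downward). The display-frame y-derivative
## is the negative of the row derivative.
image_gradients <- function(m, kernel = c("cubic_spline", "central_difference")) {
  kernel <- match.arg(kernel)
  d <- c(-0.5, 0, 0.5) # central difference as correlation taps at -1, 0, +1
  ## derivatives are offset-invariant; removing the mean keeps the
  ## recursive prefilter's boundary series exact for flat images
  m <- m - mean(m)
  if (kernel == "central_difference") {
    gy <- conv_operator(nrow(m), d) %*% m
    gx <- m %*% t(conv_operator(ncol(m), d))
  } else {
    ## derivative of the cubic-spline interpolant at the nodes: prefilter
    ## along the axis, then central-difference the coefficients (the B-spline
    ## resampling along the orthogonal axis cancels against its prefilter)
    gy <- conv_operator(nrow(m), d) %*% bspline_prefilter(m)
    gx <- t(conv_operator(ncol(m), d) %*% bspline_prefilter(t(m)))
  }
  list(gx = gx, gy_row = gy)
}
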