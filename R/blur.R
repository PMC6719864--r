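# Separable Gaussian blurring with a reflective (half-sample symmetric)
# boundary, in 2-D for ratio-image preprocessing and in 3-D (rows, columns,
# channel axis) for multichannel fusion.  Implemented as dense 1-D blur
# matrices applied per axis; image sides in this package are a few hundred
# pixels, so the matrix products are cheap and exactly reproducible.

# Discrete Gaussian kernel, truncated at 4 sigma and normalized to sum 1.
gaussian_kernel <- function(sigma, truncate = 4) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(1)
  r <- as.integer(ceiling(truncate * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Map out-of-range indices back into 1..n by half-sample reflection:
# (... 2 1 | 1 2 ... n | n n-1 ...).
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  idx <- ((idx - 1L) %% period + period) %% period  # 0-based, in [0, 2n)
  ifelse(idx < n, idx + 1L, period - idx)
}

# n x n matrix B with B %*% v = 1-D Gaussian blur of v (reflective boundary).
blur_matrix <- function(n, sigma, truncate = 4) {
  k <- gaussian_kernel(sigma, truncate)
  if (length(k) == 1L) return(diag(n))
  r <- (length(k) - 1L) / 2L
  B <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    src <- reflect_index(seq_len(n) + o, n)
    w <- k[o + r + 1L]
    for (i in seq_len(n)) B[i, src[i]] <- B[i, src[i]] + w
  }
  B
}

# 2-D Gaussian blur of a matrix (isotropic sigma in pixels).
gaussian_blur_2d <- function(m, sigma, truncate = 4) {
  if (sigma == 0) return(m)
  Br <- blur_matrix(nrow(m), sigma, truncate)
  Bc <- blur_matrix(ncol(m), sigma, truncate)
  Br %*% m %*% t(Bc)
}

# Isotropic 3-D Gaussian blur of an array (rows, cols, channels), reflective
# on all three axes including the channel axis.
gaussian_blur_3d <- function(a, sigma, truncate = 4) {
  stopifnot(length(dim(a)) == 3L)
  if (sigma == 0) return(a)
  d <- dim(a)
  Br <- blur_matrix(d[1], sigma, truncate)
  Bc <- blur_matrix(d[2], sigma, truncate)
  Bz <- blur_matrix(d[3], sigma, truncate)
  for (z in seq_len(d[3])) a[, , z] <- Br %*% a[, , z] %*% t(Bc)
  # channel axis: collapse the spatial dims to rows of an (h*w) x c matrix
  dim(a) <- c(d[1] * d[2], d[3])
  a <- a %*% t(Bz)
  dim(a) <- d
  a
}
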