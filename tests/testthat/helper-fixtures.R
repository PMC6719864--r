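# Shared fixtures.  The standard phantom and its xenon-corrected version are
# memoized so the suite generates them once.

.fixtures <- new.env(parent = emptyenv())

std_phantom <- function() {
  if (is.null(.fixtures$std)) .fixtures$std <- standard_phantom()
  .fixtures$std
}

std_dexenon <- function() {
  if (is.null(.fixtures$dex)) {
    .fixtures$dex <- dexenon_stack(std_phantom()$stack)
  }
  .fixtures$dex
}

# A small stack of hand-set channels (element Te unless stated).
mini_stack <- function(...) {
  chans <- list(...)
  image_stack(chans)
}

te_chan <- function(values, mass, nrow = NULL) {
  m <- if (is.matrix(values)) values else matrix(values, nrow = nrow %||% 1)
  channel_image(m, "Te", mass)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force 1-D/2-D/3-D Gaussian convolution with half-sample reflection,
# used as the independent oracle for the separable blur implementation.
oracle_reflect <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

oracle_blur <- function(a, sigma, truncate = 4) {
  r <- as.integer(ceiling(truncate * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  out <- array(0, d)
  nd <- length(d)
  idx <- as.matrix(expand.grid(lapply(d, seq_len)))
  for (axis in seq_len(nd)) {
    src <- array(a, d)
    out <- array(0, d)
    for (o in -r:r) {
      shifted <- idx
      shifted[, axis] <- vapply(idx[, axis] + o, oracle_reflect, integer(1),
                                n = d[axis])
      out[idx] <- out[idx] + k[o + r + 1L] * src[shifted]
    }
    a <- out
  }
  out
}
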