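# Multi-isotope channel combination.
#
# Natural-abundance tellurium spreads one probe's signal across six usable
# mass channels; fusing them improves signal-to-noise.  Arithmetic summation
# is minimally manipulative but accrues background (IMC noise is
# non-negative, so it cannot cancel); the geometric mean suppresses
# background because a zero in any channel zeroes the output pixel.  An
# optional isotropic 3-D Gaussian blur of the (row, column, channel) array
# before collapsing trades spatial resolution for a further SNR gain.

#' Arithmetic combination (pixelwise sum) of selected channels
#'
#' @param stack An [image_stack()].
#' @param masses Mass numbers of the channels to combine.
#' @return A `channel_image` labelled `Te` at mass 0 (a composite), carrying
#'   the combination settings in its `combination` attribute.
#' @export
arithmetic_combine <- function(stack, masses) {
  mats <- combine_inputs(stack, masses)
  out <- Reduce(`+`, mats)
  combined_channel(stack, masses, out, mode = "arithmetic", blur_sigma = 0)
}

#' Geometric combination (pixelwise geometric mean) of selected channels
#'
#' Computed in the log domain for stability; a pixel that is 0 in any input
#' channel is exactly 0 in the output.
#'
#' @inheritParams arithmetic_combine
#' @return A composite `channel_image` (see [arithmetic_combine()]).
#' @export
geometric_combine <- function(stack, masses) {
  mats <- combine_inputs(stack, masses)
  if (any(vapply(mats, function(m) any(m < 0), logical(1)))) {
    stop("geometric combination requires non-negative inputs (clip upstream)")
  }
  any_zero <- Reduce(`|`, lapply(mats, function(m) m == 0))
  # log(1) = 0 placeholder at zero pixels; those are overwritten below
  sumlog <- Reduce(`+`, lapply(mats, function(m) log(ifelse(m == 0, 1, m))))
  out <- exp(sumlog / length(mats))
  out[any_zero] <- 0
  combined_channel(stack, masses, out, mode = "geometric", blur_sigma = 0)
}

#' 3-D Gaussian blur of selected channels
#'
#' Stacks the selected channels (in the order given) into a
#' rows x columns x channels array and applies an isotropic Gaussian blur with
#' reflective boundaries on all three axes, including the channel axis.  Note
#' that unlike the collapse operations, the result depends on the channel
#' order.
#'
#' @inheritParams arithmetic_combine
#' @param sigma Blur sigma in pixels on all three axes (default 1).
#' @return An [image_stack()] of the blurred channels in the order given.
#' @export
blur_stack_3d <- function(stack, masses, sigma = 1) {
  stopifnot(sigma >= 0)
  mats <- combine_inputs(stack, masses)
  a <- array(unlist(mats), c(dim(mats[[1]]), length(mats)))
  a <- gaussian_blur_3d(a, sigma)
  channels <- lapply(seq_along(masses), function(i) {
    ch <- stack_channel(stack, masses[i])
    ch_replace(ch, a[, , i])
  })
  image_stack(channels, provenance = c(stack$provenance,
                                       list(blur3d_sigma = sigma)))
}

#' Combine channels with optional 3-D blurring
#'
#' Applies [blur_stack_3d()] (if `blur_sigma > 0`) and then collapses with
#' the chosen mode.  `combine(..., blur_sigma = 0)` is identical to calling
#' the collapse directly.
#'
#' @inheritParams arithmetic_combine
#' @param masses Mass numbers to combine; default `c(126, 128, 130)`, the
#'   highest-abundance tellurium isotopes, which can typically be combined
#'   geometrically without skewing the output towards zero.  Which isotopes
#'   to include is ultimately an empirical, per-experiment choice.
#' @param mode `"arithmetic"` or `"geometric"`.
#' @param blur_sigma Sigma of the 3-D pre-blur in pixels (default 0 = none).
#' @return A composite `channel_image`.
#' @export
#' @examples
#' ph <- standard_phantom()
#' st <- dexenon_stack(ph$stack)
#' cmb <- combine(st, c(125, 126, 128, 130), mode = "geometric", blur_sigma = 1)
combine <- function(stack, masses = c(126, 128, 130),
                    mode = c("arithmetic", "geometric"), blur_sigma = 0) {
  mode <- match.arg(mode)
  src <- if (blur_sigma > 0) blur_stack_3d(stack, masses, blur_sigma) else stack
  out <- switch(mode,
                arithmetic = arithmetic_combine(src, masses),
                geometric = geometric_combine(src, masses))
  attr(out, "combination")$blur_sigma <- blur_sigma
  out
}

#' Signal-to-noise ratio of an image
#'
#' `SNR = mean(signal region) / sd(noise region)`, with the population
#' (divide-by-n) standard deviation.  The regions are caller-defined — in
#' practice from knowledge of where tissue sits on the slide, or from phantom
#' ground truth.
#'
#' @param image A [channel_image()] or plain numeric matrix.
#' @param signal_mask,noise_mask Disjoint logical matrices, each with at
#'   least 2 `TRUE` pixels.
#' @return An `snr_result` with `snr`, `signal_mean`, `noise_std` and the
#'   masks.
#' @export
snr <- function(image, signal_mask, noise_mask) {
  m <- if (inherits(image, "channel_image")) ch_pixels(image) else image
  stopifnot(is.matrix(m), is.logical(signal_mask), is.logical(noise_mask))
  if (!identical(dim(m), dim(signal_mask)) ||
      !identical(dim(m), dim(noise_mask))) {
    stop("image and masks must share the same shape")
  }
  if (any(signal_mask & noise_mask)) {
    stop("signal and noise masks must be disjoint")
  }
  if (sum(signal_mask) < 2L || sum(noise_mask) < 2L) {
    stop("each mask needs at least 2 pixels")
  }
  mu_s <- mean(m[signal_mask])
  x <- m[noise_mask]
  sigma_n <- sqrt(mean((x - mean(x))^2))  # population sd (ddof = 0)
  if (sigma_n == 0) stop("degenerate noise region: standard deviation is 0")
  new_snr_result(mu_s / sigma_n, mu_s, sigma_n, signal_mask, noise_mask)
}

# Fetch and validate the selected channels as plain matrices.
combine_inputs <- function(stack, masses) {
  stopifnot(inherits(stack, "image_stack"), length(masses) >= 1L)
  lapply(masses, function(m) ch_pixels(stack_channel(stack, m)))
}

combined_channel <- function(stack, masses, pixels, mode, blur_sigma) {
  ch1 <- stack_channel(stack, masses[1])
  # composite is labelled by its first member so it can travel through the
  # stack I/O; the full recipe lives in the combination attribute
  out <- channel_image(pixels, ch_element(ch1), ch_mass(ch1),
                       ch_pixel_size(ch1))
  attr(out, "combination") <- list(mode = mode, masses = as.integer(masses),
                                   blur_sigma = blur_sigma)
  out
}
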