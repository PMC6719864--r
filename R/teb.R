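# Transmission efficiency bias (TEB).
#
# The mass cytometer detects ions of different mass with different efficiency
# (heavier Te isotopes are over-detected).  In a natural-abundance
# acquisition the pixelwise ratio of two Te channels should equal the ratio
# of their natural abundances; the deviation of the observed median ratio
# from that theoretical ratio is the TEB:
#
#   TEB(a, b) = median(A/B over valid pixels) / (ab(aTe) / ab(bTe))
#
# TEB = 1 means no bias; TEB > 1 means isotope a is over-detected relative to
# b.  Dividing the over-detected channel by TEB is the unique multiplicative
# correction restoring the natural-abundance relation, and is what SLIP
# difference imaging needs before pixels are classified.
#
# Practical details: both input images are lightly Gaussian-blurred (sigma =
# 1 pixel = 1 um at the default raster pitch) before division to suppress
# outlier pixels, and pixels below 1 count (after blurring) in either channel
# are excluded — low counts make the ratio wildly unstable.  Xenon background
# must be removed first (see dexenon_stack), otherwise xenon inflates the
# heavier channel and biases the ratio.

#' Pixelwise ratio image of two channels
#'
#' Blurs both inputs (2-D Gaussian, reflective boundary), masks out pixels
#' where either blurred input is below `threshold`, and divides.
#'
#' @param a_img,b_img Numerator and denominator [channel_image()]s, same
#'   shape.
#' @param threshold Minimum blurred counts per pixel in both channels
#'   (default 1; must be > 0 — it is also the division-by-zero guard).
#' @param sigma Gaussian blur sigma in pixels applied to both inputs before
#'   division (default 1; 0 disables).
#' @return A `ratio_image`: `values` (ratios, defined where `valid`), `valid`
#'   (logical mask), and the threshold/sigma used.
#' @export
ratio_image <- function(a_img, b_img, threshold = 1, sigma = 1) {
  stopifnot(inherits(a_img, "channel_image"), inherits(b_img, "channel_image"))
  if (!identical(dim(a_img), dim(b_img))) {
    stop("a_img and b_img must share the same shape")
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be > 0 (it guards the division)")
  }
  a <- gaussian_blur_2d(ch_pixels(a_img), sigma)
  b <- gaussian_blur_2d(ch_pixels(b_img), sigma)
  valid <- a >= threshold & b >= threshold
  values <- matrix(NA_real_, nrow(a), ncol(a))
  values[valid] <- a[valid] / b[valid]
  new_ratio_image(values, valid, threshold, sigma)
}

#' Quantify the transmission efficiency bias between two Te isotopes
#'
#' Computes the [ratio_image()] of two xenon-corrected natural-abundance
#' tellurium channels and compares its median to the theoretical abundance
#' ratio.
#'
#' @inheritParams ratio_image
#' @param table Abundance table override.
#' @return A `teb_result` with fields `isotope_a`, `isotope_b`,
#'   `median_ratio`, `theoretical_ratio`, `teb` and `n_valid`.
#' @export
#' @examples
#' ph <- standard_phantom()
#' st <- dexenon_stack(ph$stack)
#' compute_teb(stack_channel(st, 126), stack_channel(st, 128))
compute_teb <- function(a_img, b_img, threshold = 1, sigma = 1,
                        table = isotope_abundances()) {
  stopifnot(inherits(a_img, "channel_image"), inherits(b_img, "channel_image"))
  if (ch_element(a_img) != ch_element(b_img)) {
    stop("TEB is defined between isotopes of one element; got ",
         ch_element(a_img), " and ", ch_element(b_img))
  }
  r <- ratio_image(a_img, b_img, threshold, sigma)
  n <- sum(r$valid)
  if (n == 0L) stop("no valid pixels above threshold in the ratio image")
  med <- stats::median(r$values[r$valid])
  theo <- theoretical_ratio(ch_element(a_img), ch_mass(a_img), ch_mass(b_img),
                            table)
  new_teb_result(ch_mass(a_img), ch_mass(b_img), med, theo, n,
                 threshold, sigma)
}

#' Apply a TEB correction to a channel
#'
#' Divides the over-detected channel by the TEB factor.  If a `teb_result` is
#' given, the channel's mass must equal the result's `isotope_a` (the
#' numerator isotope whose over-detection the TEB measures).
#'
#' @param a_img The [channel_image()] to correct.
#' @param teb A positive number, or a `teb_result` from [compute_teb()].
#' @return The corrected `channel_image`; the divisor is recorded in the
#'   `teb_applied` attribute.
#' @export
apply_teb <- function(a_img, teb) {
  stopifnot(inherits(a_img, "channel_image"))
  if (inherits(teb, "teb_result")) {
    if (teb$isotope_a != ch_mass(a_img)) {
      stop(sprintf("TEB was computed for isotope %d over %d; cannot apply to channel %s",
                   teb$isotope_a, teb$isotope_b, ch_label(a_img)))
    }
    teb <- teb$teb
  }
  if (!is.numeric(teb) || length(teb) != 1L || teb <= 0) {
    stop("teb must be a single positive number")
  }
  out <- ch_replace(a_img, ch_pixels(a_img) / teb,
                    allow_negative = any(a_img < 0))
  attr(out, "teb_applied") <- teb
  out
}

#' SLIP difference image
#'
#' For a sequential-labelling (SLIP) experiment with an early-timepoint
#' isotope and a late-timepoint isotope, computes the signed pixelwise
#' difference `D = late/teb - early` and a three-way classification:
#' `+1` where the late signal dominates (rendered red in the conventional
#' display, e.g. increasing hypoxia), `-1` where the early signal dominates
#' (green, attenuating), `0` where they tie.
#'
#' @param early,late Xenon-corrected [channel_image()]s of the two timepoint
#'   isotopes, same shape.
#' @param teb TEB of late relative to early: a positive number or a
#'   `teb_result` whose isotope pair must be (late, early).  The late channel
#'   is divided by it before differencing.  Default 1 (no correction).
#' @return A list of class `slip_difference`: `difference` (signed matrix),
#'   `classification` (matrix of -1/0/+1), `teb_used`.
#' @export
slip_difference <- function(early, late, teb = 1) {
  stopifnot(inherits(early, "channel_image"), inherits(late, "channel_image"))
  if (!identical(dim(early), dim(late))) {
    stop("early and late must share the same shape")
  }
  if (inherits(teb, "teb_result")) {
    if (teb$isotope_a != ch_mass(late) || teb$isotope_b != ch_mass(early)) {
      stop(sprintf("TEB pair %d/%d does not match late/early channels %s/%s",
                   teb$isotope_a, teb$isotope_b, ch_label(late),
                   ch_label(early)))
    }
    teb <- teb$teb
  }
  if (!is.numeric(teb) || length(teb) != 1L || teb <= 0) {
    stop("teb must be a single positive number")
  }
  d <- ch_pixels(late) / teb - ch_pixels(early)
  structure(list(difference = d, classification = sign(d), teb_used = teb),
            class = "slip_difference")
}

#' @export
print.slip_difference <- function(x, ...) {
  cl <- x$classification
  cat(sprintf("<slip_difference> %dx%d px (teb %.4g): +1 (late/red) %d, -1 (early/green) %d, 0 %d\n",
              nrow(cl), ncol(cl), x$teb_used,
              sum(cl > 0), sum(cl < 0), sum(cl == 0)))
  invisible(x)
}

#' Fraction of SLIP pixels whose classification flips under TEB correction
#'
#' Compares the [slip_difference()] classification without correction
#' (`teb = 1`) against the classification with the supplied TEB, over pixels
#' that are classified nonzero in at least one of the two.
#'
#' @inheritParams slip_difference
#' @param teb TEB of late relative to early (number or matching
#'   `teb_result`); must differ from 1 to have any effect.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_sign_changed <- function(early, late, teb) {
  before <- slip_difference(early, late, teb = 1)$classification
  after <- slip_difference(early, late, teb = teb)$classification
  denom <- before != 0 | after != 0
  if (!any(denom)) return(0)
  sum(before[denom] != after[denom]) / sum(denom)
}

#' Render a SLIP difference as an RGB preview
#'
#' Red where the classification is `+1`, green where `-1`, with brightness
#' proportional to `|difference|` (clipped at the 99th percentile).
#'
#' @param sd A `slip_difference`.
#' @return An `height x width x 3` array in `[0, 1]` suitable for
#'   [png::writePNG()].
#' @export
slip_rgb <- function(sd) {
  stopifnot(inherits(sd, "slip_difference"))
  mag <- abs(sd$difference)
  top <- if (any(mag > 0)) {
    stats::quantile(mag[mag > 0], 0.99, names = FALSE)
  } else 1
  mag <- pmin(mag / top, 1)
  rgb <- array(0, c(nrow(mag), ncol(mag), 3L))
  rgb[, , 1][sd$classification > 0] <- mag[sd$classification > 0]
  rgb[, , 2][sd$classification < 0] <- mag[sd$classification < 0]
  rgb
}
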