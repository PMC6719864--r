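# S3 containers: channel_image, image_stack, ratio_image, teb_result,
# snr_result.  A channel_image is a plain numeric matrix carrying the isotope
# identity as attributes, so all of base R's matrix arithmetic keeps working.

#' Single-channel IMC image
#'
#' A 2-D grid of counts for one mass channel.  Rows are raster lines (origin
#' top-left); values are stored as doubles because corrections produce
#' non-integer counts.
#'
#' @param pixels Numeric matrix of counts.  Must be finite; negative values are
#'   rejected unless `allow_negative = TRUE` (used internally for unclipped
#'   background subtraction).
#' @param element Element symbol, e.g. `"Te"`.
#' @param mass Positive integer mass number.
#' @param pixel_size_um Pixel pitch in micrometres (default 1, the Hyperion
#'   raster pitch, so a blur of sigma = 1 um equals sigma = 1 pixel).
#' @param allow_negative Permit negative pixel values.
#' @return A `channel_image` object (a classed numeric matrix).
#' @export
#' @examples
#' channel_image(matrix(0:3, 2, 2), "Te", 128)
channel_image <- function(pixels, element, mass, pixel_size_um = 1,
                          allow_negative = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix")
  }
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels))) stop("pixel values must be finite")
  if (!allow_negative && any(pixels < 0)) {
    stop("pixel values must be >= 0 (use clip or allow_negative)")
  }
  mass <- as.integer(mass)
  if (length(mass) != 1L || is.na(mass) || mass <= 0L) {
    stop("mass must be a single positive integer")
  }
  if (!is.character(element) || length(element) != 1L || !nzchar(element)) {
    stop("element must be a non-empty string")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0) {
    stop("pixel_size_um must be a positive number")
  }
  structure(pixels, element = element, mass = mass,
            pixel_size_um = as.numeric(pixel_size_um),
            class = c("channel_image", class(pixels)))
}

#' @rdname channel_image
#' @param x A `channel_image`.
#' @export
ch_element <- function(x) attr(x, "element")

#' @rdname channel_image
#' @export
ch_mass <- function(x) attr(x, "mass")

#' @rdname channel_image
#' @export
ch_pixel_size <- function(x) attr(x, "pixel_size_um")

#' @rdname channel_image
#' @export
ch_pixels <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

# Short "128Te"-style label.
ch_label <- function(x) paste0(ch_mass(x), ch_element(x))

# Rebuild a channel_image with new pixel values, keeping metadata.
ch_replace <- function(x, pixels, allow_negative = FALSE) {
  channel_image(pixels, ch_element(x), ch_mass(x), ch_pixel_size(x),
                allow_negative = allow_negative)
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s  %dx%d px  (%.3g um/px)  range [%.4g, %.4g]\n",
              ch_label(x), nrow(x), ncol(x), ch_pixel_size(x),
              min(x), max(x)))
  invisible(x)
}

#' Co-registered multichannel IMC image stack
#'
#' An ordered collection of [channel_image()]s of identical shape and pixel
#' size.  `(element, mass)` pairs must be unique within a stack.
#'
#' @param channels List of `channel_image` objects.
#' @param provenance Named list of free-text metadata (processing history,
#'   skipped input columns, correction ratios used, ...).
#' @return An `image_stack` object.
#' @export
image_stack <- function(channels, provenance = list()) {
  if (!is.list(channels) || length(channels) == 0L) {
    stop("channels must be a non-empty list of channel_image objects")
  }
  ok <- vapply(channels, inherits, logical(1), what = "channel_image")
  if (!all(ok)) stop("all channels must be channel_image objects")
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all channels in a stack must share the same shape")
  }
  px <- vapply(channels, ch_pixel_size, numeric(1))
  if (any(px != px[1])) stop("all channels must share pixel_size_um")
  labels <- vapply(channels, ch_label, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate (element, mass) channel in stack: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  names(channels) <- labels
  structure(list(channels = channels, provenance = provenance),
            class = "image_stack")
}

#' @rdname image_stack
#' @param x An `image_stack`.
#' @export
stack_shape <- function(x) dim(x$channels[[1]])

#' @rdname image_stack
#' @export
stack_labels <- function(x) names(x$channels)

#' @rdname image_stack
#' @param mass Mass number to look up.
#' @param element Optional element symbol; if `NULL`, the mass alone must be
#'   unambiguous within the stack.
#' @export
stack_channel <- function(x, mass, element = NULL) {
  masses <- vapply(x$channels, ch_mass, integer(1))
  elements <- vapply(x$channels, ch_element, character(1))
  i <- which(masses == as.integer(mass) &
               (if (is.null(element)) TRUE else elements == element))
  if (length(i) == 0L) {
    stop(sprintf("stack has no channel %s%d",
                 if (is.null(element)) "" else element, as.integer(mass)))
  }
  if (length(i) > 1L) {
    stop(sprintf("mass %d is ambiguous in stack (channels: %s); give element",
                 as.integer(mass), paste(names(x$channels)[i], collapse = ", ")))
  }
  x$channels[[i]]
}

#' @rdname image_stack
#' @export
stack_has_channel <- function(x, mass, element = NULL) {
  masses <- vapply(x$channels, ch_mass, integer(1))
  elements <- vapply(x$channels, ch_element, character(1))
  any(masses == as.integer(mass) &
        (if (is.null(element)) TRUE else elements == element))
}

#' @export
print.image_stack <- function(x, ...) {
  sh <- stack_shape(x)
  cat(sprintf("<image_stack> %d channel(s), %dx%d px: %s\n",
              length(x$channels), sh[1], sh[2],
              paste(stack_labels(x), collapse = " ")))
  if (length(x$provenance)) {
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  }
  invisible(x)
}

# Internal constructor for ratio images (see ratio_image() in teb.R).
new_ratio_image <- function(values, valid, threshold_used, sigma_used) {
  stopifnot(is.matrix(values), is.matrix(valid),
            identical(dim(values), dim(valid)))
  structure(list(values = values, valid = valid,
                 threshold_used = threshold_used, sigma_used = sigma_used),
            class = "ratio_image")
}

#' @export
print.ratio_image <- function(x, ...) {
  n <- sum(x$valid)
  cat(sprintf("<ratio_image> %dx%d px, %d valid (threshold %.3g, sigma %.3g)\n",
              nrow(x$values), ncol(x$values), n, x$threshold_used,
              x$sigma_used))
  if (n > 0) {
    cat(sprintf("  median of valid ratios: %.6g\n",
                stats::median(x$values[x$valid])))
  }
  invisible(x)
}

new_teb_result <- function(isotope_a, isotope_b, median_ratio,
                           theoretical_ratio, n_valid,
                           threshold, sigma) {
  structure(list(isotope_a = as.integer(isotope_a),
                 isotope_b = as.integer(isotope_b),
                 median_ratio = median_ratio,
                 theoretical_ratio = theoretical_ratio,
                 teb = median_ratio / theoretical_ratio,
                 n_valid = as.integer(n_valid),
                 threshold = threshold, sigma = sigma),
            class = "teb_result")
}

#' @export
print.teb_result <- function(x, ...) {
  cat(sprintf("<teb_result> Te pair %d/%d\n", x$isotope_a, x$isotope_b))
  cat(sprintf("  median ratio      %.6g\n", x$median_ratio))
  cat(sprintf("  theoretical ratio %.6g\n", x$theoretical_ratio))
  cat(sprintf("  TEB               %.6g  (1 = unbiased; >1 = %d over-detected)\n",
              x$teb, x$isotope_a))
  cat(sprintf("  valid pixels      %d\n", x$n_valid))
  invisible(x)
}

new_snr_result <- function(snr, signal_mean, noise_std, signal_mask,
                           noise_mask) {
  structure(list(snr = snr, signal_mean = signal_mean, noise_std = noise_std,
                 signal_mask = signal_mask, noise_mask = noise_mask),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("<snr_result> SNR %.4g (signal mean %.4g over %d px / noise sd %.4g over %d px)\n",
              x$snr, x$signal_mean, sum(x$signal_mask), x$noise_std,
              sum(x$noise_mask)))
  invisible(x)
}
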