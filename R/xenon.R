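# Xenon background removal.
#
# Argon carrier gas can be contaminated with xenon, whose isotopes at masses
# 124, 126, 128 and 130 are isobaric with tellurium.  The 134 channel contains
# xenon only (no stable Te-134), so the xenon component of a contaminated
# channel is the 134 image scaled by the natural-abundance ratio of the two
# xenon isotopes, and the tellurium image is recovered by subtraction:
#
#   observed = Te + Xe_component,   Xe_component = X134 * ab(mXe) / ab(134Xe)
#
# Transient xenon spikes during the raster produce whole-row streaks; the
# subtraction removes their expected contribution pixel by pixel.

#' Estimate the xenon component of a tellurium mass channel
#'
#' Scales the pure-xenon 134 channel by the natural-abundance ratio of
#' `target_mass`-Xe to 134-Xe (or by `ratio_override`).
#'
#' @param xenon_ref The 134 Xe [channel_image()].
#' @param target_mass Mass number of the contaminated channel; must have a
#'   stable xenon isobar (124, 126, 128, 129, 130, 131, 132, 136).
#' @param ratio_override Optional positive spillover ratio to use instead of
#'   the theoretical abundance ratio (e.g. from
#'   [empirical_spillover_ratio()]).
#' @param table Abundance table override.
#' @return A `channel_image` labelled `Xe`/`target_mass` holding the estimated
#'   xenon counts.
#' @export
estimate_xenon_component <- function(xenon_ref, target_mass,
                                     ratio_override = NULL,
                                     table = isotope_abundances()) {
  stopifnot(inherits(xenon_ref, "channel_image"))
  target_mass <- as.integer(target_mass)
  if (is.null(ratio_override)) {
    xe_masses <- table$mass[table$element == "Xe"]
    if (!(target_mass %in% xe_masses)) {
      stop(sprintf("no xenon isobar at mass %d; cannot estimate xenon component",
                   target_mass))
    }
    r <- theoretical_ratio("Xe", target_mass, 134, table)
  } else {
    if (!is.numeric(ratio_override) || ratio_override <= 0) {
      stop("ratio_override must be a positive number")
    }
    r <- ratio_override
  }
  channel_image(ch_pixels(xenon_ref) * r, "Xe", target_mass,
                ch_pixel_size(xenon_ref))
}

#' Subtract the xenon background from an observed channel
#'
#' Computes `observed - xenon_component` pixelwise.  With `clip = TRUE`
#' (default) negative results are set to 0, which downstream ratio and
#' geometric operations require; `clip = FALSE` keeps negatives so that the
#' corrected background is unbiased around zero.
#'
#' @param observed The contaminated [channel_image()] (a Te mass channel).
#' @param xenon_ref The 134 Xe channel, same shape.
#' @param clip Clip negative pixels to zero.
#' @inheritParams estimate_xenon_component
#' @return A `channel_image` labelled `Te` at the observed mass.
#' @export
subtract_xenon <- function(observed, xenon_ref, clip = TRUE,
                           ratio_override = NULL,
                           table = isotope_abundances()) {
  stopifnot(inherits(observed, "channel_image"),
            inherits(xenon_ref, "channel_image"))
  if (!identical(dim(observed), dim(xenon_ref))) {
    stop("observed and xenon_ref must share the same shape")
  }
  y <- estimate_xenon_component(xenon_ref, ch_mass(observed),
                                ratio_override, table)
  r <- if (is.null(ratio_override)) {
    theoretical_ratio("Xe", ch_mass(observed), 134, table)
  } else ratio_override
  t_img <- ch_pixels(observed) - ch_pixels(y)
  n_clipped <- sum(t_img < 0)
  if (clip) t_img[t_img < 0] <- 0
  out <- channel_image(t_img, "Te", ch_mass(observed),
                       ch_pixel_size(observed), allow_negative = !clip)
  attr(out, "xenon_ratio_used") <- r
  attr(out, "n_clipped") <- if (clip) n_clipped else 0L
  out
}

#' Empirical xenon spillover ratio from a tissue-free region
#'
#' Instead of the theoretical abundance ratio, the actual per-acquisition
#' spillover can be measured as the median pixelwise ratio of a contaminated
#' channel to the 134 channel over a region known to contain no tissue (and
#' hence no tellurium).  The median is used because xenon streaks make the
#' per-pixel ratios heavy-tailed.
#'
#' @param observed Contaminated [channel_image()].
#' @param xenon_ref The 134 Xe channel, same shape.
#' @param background_mask Logical matrix, `TRUE` on tissue-free pixels.
#' @param threshold Minimum counts required in both channels for a pixel to
#'   enter the median (guards the division); default 1.
#' @return The median ratio (positive scalar).  At least 100 valid pixels are
#'   required.
#' @export
empirical_spillover_ratio <- function(observed, xenon_ref, background_mask,
                                      threshold = 1) {
  stopifnot(inherits(observed, "channel_image"),
            inherits(xenon_ref, "channel_image"),
            is.logical(background_mask))
  if (!identical(dim(observed), dim(background_mask)) ||
      !identical(dim(observed), dim(xenon_ref))) {
    stop("observed, xenon_ref and background_mask must share the same shape")
  }
  valid <- background_mask & ch_pixels(observed) >= threshold &
    ch_pixels(xenon_ref) >= threshold
  n <- sum(valid)
  if (n < 100L) {
    stop(sprintf("only %d valid background pixels (>= 100 required)", n))
  }
  stats::median(ch_pixels(observed)[valid] / ch_pixels(xenon_ref)[valid])
}

#' Remove xenon background from every contaminated channel of a stack
#'
#' Applies [subtract_xenon()] to each Te channel whose mass has a stable
#' xenon isobar (124, 126, 128, 130); channels without one (120, 122, 123,
#' 125) pass through untouched.  The 134 Xe reference channel is retained in
#' the output.
#'
#' @param stack An [image_stack()] containing a 134 Xe channel.
#' @param clip Clip negative corrected pixels to zero.
#' @param empirical Optional logical background mask; if given, the spillover
#'   ratio for each corrected channel is measured with
#'   [empirical_spillover_ratio()] instead of taken from the abundance table.
#' @param ratios Optional named list/vector `mass = ratio` overriding the
#'   spillover ratio for specific masses (takes precedence over `empirical`).
#' @param table Abundance table override.
#' @return A corrected `image_stack`; the per-channel ratios used are recorded
#'   in its provenance.
#' @export
dexenon_stack <- function(stack, clip = TRUE, empirical = NULL, ratios = NULL,
                          table = isotope_abundances()) {
  stopifnot(inherits(stack, "image_stack"))
  if (!stack_has_channel(stack, 134, "Xe")) {
    stop("stack has no 134 Xe reference channel; cannot remove xenon")
  }
  xe <- stack_channel(stack, 134, "Xe")
  used <- list()
  channels <- lapply(stack$channels, function(ch) {
    if (ch_element(ch) != "Te" || !(ch_mass(ch) %in% te_xenon_isobars())) {
      return(ch)
    }
    mass <- ch_mass(ch)
    override <- NULL
    if (!is.null(ratios) && as.character(mass) %in% names(ratios)) {
      override <- as.numeric(ratios[[as.character(mass)]])
    } else if (!is.null(empirical)) {
      override <- empirical_spillover_ratio(ch, xe, empirical)
    }
    corrected <- subtract_xenon(ch, xe, clip = clip,
                                ratio_override = override, table = table)
    used[[as.character(mass)]] <<- attr(corrected, "xenon_ratio_used")
    corrected
  })
  prov <- stack$provenance
  prov$dexenon_ratios <- used
  prov$dexenon_clip <- clip
  image_stack(unname(channels), provenance = prov)
}
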