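# Synthetic IMC phantoms with ground truth.
#
# A phantom emulates the statistical structure of a tellurium IMC
# acquisition: a smooth tissue blob, Poisson counts split across Te isotopes
# by natural abundance (optionally with per-isotope detection bias), a
# xenon baseline in the 134 channel plus its isobaric spillover into the
# 124/126/128/130 channels at table ratios, and whole-row xenon "streaks"
# that mimic transient spikes during the raster.  Every correction in the
# package can thereby be validated against a known answer without
# instrument data.

#' Phantom specification
#'
#' @param height,width Image size in pixels.
#' @param tissue_fraction Fraction of pixels covered by the tissue blob, in
#'   `[0, 1]`.
#' @param mean_tissue_intensity Expected total Te counts per tissue pixel
#'   (split across isotopes by natural abundance).
#' @param isotopes Te mass numbers to generate.
#' @param bias Named vector/list `mass = factor` of multiplicative detection
#'   bias applied to the Te rates (default all 1).
#' @param xenon_baseline Expected 134-Xe counts per pixel.
#' @param streak_rows Number of full raster rows hit by a xenon spike.
#' @param streak_amplitude Multiple of the baseline on streak rows.
#' @param background_rate Expected residual Te counts per pixel everywhere on
#'   the slide (contamination floor, split by natural abundance; default 0).
#' @param seed Integer seed; identical seeds give bit-identical phantoms.
#' @param noise `"poisson"` (counts) or `"none"` (the noiseless expectation
#'   rates themselves, for algebraic exactness checks).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(height = 256, width = 256, tissue_fraction = 0.4,
                         mean_tissue_intensity = 50,
                         isotopes = c(122, 124, 125, 126, 128, 130),
                         bias = NULL, xenon_baseline = 2, streak_rows = 5,
                         streak_amplitude = 20, background_rate = 0,
                         seed = 0, noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  isotopes <- as.integer(isotopes)
  if (length(isotopes) == 0L) stop("isotope list must not be empty")
  te_masses <- isotope_abundances()
  te_masses <- te_masses$mass[te_masses$element == "Te"]
  if (!all(isotopes %in% te_masses)) {
    stop("isotopes must be stable Te mass numbers: ",
         paste(te_masses, collapse = ", "))
  }
  if (tissue_fraction < 0 || tissue_fraction > 1) {
    stop("tissue_fraction must be in [0, 1]")
  }
  if (mean_tissue_intensity < 0 || xenon_baseline < 0 ||
      streak_amplitude < 0 || background_rate < 0) {
    stop("rates must be >= 0")
  }
  b <- stats::setNames(rep(1, length(isotopes)), isotopes)
  if (!is.null(bias)) {
    if (is.null(names(bias)) || !all(names(bias) %in% names(b))) {
      stop("bias must be named by generated isotope mass numbers")
    }
    if (any(unlist(bias) <= 0)) stop("bias factors must be > 0")
    b[names(bias)] <- unlist(bias)
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 tissue_fraction = tissue_fraction,
                 mean_tissue_intensity = mean_tissue_intensity,
                 isotopes = isotopes, bias = b,
                 xenon_baseline = xenon_baseline,
                 streak_rows = as.integer(streak_rows),
                 streak_amplitude = streak_amplitude,
                 background_rate = background_rate,
                 seed = as.integer(seed), noise = noise),
            class = "phantom_spec")
}

#' Generate a phantom acquisition with ground truth
#'
#' Observed channels are built per the acquisition model: each Te-isobar
#' channel is the sum of a tellurium component (Poisson with rate
#' `(tissue_mask * mean_tissue_intensity + background_rate) * abundance *
#' bias`) and, where a stable xenon isobar exists, a xenon component at the
#' natural-abundance ratio to the 134 baseline (streak rows multiplied by
#' `streak_amplitude`).  The 134 Xe channel itself is included.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `stack` (the observed [image_stack()]) and `truth`
#'   (class `phantom_truth`: `tissue_mask`, per-isotope noiseless Te
#'   expectations `true_te`, xenon expectations `true_xe`, `streak_rows`,
#'   `bias`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  h <- spec$height; w <- spec$width
  tab <- isotope_abundances()

  # tissue blob: threshold smoothed noise at the requested area fraction
  tissue <- matrix(FALSE, h, w)
  if (spec$tissue_fraction > 0) {
    field <- gaussian_blur_2d(matrix(stats::rnorm(h * w), h, w),
                              sigma = min(h, w) / 16)
    cut <- stats::quantile(field, 1 - spec$tissue_fraction, names = FALSE)
    tissue <- field > cut
    if (spec$tissue_fraction == 1) tissue[] <- TRUE
  }

  streaks <- if (spec$streak_rows > 0) {
    sort(sample.int(h, spec$streak_rows))
  } else integer(0)
  streak_factor <- rep(1, h)
  streak_factor[streaks] <- spec$streak_amplitude

  draw <- function(rate) {
    if (spec$noise == "none") rate
    else matrix(stats::rpois(h * w, rate), h, w)
  }

  te_rate_total <- tissue * spec$mean_tissue_intensity + spec$background_rate
  xe_rate_134 <- matrix(spec$xenon_baseline * streak_factor, h, w)

  true_te <- list()
  true_xe <- list()
  channels <- vector("list", length(spec$isotopes) + 1L)
  for (i in seq_along(spec$isotopes)) {
    mass <- spec$isotopes[i]
    key <- as.character(mass)
    te_rate <- te_rate_total * abundance("Te", mass, tab) * spec$bias[[key]]
    true_te[[key]] <- te_rate
    obs <- draw(te_rate)
    if (mass %in% te_xenon_isobars()) {
      xe_rate <- xe_rate_134 * theoretical_ratio("Xe", mass, 134, tab)
      true_xe[[key]] <- xe_rate
      obs <- obs + draw(xe_rate)
    }
    channels[[i]] <- channel_image(obs, "Te", mass)
  }
  true_xe[["134"]] <- xe_rate_134
  channels[[length(channels)]] <- channel_image(draw(xe_rate_134), "Xe", 134)

  truth <- structure(list(tissue_mask = tissue, true_te = true_te,
                          true_xe = true_xe, streak_rows = streaks,
                          bias = spec$bias),
                     class = "phantom_truth")
  stack <- image_stack(channels,
                       provenance = list(phantom_seed = spec$seed,
                                         phantom_noise = spec$noise))
  list(stack = stack, truth = truth)
}

#' The standard test phantom
#'
#' The fixed fixture used across the test suite: 256 x 256 pixels, 40%
#' tissue at 50 expected Te counts/pixel over isotopes
#' 122/124/125/126/128/130, no injected bias, xenon baseline 2 with 5 streak
#' rows at 20x, a slide-background residue of 2 counts/pixel (so the noise
#' region carries realistic nonzero counts in every channel), seed 0.
#'
#' @return As [generate_phantom()].
#' @export
standard_phantom <- function() {
  generate_phantom(phantom_spec(background_rate = 2))
}

#' Signal and noise masks from phantom ground truth
#'
#' Builds the "arbitrarily defined" signal and noise regions that
#' signal-to-noise scoring needs from the phantom's tissue mask: the signal
#' region is the tissue eroded by `margin` pixels and the noise region is the
#' background further than `margin` pixels from any tissue.  The margin keeps
#' blurred tissue signal from bleeding into the noise region, mirroring how
#' such regions are drawn on real slides (well inside the tissue and well
#' away from it).
#'
#' @param truth A `phantom_truth` (or any logical tissue mask).
#' @param margin Margin in pixels (default 6, comfortably beyond the support
#'   of a sigma = 1 blur).
#' @return A list with logical matrices `signal` and `noise`.
#' @export
phantom_masks <- function(truth, margin = 6) {
  tissue <- if (inherits(truth, "phantom_truth")) truth$tissue_mask else truth
  stopifnot(is.logical(tissue), is.matrix(tissue))
  list(signal = !dilate_mask(!tissue, margin),
       noise = !dilate_mask(tissue, margin))
}

# Binary dilation with a (2r+1) square structuring element, done as two
# separable 1-D sliding-OR passes.
dilate_mask <- function(m, r) {
  if (r <= 0) return(m)
  shift_or <- function(x, along_rows) {
    out <- x
    n <- if (along_rows) nrow(x) else ncol(x)
    for (o in seq_len(min(r, n - 1L))) {
      if (along_rows) {
        out[seq_len(n - o), ] <- out[seq_len(n - o), ] | x[seq_len(n - o) + o, ]
        out[seq_len(n - o) + o, ] <- out[seq_len(n - o) + o, ] | x[seq_len(n - o), ]
      } else {
        out[, seq_len(n - o)] <- out[, seq_len(n - o)] | x[, seq_len(n - o) + o]
        out[, seq_len(n - o) + o] <- out[, seq_len(n - o) + o] | x[, seq_len(n - o)]
      }
    }
    out
  }
  shift_or(shift_or(m, TRUE), FALSE)
}

#' Inject a post-hoc transmission bias into a stack
#'
#' Multiplies each named channel by its factor, on the observed counts (no
#' re-sampling) — the post-hoc route for simulating detector bias.  To scale
#' the Poisson rates before sampling instead, use the `bias` field of
#' [phantom_spec()].
#'
#' @param stack An [image_stack()].
#' @param bias Named vector/list `mass = factor`, factors > 0.
#' @return The biased `image_stack`.
#' @export
inject_teb <- function(stack, bias) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(names(bias)) || any(unlist(bias) <= 0)) {
    stop("bias must be a named (by mass) collection of positive factors")
  }
  masses <- vapply(stack$channels, ch_mass, integer(1))
  for (key in names(bias)) {
    if (!(as.integer(key) %in% masses)) {
      stop("unknown mass in bias: ", key)
    }
  }
  channels <- lapply(stack$channels, function(ch) {
    key <- as.character(ch_mass(ch))
    if (key %in% names(bias)) {
      ch_replace(ch, ch_pixels(ch) * as.numeric(bias[[key]]))
    } else ch
  })
  prov <- stack$provenance
  prov$injected_bias <- bias
  image_stack(unname(channels), provenance = prov)
}
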