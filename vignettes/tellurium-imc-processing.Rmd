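---
title: "Processing tellurium imaging mass cytometry data with tecyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing tellurium imaging mass cytometry data with tecyto}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tecyto)
```

## The problem

Imaging mass cytometry (IMC) ablates a tissue section pixel by pixel with a
rastering laser and quantifies each elemental isotope in the plume with an
inductively-coupled-plasma time-of-flight mass spectrometer, giving one image
per mass channel. Tellurium-containing small-molecule probes extend IMC beyond
antibody staining — most notably in SLIP experiments (sequential labelling
with isotopologous probes), where the same compound is dosed twice with two
different enriched isotopes so that two mass channels encode two timepoints.

Tellurium brings three data-processing problems that generic IMC software does
not address, and this package implements one correction for each:

1. **Xenon background.** The argon carrier gas carries trace xenon, whose
   stable isotopes at masses 124, 126, 128 and 130 are isobaric with tellurium
   at unit mass resolution. Transient xenon spikes during the raster appear as
   whole-row streaks. `dexenon_stack()` removes the xenon component.
2. **Transmission efficiency bias (TEB).** The instrument detects heavier
   ions more efficiently than lighter ones, so two channels of the *same*
   probe are scaled differently. This cancels in single-channel images but
   directly distorts SLIP difference images. `compute_teb()` quantifies the
   bias from a natural-abundance acquisition and `apply_teb()` corrects it.
3. **Signal-to-noise of natural-abundance imaging.** A natural-abundance
   tellurium probe spreads its signal over six usable isotopes;
   `combine()` fuses them (arithmetically or geometrically, with an optional
   3-D blur) into one image with better SNR.

All three are validated against a synthetic phantom with known ground truth
(`generate_phantom()`), so nothing in the test suite depends on instrument
data.

## Xenon removal

The 134 channel contains xenon but no tellurium (there is no stable Te-134),
so it measures the xenon level in every pixel. For a contaminated mass
channel $m$ the observed image decomposes as

$$ I_m = T_m + Y_m, \qquad
   Y_m = X_{134}\,\frac{\mathrm{ab}(^{m}\mathrm{Xe})}{\mathrm{ab}(^{134}\mathrm{Xe})}, $$

and the tellurium image is recovered by subtraction, $T_m = I_m - Y_m$. The
abundance ratios come from a bundled CIAAW/NIST-style isotopic-composition
table (`isotope_abundances()`; the 128/134 ratio is 0.183). Because each
xenon spike raises the 134 channel and the contaminated channel
proportionally, the subtraction removes streaks in expectation, not just a
constant baseline.

Choices worth knowing about:

* **Clipping.** Subtraction of two noisy non-negative images produces
  negative pixels where the true tellurium signal is ~0. The default clips
  them to zero, because downstream ratio images and geometric combination
  need non-negative counts. `clip = FALSE` keeps negatives so the corrected
  background is unbiased around zero — use it for any statistic that averages
  background pixels.
* **Reference channel.** 134 is the fixed reference; 136-Xe would also work
  but offering both would complicate provenance for no practical gain.
* **Empirical spillover.** If an acquisition contains a region guaranteed
  tissue-free, `empirical_spillover_ratio()` measures the actual
  contaminated/134 ratio there as a median over pixels with at least 1 count
  in both channels (the median resists streak-driven heavy tails). At least
  100 valid pixels are required for a stable estimate. Mass 125 has no
  stable xenon isobar and is deliberately never corrected.

## Transmission efficiency bias

In a natural-abundance acquisition, two tellurium channels $A$ (isotope $a$)
and $B$ (isotope $b$) should satisfy
$A_{ij}/B_{ij} = \mathrm{ab}(^{a}\mathrm{Te})/\mathrm{ab}(^{b}\mathrm{Te})$.
The TEB is the deviation from that relation:

$$ \mathrm{TEB}(a, b) =
   \frac{\operatorname{median}(R)}{\mathrm{ab}(^{a}\mathrm{Te}) /
   \mathrm{ab}(^{b}\mathrm{Te})}, \qquad R_{ij} = A_{ij}/B_{ij}, $$

so TEB = 1 means no bias and TEB > 1 means isotope $a$ is over-detected
relative to $b$. A ratio-based estimate (rather than a regression of one
channel on the other) avoids designating either isotope as the dependent
variable. Dividing channel $A$ by the TEB is the unique multiplicative
correction that restores the natural-abundance relation, which is why
`apply_teb()` divides.

Tunable parameters, with defaults and rationale:

* `threshold = 1` count/pixel: ratios of near-zero counts are wildly
  unstable; pixels below the threshold in either (blurred) channel are
  excluded from the median. The threshold doubles as the division-by-zero
  guard, so it must be positive.
* `sigma = 1` pixel: a light Gaussian blur of both inputs before division
  suppresses isolated outlier pixels. At the default 1 µm raster pitch
  (`pixel_size_um = 1`), σ = 1 pixel equals σ = 1 µm. We blur the *inputs*
  rather than the ratio image: blurring $R$ itself would average ratios,
  which is a statistically different (and harder to reason about) estimator.
  The blur uses a reflective boundary so edge pixels are not darkened.
* Xenon removal must precede TEB calculation — xenon adds mass-dependent
  background that shifts the ratio (the test suite demonstrates the TEB error
  is strictly larger without it).

TEB is a property of the instrument on the day, not of the sample: it should
be re-measured near each experiment and per isotope pair. The package
deliberately models it as a scalar per pair per acquisition (no per-pixel
fields, no drift model).

For SLIP experiments, `slip_difference()` computes
$D = \mathrm{late}/\mathrm{TEB} - \mathrm{early}$ and classifies each pixel
as +1 (late dominates; conventionally rendered red, e.g. increasing hypoxia),
−1 (early dominates; green) or 0. `fraction_sign_changed()` reports what
fraction of classified pixels flip between the uncorrected and corrected
classifications — the headline measure of how much TEB correction matters for
interpretation.

## Channel combination and SNR

For natural-abundance experiments, `combine()` fuses several tellurium
channels:

* **arithmetic** — the pixelwise sum. Minimally manipulative, but IMC noise
  is non-negative, so background accrues linearly with channel count instead
  of cancelling.
* **geometric** — the pixelwise $n$-th root of the product, computed in the
  log domain for stability with an exact-zero short-circuit: a zero in any
  channel zeroes the output pixel. This is what suppresses background, since
  true background pixels are very likely to be zero in at least one channel.
  Including a very low-abundance isotope skews the output towards zero, so
  the default set is {126, 128, 130} (the three most abundant isotopes);
  which isotopes to include is ultimately an empirical, per-experiment call.
* An optional isotropic **3-D Gaussian blur** (`blur_sigma`) of the
  (rows × columns × channels) array before collapsing. Blurring across the
  channel axis shares information between isotopes of the same probe before
  the collapse, at the cost of spatial resolution; each experiment has its
  own acceptable trade-off. The channel axis uses the same reflective
  boundary as the spatial axes — with only 3–4 channels the boundary rule
  materially affects the end channels, so it is a recorded choice, and the
  channel order (ascending mass by default, adjacent masses being most
  correlated) genuinely matters to the result.

Quality is scored with `snr()`: the mean over a signal region divided by the
standard deviation over a noise region. The population (divide-by-$n$)
standard deviation is used — with thousands of mask pixels the distinction
from the sample estimator is cosmetic, but it is fixed and recorded. The
regions are the user's responsibility (typically drawn from knowledge of
where tissue sits on the slide); `phantom_masks()` builds them from phantom
ground truth, eroding the tissue mask by a 6-pixel margin on both sides so
that blurred tissue signal cannot bleed into the noise region and dominate
its standard deviation.

## The synthetic phantom

`generate_phantom()` emulates the statistical structure the corrections care
about, with full ground truth:

* a smooth tissue blob (thresholded smoothed Gaussian noise) covering a
  requested area fraction — its exact geometry is not a contract, only the
  fraction;
* per-pixel Poisson counts for each tellurium isotope with rate
  (tissue × mean intensity + slide background) × natural abundance ×
  detection bias;
* a Poisson xenon baseline in the 134 channel, spilling into the 124, 126,
  128 and 130 channels at exactly the abundance-table ratios, with randomly
  placed full raster rows multiplied by a streak amplitude (a temporal xenon
  spike maps to a row because the laser rasters line by line);
* optional per-isotope multiplicative bias, either scaling the Poisson rates
  (the `bias` field) or applied post hoc to sampled counts
  (`inject_teb()`).

`standard_phantom()` fixes the configuration used throughout the test suite:
256 × 256 pixels, 40 % tissue at 50 expected Te counts/pixel across isotopes
122/124/125/126/128/130, xenon baseline 2 with five 20× streak rows, a slide
background of 2 counts/pixel, seed 0. The sizes keep every test and the
whole-suite runtime in seconds while leaving ~26 000 tissue pixels — enough
for median-based estimates to land well inside the tolerances asserted. The
slide-background floor deserves a note: real slides always carry low-level
residue counts in every channel, and without such a floor the phantom's
background would be *exactly* zero in channels without a xenon isobar,
making any noise-region standard deviation degenerate and SNR comparisons
meaningless. A floor of 2 counts/pixel (4 % of the tissue intensity) gives
the noise region the realistic sparse-counts character that makes geometric
combination interesting. `generate_phantom()` defaults the floor to 0 so
that analytic edge cases (e.g. a tissue-free phantom being pure xenon) stay
exact.

What the phantom does **not** model: cell-scale morphology, antibody or
lanthanide channels, probe pharmacokinetics, detector dead-time or
saturation during extreme xenon spikes, and instrument drift between
acquisitions. Passing tests therefore demonstrate correctness of the
*algorithms* under a faithful noise model, not performance on any particular
tissue.

## Numerical choices

* Counts are stored as doubles throughout (corrections produce
  non-integers); TIFF output is IEEE float32, and the bundled writer
  round-trips any float32-representable value bit-exactly.
* Gaussian kernels are sampled and truncated at 4σ, normalized to sum 1;
  all blurs use half-sample-symmetric reflection at every boundary.
* Medians use R's midpoint convention for even counts.
* The geometric mean short-circuits exact zeros rather than relying on
  `exp(log(0))`, preserving zero-propagation exactly.
* `snr()` raises an error on a zero noise standard deviation rather than
  returning infinity.
* Phantom determinism: all randomness is drawn under `withr::with_seed`, so
  a spec with the same seed reproduces bit-identical stacks regardless of
  the caller's RNG state.

## Known limitations

* The abundance table is a standard compilation; the third decimal of
  derived ratios can differ between compilations (0.183 is stable, a fourth
  decimal would not be guaranteed).
* The xenon correction is purely per-pixel; it does not model temporal spike
  shape within a row, nor possible 134-channel saturation during large
  spikes.
* TEB correction assumes a single multiplicative bias per isotope pair per
  acquisition; drift within a long acquisition is not corrected, only
  re-measurable.
* The pixel-table reader accepts the documented header dialects
  (`128Te`, `Te128`, `128Te(Te128Di)`); exotic vendor variants may need the
  explicit label override of the TIFF reader or renamed columns.
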