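# tecyto

Processing tools for tellurium imaging mass cytometry (IMC).

Tellurium-containing probes extend IMC beyond antibody staining — in
particular SLIP experiments (sequential labelling with isotopologous probes),
where the same probe dosed twice with two enriched isotopes encodes two
timepoints in two mass channels. Tellurium data need three corrections that
generic IMC software does not provide, and this package implements all three,
plus the I/O and a ground-truth phantom generator to validate them:

1. **Xenon background removal.** Stable xenon isotopes at masses 124, 126,
   128 and 130 are isobaric with tellurium, and trace xenon in the argon
   carrier gas adds background — including whole-row streaks from transient
   spikes. The 134 channel contains xenon only, so for a contaminated
   channel *m*,

   *I*<sub>m</sub> = *T*<sub>m</sub> + *Y*<sub>m</sub>,  *Y*<sub>m</sub> = *X*<sub>134</sub> · ab(<sup>m</sup>Xe)/ab(<sup>134</sup>Xe),

   and `dexenon_stack()` recovers *T*<sub>m</sub> = *I*<sub>m</sub> −
   *Y*<sub>m</sub> (abundance ratio 0.183 for mass 128, from the bundled
   CIAAW/NIST-style table; or an empirically measured ratio from a
   tissue-free region).

2. **Transmission efficiency bias (TEB).** The instrument over-detects
   heavier isotopes. From a natural-abundance acquisition,

   TEB(a, b) = median(*A*/*B*) / (ab(<sup>a</sup>Te)/ab(<sup>b</sup>Te)),

   computed by `compute_teb()` on xenon-corrected, lightly blurred
   (σ = 1 px), thresholded (≥ 1 count) channels; TEB = 1 means no bias.
   `apply_teb()` divides the over-detected channel by it, and
   `slip_difference()` / `fraction_sign_changed()` quantify what the
   correction changes in a SLIP difference image.

3. **Channel combination.** `combine()` fuses several natural-abundance
   channels arithmetically (sum) or geometrically (n-th root of the product,
   with exact zero propagation), optionally after an isotropic 3-D Gaussian
   blur across rows, columns and the channel axis; `snr()` scores the result
   as signal-region mean over noise-region standard deviation.

Supported formats: instrument pixel tables (tab- or comma-separated, one row
per pixel), multi-page 32-bit float TIFF stacks with per-page channel labels,
and per-channel CSV grids. A command-line interface
(`system.file("cli", "tecyto", package = "tecyto")`) exposes `simulate`,
`dexenon`, `teb`, `slipdiff` and `combine` subcommands.

## Worked example

Everything below runs without instrument data, on the package's standard
phantom (256 × 256 px, 40 % tissue, Poisson counts split across six Te
isotopes by natural abundance, xenon baseline with five streak rows,
seed 0):

```r
library(tecyto)

ph  <- standard_phantom()
ph$stack
#> <image_stack> 7 channel(s), 256x256 px: 122Te 124Te 125Te 126Te 128Te 130Te 134Xe

dex <- dexenon_stack(ph$stack)           # xenon removed from 124/126/128/130

compute_teb(stack_channel(dex, 126), stack_channel(dex, 128))
#> <teb_result> Te pair 126/128
#>   median ratio      0.589704
#>   theoretical ratio 0.593573
#>   TEB               0.993482  (1 = unbiased; >1 = 126 over-detected)
#>   valid pixels      28278
```

The phantom is unbiased, and the measured TEB is 1 within noise. Injecting a
20 % detection bias and re-measuring recovers it:

```r
biased <- inject_teb(dex, list("126" = 1.2))
compute_teb(stack_channel(biased, 126), stack_channel(biased, 128))
#> <teb_result> Te pair 126/128
#>   median ratio      0.707645
#>   theoretical ratio 0.593573
#>   TEB               1.19218  (1 = unbiased; >1 = 126 over-detected)
#>   valid pixels      28650
```

Geometric fusion of four channels with a 3-D blur beats any single channel's
signal-to-noise by a wide margin:

```r
mk <- phantom_masks(ph$truth)            # tissue/background with a 6 px margin
snr(combine(dex, c(125, 126, 128, 130), mode = "geometric", blur_sigma = 1),
    mk$signal, mk$noise)
#> <snr_result> SNR 101.2 (signal mean 11.16 over 15976 px / noise sd 0.1103 over 28799 px)
snr(stack_channel(dex, 130), mk$signal, mk$noise)
#> <snr_result> SNR 15.34 (signal mean 17.75 over 15976 px / noise sd 1.157 over 28799 px)
```

The SNR of 101.2 for the fused image versus 15.3 for the best single channel
is the phantom-scale counterpart of the improvement seen on tissue.

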