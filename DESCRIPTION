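Package: tecyto
Title: Processing Tools for Tellurium Imaging Mass Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrections and channel-fusion tools for imaging mass cytometry
    (IMC) experiments that use tellurium-containing probes. Implements removal
    of isobaric xenon background from tellurium mass channels using the pure
    xenon 134 channel and natural isotopic abundances, quantification and
    correction of the instrument's transmission efficiency bias (TEB) between
    tellurium isotopes from natural-abundance acquisitions, difference imaging
    for sequential labelling with isotopologous probes (SLIP), and combination
    of multiple tellurium mass channels (arithmetic or geometric, with optional
    3-D Gaussian blurring) to improve signal-to-noise ratio. Includes readers
    and writers for instrument-exported pixel tables, multi-page 32-bit float
    TIFF stacks and per-channel CSV grids, a synthetic tissue-phantom generator
    with known ground truth for validating every correction, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
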