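Package: zstacknorm
Title: Depth-Attenuation Correction and Visualization for Confocal Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects depth-dependent fluorescence intensity loss in confocal
    Z-stacks by section-specific intensity normalization (SsIN): each optical
    section of a signal-of-interest channel is divided, pixel by pixel, by the
    non-zero mean of a housekeeping normalization channel at the same focal
    depth. Renders section-normalized intensity projections (SNIP): orthogonal
    mean-intensity projections min/max scaled to 8-bit heatmaps. Includes
    depth-loss and per-section histogram diagnostics, linear
    brightness/contrast rescaling, TIFF image-sequence input/output that
    preserves native bit depth, a synthetic phantom generator with known
    ground-truth attenuation for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tiff,
    jsonlite,
    yaml,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
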