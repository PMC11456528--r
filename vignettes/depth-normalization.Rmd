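---
title: "Correcting depth-dependent fluorescence loss in confocal Z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting depth-dependent fluorescence loss in confocal Z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zstacknorm)
```

## The problem

Confocal optical sectioning loses fluorescence signal as the focal plane
moves deeper into a 3D specimen: excitation and emission light are scattered
and absorbed by the tissue above the plane. In thick preparations — cell
clusters tens of micrometres deep, embryonic tissue, organoids — the detected
intensity of a protein stain can fall by more than half between the top and
the bottom of a Z-stack even when the protein itself is uniformly
distributed. Any conclusion about *where* a protein sits in the volume is
confounded by *how deep* that location is.

## The model

`zstacknorm` corrects this bias by **section-specific intensity
normalization (SsIN)**. Two channels are acquired from the same sample with
identical sectioning: the **signal of interest (SOI)**, whose spatial
distribution is under study, and a **normalization signal (NS)** — a
housekeeping stain such as DAPI — assumed to attenuate proportionally with
the SOI.

Write the detected intensity of channel $c$ at pixel $(y,x)$ of section $z$
as

$$ I_c(z, y, x) \;=\; a(z)\, B_c(y, x, z) + \varepsilon, $$

where $B_c$ is the true (unattenuated) signal, $a(z)$ the shared per-section
attenuation factor and $\varepsilon$ noise. SsIN estimates $a(z)$ (up to a
constant) by the **section-specific mean (SSM)** of the NS — the mean over
its *non-zero* pixels, so empty regions of the field of view do not dilute
the estimate — and divides every SOI pixel by the SSM at its depth:

$$ \tilde I(z, y, x) \;=\; \frac{I_{\mathrm{SOI}}(z, y, x)}
   {\overline{I_{\mathrm{NS}}}(z)} \times \max_z \overline{I_{\mathrm{NS}}}(z). $$

If the NS base pattern is depth-flat, $\overline{I_{\mathrm{NS}}}(z) \propto
a(z)$ and the division cancels the attenuation exactly, while genuine
depth structure of the SOI (a protein really concentrated near the top)
passes through unchanged. The trailing factor is discussed below.

Before normalization the SOI is segmented by **histogram thresholding**: the
user supplies an inclusive intensity window and everything outside it is
treated as background or artifact (saturated antibody precipitates, for
example) and set to zero in the output. The threshold is applied to the SOI
only — the depth-loss information of the NS lives largely in its low pixel
values, which a threshold would destroy — and zero-valued pixels are always
excluded from every mean.

**SNIP** (section-normalized intensity projection) then summarizes the
volume as three mean-intensity projections — over $z$ (the xy view), over
rows (xz) and over columns (yz) — each min/max scaled to 8-bit and shown as
an orthogonal heatmap. Applied after SsIN, the xz and yz views show protein
localization free of the depth gradient.

## Worked example

```{r example}
model <- attenuation_model("exponential", 40, final_fraction = 0.3)
pair <- generate_pair(phantom_spec(shape = c(40, 128, 128), seed = 1), model)

pre <- depth_profile(pair$soi)
round(min(pre$percent), 1)          # 30: the deepest section keeps 30%

norm <- ssin_normalize(pair$soi, section_means(pair$ns),
                       threshold_range(0, 255))
post <- depth_profile(norm)
round(range(post$percent), 1)       # ~100 everywhere: flatness recovered
```

## Tunable parameters

* **Threshold window** (`threshold_range(lo, hi)`, native intensity units;
  default the full dynamic range). Widen to keep faint deep signal; narrow
  to reject artifacts. Remember the window is fixed across depth, so true
  signal that attenuates below `lo` in deep sections is lost — inspect the
  histogram cube when choosing it.
* **`rescale_mode`** of `ssin_normalize()`: raw SsIN ratios are far below 1
  and would vanish when exported at the native integer bit depth. The
  default `"max_mean"` multiplies them by $\max_z \overline{I_{\mathrm{NS}}}(z)$,
  leaving the brightest-NS section approximately unchanged and brightening
  deeper ones, so the output stays on an intensity-like scale. `"none"`
  returns the raw ratios. This scale restoration is this package's explicit
  convention for reconciling sub-unity ratios with native-bit-depth export.
* **Brightness/contrast window** (`compute_scale()`/`apply_scale()`): a
  linear map `clip(round(alpha * p - beta))` with
  `alpha = dtype_max / (user_max - user_min)` and `beta = user_min * alpha`,
  sending the window onto the full range; values outside the window
  saturate. `window_stats()` prints per-section percentiles to guide the
  choice in place of an interactive picker.
* **Histogram bins** (`n_bins`, default 256): uniform over the dynamic range
  for integer stacks, over the observed range for normalized stacks; the
  heatmap colors `log(1 + count)` so empty bins render at the colormap
  floor.

## What the synthetic phantoms emulate — and what they do not

`generate_pair()` builds a two-channel acquisition with known ground truth:

* a circular cluster footprint (disk) on a **zero background**, the NS
  decorated with brighter nuclei-like Gaussian blobs;
* an SOI that is depth-uniform (a homogeneously distributed mitochondrial
  protein), or confined to a top cap plus peripheral ring over a dim
  interior (`top_shell`, a membrane receptor of the outer cell layers), or
  to the ring only (`peripheral_shell`);
* a shared per-section attenuation $a(z)$, exponential by default
  ($a(z) = e^{-\lambda z}$, the form used throughout the decay-correction
  literature), reaching 30% at the deepest of 40 sections in the default
  configuration — the severe-loss regime observed in real cell clusters of
  comparable thickness (~1 µm per section, cluster ~40 µm);
* additive Gaussian noise applied **only where the base pattern is
  non-zero**, then rounding and clipping to the integer dynamic range.
  Signal-borne (shot-like) noise is the dominant stochastic term on
  fluorescent structures, and keeping the background exactly zero matches
  the premise of the zero-pixel exclusion rule. Real detectors add a small
  dark/read noise everywhere; a background pedestal that does not attenuate
  with depth violates the proportionality assumption and degrades SsIN on
  real data — the phantoms deliberately do not model it, so passing tests
  say nothing about background-contaminated acquisitions.

The phantoms also omit optics: no point-spread function, no light scattering
anisotropy, no photobleaching over acquisition time. They validate the
*arithmetic* of the pipeline and its statistical behavior under noise, not
the biological realism of any particular acquisition.

`quantize = FALSE` returns the idealized continuous-intensity phantom. On
it, proportional attenuation cancels to floating-point precision
(deviations ~1e-15), which is how the exact-cancellation property is
verified. On quantized 8-bit stacks the attainable flatness is bounded by
rounding: at the deepest section the per-pixel rounding error of up to 0.5
on means of order 45–55 leaves residuals of order 1–2%, which is what the
quantized end-to-end checks expect.

## Noise tolerance derivation

For a noisy phantom, `expected_flat_profile()` predicts the post-SsIN
profile and a tolerance band from first principles, before any measurement:
with noise $\sigma$ and quantization variance $1/12$,
$\sigma_\mathrm{eff}^2 = \sigma^2 + 1/12$, the relative standard error of a
section's masked mean is $\sigma_\mathrm{eff} / (\sqrt{n}\,\mu(z))$ per
channel; the percent profile divides by the maximum section, so per-section
deviations combine the SOI and NS errors of that section and of the maximum
section (`sem`). Because a flatness check compares *all* $Z$ sections
simultaneously, the profile-wide band is the expected scale of the largest
excursion among $Z$ near-independent Gaussian deviations,
$2\,\max_z r(z) \sqrt{2 \ln 2Z} \times 100$ percent points (`tol`). The
noise-robustness checks require every section of a run to stay within three
such bands.

## Numerical conventions

* Rounding is half-away-from-zero everywhere an intensity is quantized
  (grayscale conversion, min/max scaling, brightness/contrast, TIFF export).
* Grayscale conversion of RGB frames uses the standard luma weights
  0.299/0.587/0.114; input frames are treated as RGB.
* ROIs are 0-based and half-open, `c(x0, y0, x1, y1)` with x = column,
  y = row.
* `minmax_scale()` of a constant image returns all zeros (no range to
  stretch).
* Each SNIP view is min/max scaled independently, so each fills its own
  0–255 range; raw projections are always returned alongside for
  quantitative comparisons across views.
* Projections include zero pixels; the zero-exclusion rule applies to mean
  *calculations* (SSM, depth profiles), not to projections. Thresholds gate
  normalization and diagnostics, not projections.
* An NS section with no non-zero pixels is a hard error naming the section:
  imputing a mean would silently corrupt the normalization.
* TIFF sequences are written uncompressed, one grayscale file per section,
  zero-padded names (`section_000.tif`), and round-trip integer stacks
  bit-identically; filename order on load uses a natural-numeric sort
  (`s2` before `s10`).

## Design choices made where the design was open

* **Scale restoration** (`max_mean`) as the default export path — see above.
* **Offset sign**: the linear transform is `alpha * p - beta`; it is the
  only sign convention under which the window minimum maps to 0 and the
  maximum to the top of the range. Out-of-window values clip rather than
  wrap.
* **Depth profiles** report both raw per-section means and percent-of-max,
  since either scale is useful when comparing pre/post normalization.
* **Problem sizes** used in the validation suite — 40 sections of 128×128
  for the headline phantoms, 100 repetitions for the noise study, 3×4×4
  stacks for brute-force oracle comparisons — were chosen as the smallest
  sizes at which the statistics of interest are stable.
* The interactive notebook workflow of comparable tools is replaced by a
  scriptable CLI (`run_cli()`, `inst/cli/zstacknorm`) with a YAML config,
  flag overrides and a JSON manifest per run, so every analysis is
  reproducible from its output directory.

## Limitations

SsIN is only as good as the normalization signal: if the NS photobleaches
faster than the SOI, or is itself depth-structured, the correction inherits
that bias. Histogram thresholding is a fixed global window; uneven
illumination or genuinely dim deep structures can fall outside it. The
method standardizes intensities — it does not deconvolve, denoise, or
increase resolution, and it performs no pixel reassignment.
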