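# Section-specific intensity normalization (SsIN).
#
# Fluorescence detected from a 3D specimen decays with focal depth (light
# scattering/absorption). If a housekeeping normalization signal (NS, e.g.
# DAPI) attenuates proportionally with the signal of interest (SOI), dividing
# every SOI pixel by the non-zero mean of the NS at the same optical section
# cancels the shared depth factor while leaving genuine spatial structure of
# the SOI intact.

#' Inclusive pixel-value threshold
#'
#' Defines which pixel values participate in analysis. Pixels outside
#' `[lo, hi]` are treated as background or experimental artifact (e.g.
#' saturated antibody precipitates) and excluded; zero-value pixels are always
#' excluded from mean calculations regardless of the bounds.
#'
#' @param lo,hi Inclusive lower/upper bounds in native intensity units.
#' @return An object of class `ThresholdRange`.
#' @export
threshold_range <- function(lo, hi) {
  if (anyNA(c(lo, hi)) || lo < 0 || lo > hi) {
    stop_validation("invalid threshold: need 0 <= lo <= hi")
  }
  structure(list(lo = lo, hi = hi), class = "ThresholdRange")
}

#' @export
print.ThresholdRange <- function(x, ...) {
  cat(sprintf("ThresholdRange: [%g, %g]\n", x$lo, x$hi))
  invisible(x)
}

# Full-range threshold for a given bit depth (zero exclusion still applies).
full_threshold <- function(bd) threshold_range(0, 2^bd - 1)

#' Analysis mask of a section
#'
#' TRUE exactly where `lo <= pixel <= hi` and the pixel is non-zero. The mask
#' may be all-FALSE.
#'
#' @param section A 2D numeric matrix.
#' @param threshold A [threshold_range()].
#' @return A logical matrix of the same shape.
#' @export
analysis_mask <- function(section, threshold) {
  stopifnot(inherits(threshold, "ThresholdRange"))
  section >= threshold$lo & section <= threshold$hi & section != 0
}

#' Mean of the masked pixels of a section
#'
#' @param section A 2D numeric matrix.
#' @param mask A logical matrix from [analysis_mask()].
#' @return The arithmetic mean of `section[mask]`.
#' @export
masked_mean <- function(section, mask) {
  if (!any(mask)) stop_validation("no analyzable pixels in section")
  mean(section[mask])
}

#' Per-section non-zero means of the normalization signal
#'
#' Computes the section-specific mean (SSM) of the NS channel at every optical
#' section: the mean over non-zero pixels only, so that empty regions of the
#' field of view (no cells) do not dilute the estimate. No user threshold is
#' applied to the NS — much of the depth-loss information lives in its low
#' pixel values, which a threshold would discard.
#'
#' @param ns_stack The normalization-signal `ZStack`.
#' @return An object of class `SectionMeans`: a numeric vector with one
#'   strictly positive entry per section.
#' @examples
#' ns <- zstack(list(matrix(100, 2, 2), matrix(50, 2, 2)), 8)
#' section_means(ns)
#' @export
section_means <- function(ns_stack) {
  z <- n_sections(ns_stack)
  thr <- full_threshold(bit_depth(ns_stack))
  means <- numeric(z)
  for (i in seq_len(z)) {
    sec <- get_section(ns_stack, i)
    mask <- analysis_mask(sec, thr)
    if (!any(mask)) {
      stop_validation("no analyzable pixels in section ", i,
                      " of the normalization stack")
    }
    means[i] <- masked_mean(sec, mask)
  }
  structure(means, class = "SectionMeans")
}

#' @export
print.SectionMeans <- function(x, ...) {
  cat(sprintf("SectionMeans: %d sections, range [%.4g, %.4g]\n",
              length(x), min(x), max(x)))
  invisible(x)
}

#' Section-specific intensity normalization of the signal of interest
#'
#' Divides every in-threshold, non-zero SOI pixel by the NS mean at the same
#' focal depth. Out-of-threshold and zero pixels are set to 0 in the output,
#' preserving image geometry. Because the raw ratios are well below 1, the
#' default `rescale_mode = "max_mean"` multiplies them by `max(ns_means)`:
#' the section with the brightest NS is left approximately unchanged and
#' deeper sections are brightened, so the result remains on an intensity-like
#' scale that survives export at the native bit depth.
#'
#' @param soi_stack The signal-of-interest `ZStack`.
#' @param ns_means [section_means()] of the paired NS stack (or an NS
#'   `ZStack`, from which the means are computed). Both channels must come
#'   from the same acquisition: identical section count, thickness and
#'   resolution.
#' @param soi_threshold A [threshold_range()] applied to the SOI only.
#' @param rescale_mode `"max_mean"` (default, ratios times `max(ns_means)`)
#'   or `"none"` (raw ratios).
#' @return A `NormalizedZStack` carrying the SOI's bit depth as
#'   `source_bit_depth`.
#' @examples
#' soi <- zstack(list(matrix(80, 2, 2), matrix(40, 2, 2)), 8)
#' ns  <- zstack(list(matrix(100, 2, 2), matrix(50, 2, 2)), 8)
#' out <- ssin_normalize(soi, section_means(ns), threshold_range(0, 255),
#'                       rescale_mode = "none")
#' get_section(out, 2)  # 40/50 = 0.8 everywhere
#' @export
ssin_normalize <- function(soi_stack, ns_means,
                           soi_threshold = full_threshold(bit_depth(soi_stack)),
                           rescale_mode = c("max_mean", "none")) {
  rescale_mode <- match.arg(rescale_mode)
  if (inherits(ns_means, "ZStack")) ns_means <- section_means(ns_means)
  if (!inherits(ns_means, "SectionMeans")) {
    stop_validation("ns_means must be a SectionMeans or an NS ZStack")
  }
  if (length(ns_means) != n_sections(soi_stack)) {
    stop_validation("channel stacks not aligned: SOI has ",
                    n_sections(soi_stack), " sections, NS means ",
                    length(ns_means))
  }
  if (any(ns_means <= 0)) {
    stop_validation("non-positive NS section mean at section ",
                    which(ns_means <= 0)[1])
  }
  arr <- unclass(soi_stack)
  keep <- arr >= soi_threshold$lo & arr <= soi_threshold$hi & arr != 0
  denom <- rep(unclass(ns_means), each = stack_height(soi_stack) *
                 stack_width(soi_stack))
  out <- ifelse(keep, arr / denom, 0)
  if (rescale_mode == "max_mean") out <- out * max(ns_means)
  normalized_zstack(array(out, dim = dim(arr)),
                    source_bit_depth = bit_depth(soi_stack))
}
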