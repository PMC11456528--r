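# Depth-loss and pixel-distribution diagnostics, computed before and after
# normalization so the effect of SsIN can be inspected quantitatively.

default_threshold <- function(stack) {
  if (inherits(stack, "NormalizedZStack")) {
    threshold_range(0, Inf)
  } else {
    full_threshold(bit_depth(stack))
  }
}

#' Depth-loss profile of a Z-stack
#'
#' Computes the masked mean pixel value of each optical section (in-threshold,
#' non-zero pixels only) and expresses it as a percentage of the maximum
#' section mean of the whole stack. A depth-flat stack yields 100 at every
#' section; attenuation shows up as a decline with section index. Both the
#' raw per-section means and the percent-of-max values are returned.
#'
#' @param stack A `ZStack` or `NormalizedZStack`.
#' @param threshold A [threshold_range()]; by default the full dynamic range
#'   (zero-value pixels are always excluded).
#' @return An object of class `DepthProfile`: list with `percent` (numeric,
#'   one entry per section, maximum exactly 100), `means` (raw masked means)
#'   and `n_sections`.
#' @examples
#' zs <- zstack(list(matrix(100, 2, 2), matrix(80, 2, 2), matrix(60, 2, 2)), 8)
#' depth_profile(zs)$percent
#' @export
depth_profile <- function(stack, threshold = default_threshold(stack)) {
  z <- n_sections(stack)
  means <- numeric(z)
  for (i in seq_len(z)) {
    sec <- get_section(stack, i)
    mask <- analysis_mask(sec, threshold)
    if (!any(mask)) stop_validation("no analyzable pixels in section ", i)
    means[i] <- masked_mean(sec, mask)
  }
  structure(list(percent = means / max(means) * 100,
                 means = means,
                 n_sections = z),
            class = "DepthProfile")
}

#' @export
print.DepthProfile <- function(x, ...) {
  cat(sprintf("DepthProfile: %d sections, min %.2f%% of max\n",
              x$n_sections, min(x$percent)))
  invisible(x)
}

#' @export
as.data.frame.DepthProfile <- function(x, ...) {
  data.frame(section = seq_len(x$n_sections) - 1L,
             mean = x$means, percent_of_max = x$percent)
}

#' Per-section intensity histograms as one matrix
#'
#' Condenses the pixel-value histogram of every optical section into a single
#' sections-by-bins count matrix: row = optical section, column = histogram
#' bin, entry = number of in-threshold, non-zero pixels of that section
#' falling in the bin. Bins are uniform over the full dynamic range
#' (`[0, 2^bit_depth - 1]`) for integer stacks, or `[0, max(stack)]` for
#' real-valued normalized stacks; the final bin is right-closed.
#'
#' @param stack A `ZStack` or `NormalizedZStack`.
#' @param n_bins Number of bins (>= 2); default 256.
#' @param threshold A [threshold_range()].
#' @return An object of class `HistogramCube`: list with `counts`
#'   (`n_sections x n_bins` integer matrix) and `bin_edges` (length
#'   `n_bins + 1`).
#' @export
histogram_cube <- function(stack, n_bins = 256L,
                           threshold = default_threshold(stack)) {
  if (length(n_bins) != 1L || is.na(n_bins) || n_bins < 2L) {
    stop_validation("invalid bin count")
  }
  n_bins <- as.integer(n_bins)
  upper <- if (inherits(stack, "NormalizedZStack")) {
    max(max(stack), .Machine$double.eps)
  } else {
    2^bit_depth(stack) - 1
  }
  edges <- seq(0, upper, length.out = n_bins + 1L)
  z <- n_sections(stack)
  counts <- matrix(0L, nrow = z, ncol = n_bins)
  for (i in seq_len(z)) {
    sec <- get_section(stack, i)
    px <- sec[analysis_mask(sec, threshold)]
    px <- px[px <= upper]  # guard: values beyond the binned range
    if (length(px)) {
      idx <- findInterval(px, edges, rightmost.closed = TRUE)
      counts[i, ] <- tabulate(idx, nbins = n_bins)
    }
  }
  structure(list(counts = counts, bin_edges = edges, n_bins = n_bins),
            class = "HistogramCube")
}

#' @export
print.HistogramCube <- function(x, ...) {
  cat(sprintf("HistogramCube: %d sections x %d bins, %d pixels counted\n",
              nrow(x$counts), x$n_bins, sum(x$counts)))
  invisible(x)
}

# Open a png or svg device depending on the file extension.
open_device <- function(out, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(out))
  switch(ext,
    png = grDevices::png(out, width = width, height = height,
                         units = "in", res = 150),
    svg = grDevices::svg(out, width = width, height = height),
    stop_validation("unsupported figure format: .", ext, " (use png or svg)")
  )
}

#' Render a pre- vs post-normalization depth-loss plot
#'
#' @param pre,post [depth_profile()] objects with equal section counts
#'   (`post` may be NULL to plot a single profile).
#' @param out Output figure path (`.png` or `.svg`).
#' @param labels Legend labels for the two profiles.
#' @return Invisibly, `out`.
#' @export
render_depth_plot <- function(pre, post = NULL, out,
                              labels = c("pre-SsIN", "post-SsIN")) {
  stopifnot(inherits(pre, "DepthProfile"))
  if (!is.null(post)) {
    stopifnot(inherits(post, "DepthProfile"))
    if (post$n_sections != pre$n_sections) {
      stop_validation("profiles have different section counts")
    }
  }
  open_device(out)
  on.exit(grDevices::dev.off(), add = TRUE)
  xs <- seq_len(pre$n_sections) - 1L
  graphics::plot(xs, pre$percent, type = "o", pch = 16, cex = 0.6,
                 col = "#1b6ca8", ylim = c(0, 105),
                 xlab = "optical section (0 = shallowest)",
                 ylab = "mean pixel value (% of maximum section mean)")
  if (!is.null(post)) {
    graphics::lines(xs, post$percent, type = "o", pch = 17, cex = 0.6,
                    col = "#c0392b")
    graphics::legend("bottomleft", legend = labels, col =
                       c("#1b6ca8", "#c0392b"), pch = c(16, 17), lty = 1,
                     bty = "n")
  }
  invisible(out)
}

#' Render a histogram cube as a heatmap
#'
#' x-axis: histogram bin; y-axis: optical section; color: pixel count on a
#' `log(1 + count)` scale so empty bins map to the colormap floor.
#'
#' @param cube A [histogram_cube()].
#' @param out Output figure path (`.png` or `.svg`).
#' @param colormap Name of a [grDevices::hcl.colors()] palette.
#' @return Invisibly, `out`.
#' @export
render_histogram_cube <- function(cube, out, colormap = "viridis") {
  stopifnot(inherits(cube, "HistogramCube"))
  open_device(out)
  on.exit(grDevices::dev.off(), add = TRUE)
  z <- nrow(cube$counts)
  mids <- (cube$bin_edges[-1] + cube$bin_edges[-length(cube$bin_edges)]) / 2
  graphics::image(x = mids, y = seq_len(z) - 1L,
                  z = t(log1p(cube$counts)),
                  col = grDevices::hcl.colors(64, colormap),
                  xlab = "pixel value (bin midpoint)",
                  ylab = "optical section", useRaster = TRUE)
  invisible(out)
}

#' Write a depth profile or histogram cube to CSV
#'
#' @param x A `DepthProfile` or `HistogramCube`.
#' @param out Output CSV path.
#' @return Invisibly, `out`.
#' @export
write_diagnostic_csv <- function(x, out) {
  if (inherits(x, "DepthProfile")) {
    utils::write.csv(as.data.frame(x), out, row.names = FALSE)
  } else if (inherits(x, "HistogramCube")) {
    df <- as.data.frame(x$counts)
    names(df) <- sprintf("bin_%g_%g", x$bin_edges[-length(x$bin_edges)],
                         x$bin_edges[-1])
    df <- cbind(section = seq_len(nrow(df)) - 1L, df)
    utils::write.csv(df, out, row.names = FALSE)
  } else {
    stop_validation("cannot export object of class ", class(x)[1])
  }
  invisible(out)
}
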