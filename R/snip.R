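# Section-normalized intensity projection (SNIP): mean-intensity projections
# along each axis of the volume, min/max scaled to 8-bit and shown as an
# orthogonal-view heatmap. Applied to a SsIN-normalized stack it reveals
# protein localization free of the depth-attenuation bias.

#' Mean-intensity projection along one axis
#'
#' Averages all pixels along the chosen axis. All pixels participate —
#' thresholding affects normalization and depth plots, not projections, so
#' the projection remains a plain mean-intensity projection of the volume.
#'
#' Axis naming: `"z"` collapses depth and yields the xy view (height x width);
#' `"y"` collapses rows and yields the xz view (sections x width); `"x"`
#' collapses columns and yields the yz view (height x sections). In the xz and
#' yz views the section axis runs shallow to deep.
#'
#' @param stack A `ZStack` or `NormalizedZStack`.
#' @param axis `"z"`, `"y"` or `"x"`.
#' @return A real-valued matrix.
#' @examples
#' zs <- zstack(list(matrix(0, 1, 1), matrix(10, 1, 1)), 8)
#' mean_projection(zs, "z")  # 5
#' @export
mean_projection <- function(stack, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  arr <- unclass(stack)
  switch(axis,
    z = rowMeans(arr, dims = 2L),                    # H x W
    y = t(colMeans(arr, dims = 1L)),                 # Z x W
    x = rowMeans(aperm(arr, c(1L, 3L, 2L)), dims = 2L)  # H x Z
  )
}

#' Min/max scale an image to the 8-bit range
#'
#' Linearly maps the smallest value to 0 and the largest to 255 so the full
#' visual range is used; rounding is half-away-from-zero. A constant image
#' has no range to stretch and maps to all zeros.
#'
#' @param img A numeric matrix.
#' @return An integer matrix with values in `[0, 255]`.
#' @examples
#' minmax_scale(matrix(c(50, 100, 150), 1))  # 0 128 255
#' @export
minmax_scale <- function(img) {
  if (length(img) == 0L) stop_validation("empty image")
  lo <- min(img); hi <- max(img)
  out <- if (hi > lo) round_half_up((img - lo) / (hi - lo) * 255) else img * 0
  storage.mode(out) <- "integer"
  out
}

#' Orthogonal mean-projection heatmap (SNIP)
#'
#' Computes the xy, xz and yz mean projections of a stack, min/max scales each
#' view independently to 8-bit, and (optionally) renders them as a composite
#' orthogonal-view heatmap: xy in the center, xz below it (sharing the x
#' axis), yz to its right (sharing the y axis), plus a color bar. Raw
#' projections are returned alongside the scaled ones for quantitative use.
#'
#' @param stack A `ZStack` or `NormalizedZStack`.
#' @param colormap Name of a [grDevices::hcl.colors()] palette
#'   (perceptually uniform `"viridis"` by default).
#' @param out Optional figure path (`.png`/`.svg`); if `NULL` nothing is
#'   rendered.
#' @return An object of class `ProjectionSet`: list with elements `xy`, `xz`,
#'   `yz`, each a list of `raw` (real means) and `scaled` (8-bit) matrices.
#' @export
snip_heatmap <- function(stack, colormap = "viridis", out = NULL) {
  views <- list(
    xy = mean_projection(stack, "z"),
    xz = mean_projection(stack, "y"),
    yz = mean_projection(stack, "x")
  )
  ps <- structure(
    lapply(views, function(v) list(raw = v, scaled = minmax_scale(v))),
    class = "ProjectionSet"
  )
  if (!is.null(out)) render_projection_set(ps, out, colormap)
  ps
}

#' @export
print.ProjectionSet <- function(x, ...) {
  cat(sprintf(
    "ProjectionSet: xy %dx%d, xz %dx%d, yz %dx%d (raw + 8-bit scaled)\n",
    nrow(x$xy$raw), ncol(x$xy$raw), nrow(x$xz$raw), ncol(x$xz$raw),
    nrow(x$yz$raw), ncol(x$yz$raw)))
  invisible(x)
}

# image() draws rows along x; orient so matrix row 1 is the top of the panel.
draw_view <- function(m, cols, zlim) {
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = cols, zlim = zlim, axes = FALSE, xlab = "", ylab = "",
                  useRaster = TRUE)
  graphics::box(col = "grey40")
}

#' Render a projection set as a composite orthogonal-view figure
#'
#' @param ps A `ProjectionSet` from [snip_heatmap()].
#' @param out Figure path (`.png`/`.svg`).
#' @param colormap Palette name for [grDevices::hcl.colors()].
#' @return Invisibly, `out`.
#' @export
render_projection_set <- function(ps, out, colormap = "viridis") {
  stopifnot(inherits(ps, "ProjectionSet"))
  open_device(out, width = 8, height = 7)
  on.exit(grDevices::dev.off(), add = TRUE)
  cols <- grDevices::hcl.colors(256, colormap)
  graphics::layout(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE),
                   widths = c(4, 1.6), heights = c(4, 1.6))
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  draw_view(ps$xy$scaled, cols, c(0, 255))
  graphics::title("xy (mean over z)", cex.main = 0.9)
  draw_view(ps$yz$scaled, cols, c(0, 255))
  graphics::title("yz (depth →)", cex.main = 0.9)
  draw_view(ps$xz$scaled, cols, c(0, 255))
  graphics::title("xz (depth ↓)", cex.main = 0.9)
  # color bar
  graphics::image(x = 1, y = 0:255, z = matrix(0:255, 1), col = cols,
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, at = c(0, 128, 255), las = 1, cex.axis = 0.8)
  graphics::title("scaled\nintensity", cex.main = 0.8)
  invisible(out)
}

#' Export a projection set to disk
#'
#' Writes each scaled view as an 8-bit TIFF and each raw view as CSV.
#'
#' @param ps A `ProjectionSet`.
#' @param directory Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Invisibly, the files written.
#' @export
save_projection_set <- function(ps, directory, prefix = "snip") {
  stopifnot(inherits(ps, "ProjectionSet"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", directory)
  }
  files <- character(0)
  for (view in names(ps)) {
    ftif <- file.path(directory, sprintf("%s_%s_scaled.tif", prefix, view))
    tiff::writeTIFF(ps[[view]]$scaled / 255, ftif, bits.per.sample = 8L,
                    compression = "none")
    fcsv <- file.path(directory, sprintf("%s_%s_raw.csv", prefix, view))
    utils::write.csv(ps[[view]]$raw, fcsv, row.names = FALSE)
    files <- c(files, ftif, fcsv)
  }
  invisible(files)
}
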