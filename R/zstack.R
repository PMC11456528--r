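# ZStack container: a confocal Z-stack as an ordered series of equally sized
# 2D grayscale optical sections. Stored as a numeric [y, x, z] array; section
# index 1 is the shallowest focal plane (acquisition proceeds top -> down).

#' Construct a Z-stack
#'
#' A `ZStack` holds an ordered sequence of equally sized 2D grayscale optical
#' sections together with the acquisition bit depth. Section 1 is the
#' shallowest (top) focal plane; the index increases with imaging depth.
#'
#' Values must lie in `[0, 2^bit_depth - 1]`. Integer storage is not enforced
#' in the container (normalization and phantom generation produce real-valued
#' intensities); integrality is imposed when a stack is written to TIFF by
#' [save_stack()].
#'
#' @param sections A numeric 3D array `[y, x, z]`, or a list of equally sized
#'   numeric matrices (one per optical section, shallowest first).
#' @param bit_depth Dynamic range of the acquisition: 8 or 16.
#' @return An object of class `ZStack`.
#' @seealso [normalized_zstack()], [load_stack()], [save_stack()]
#' @examples
#' zs <- zstack(array(7, dim = c(4, 4, 3)), bit_depth = 8)
#' n_sections(zs)
#' @export
zstack <- function(sections, bit_depth = 8L) {
  arr <- as_section_array(sections)
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) {
    stop_validation("bit_depth must be 8 or 16, got ", bit_depth)
  }
  if (anyNA(arr)) stop_validation("stack contains NA pixel values")
  vmax <- 2^bit_depth - 1
  if (min(arr) < 0 || max(arr) > vmax) {
    stop_validation(
      "pixel values outside [0, ", vmax, "] for bit depth ", bit_depth
    )
  }
  structure(arr, bit_depth = bit_depth, class = "ZStack")
}

#' Construct a normalized Z-stack
#'
#' A `NormalizedZStack` holds the real-valued, non-negative output of
#' [ssin_normalize()]. It has no upper bound before export; [save_stack()]
#' clips and rounds it back to the source bit depth.
#'
#' @param sections Numeric 3D array `[y, x, z]` or list of matrices.
#' @param source_bit_depth Bit depth of the stack it was derived from (8/16).
#' @return An object of class `NormalizedZStack`.
#' @export
normalized_zstack <- function(sections, source_bit_depth = 8L) {
  arr <- as_section_array(sections)
  source_bit_depth <- as.integer(source_bit_depth)
  if (!source_bit_depth %in% c(8L, 16L)) {
    stop_validation("source_bit_depth must be 8 or 16")
  }
  if (anyNA(arr)) stop_validation("stack contains NA pixel values")
  if (min(arr) < 0) stop_validation("normalized stack has negative values")
  structure(arr, source_bit_depth = source_bit_depth,
            class = "NormalizedZStack")
}

# Coerce list-of-matrices / matrix / 3D array to a [y, x, z] array.
as_section_array <- function(sections) {
  if (is.list(sections)) {
    if (length(sections) == 0L) stop_validation("stack has no sections")
    dims <- unique(lapply(sections, dim))
    if (length(dims) != 1L || length(dims[[1]]) != 2L) {
      stop_validation("inconsistent section shape")
    }
    arr <- array(unlist(sections, use.names = FALSE),
                 dim = c(dims[[1]], length(sections)))
  } else if (is.matrix(sections)) {
    arr <- array(sections, dim = c(dim(sections), 1L))
  } else if (is.array(sections) && length(dim(sections)) == 3L) {
    arr <- sections
  } else {
    stop_validation("sections must be a 3D array or a list of matrices")
  }
  if (any(dim(arr) == 0L)) stop_validation("stack has degenerate dimensions")
  storage.mode(arr) <- "double"
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' @export
print.ZStack <- function(x, ...) {
  cat(sprintf("ZStack: %d sections of %dx%d (height x width), %d-bit\n",
              n_sections(x), stack_height(x), stack_width(x), bit_depth(x)))
  cat(sprintf("  intensity range: [%g, %g]\n", min(x), max(x)))
  invisible(x)
}

#' @export
print.NormalizedZStack <- function(x, ...) {
  cat(sprintf(
    "NormalizedZStack: %d sections of %dx%d, source %d-bit, range [%g, %g]\n",
    n_sections(x), stack_height(x), stack_width(x), bit_depth(x),
    min(x), max(x)))
  invisible(x)
}

#' Z-stack dimensions and metadata
#'
#' @param stack A `ZStack` or `NormalizedZStack`.
#' @return `n_sections()`, `stack_height()`, `stack_width()` return integers;
#'   `bit_depth()` returns 8 or 16 (for a `NormalizedZStack`, the source bit
#'   depth); `get_section()` returns the z-th section as a matrix.
#' @export
n_sections <- function(stack) dim(stack)[3L]

#' @rdname n_sections
#' @export
stack_height <- function(stack) dim(stack)[1L]

#' @rdname n_sections
#' @export
stack_width <- function(stack) dim(stack)[2L]

#' @rdname n_sections
#' @export
bit_depth <- function(stack) {
  bd <- attr(stack, "bit_depth", exact = TRUE)
  if (is.null(bd)) bd <- attr(stack, "source_bit_depth", exact = TRUE)
  if (is.null(bd)) stop_validation("object has no bit depth attribute")
  bd
}

#' @rdname n_sections
#' @param z Section index (1-based, 1 = shallowest focal plane).
#' @export
get_section <- function(stack, z) {
  if (z < 1L || z > n_sections(stack)) {
    stop_validation("section index out of range: ", z)
  }
  stack[, , z]
}

# Rebuild a stack of the same class around a new pixel array.
rewrap_stack <- function(arr, template) {
  if (inherits(template, "NormalizedZStack")) {
    normalized_zstack(arr, source_bit_depth = bit_depth(template))
  } else {
    zstack(arr, bit_depth = bit_depth(template))
  }
}

#' Crop every section of a Z-stack to a rectangular region of interest
#'
#' Restricting analysis to a region of interest excludes structures that would
#' distort normalization or projections — for example a cell monolayer
#' surrounding a cluster, which attenuates differently from the thick specimen
#' itself.
#'
#' Coordinates are 0-based and half-open: the ROI keeps columns
#' `x0 <= x < x1` and rows `y0 <= y < y1`, with x indexing columns and y rows.
#'
#' @param stack A `ZStack` or `NormalizedZStack`.
#' @param roi Numeric vector `c(x0, y0, x1, y1)`.
#' @return A stack of the same class containing only the ROI; the number of
#'   sections is unchanged.
#' @examples
#' zs <- zstack(array(seq_len(4 * 4 * 2), dim = c(4, 4, 2)), bit_depth = 16)
#' cropped <- crop_stack(zs, c(1, 1, 3, 3))
#' dim(cropped)
#' @export
crop_stack <- function(stack, roi) {
  if (length(roi) != 4L || anyNA(roi)) {
    stop_validation("invalid ROI: expected c(x0, y0, x1, y1)")
  }
  x0 <- roi[1]; y0 <- roi[2]; x1 <- roi[3]; y1 <- roi[4]
  if (any(roi != floor(roi)) ||
      x0 < 0 || y0 < 0 || x0 >= x1 || y0 >= y1 ||
      x1 > stack_width(stack) || y1 > stack_height(stack)) {
    stop_validation("invalid ROI")
  }
  arr <- unclass(stack)[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  rewrap_stack(arr, stack)
}

# Round half away from zero (for non-negative intensities this is
# floor(x + 0.5)); base round() would round halves to even.
round_half_up <- function(x) floor(x + 0.5)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Validation errors carry a dedicated condition class so the CLI can map
# them to exit code 2 (vs 1 for runtime failures).
stop_validation <- function(...) {
  stop(structure(
    class = c("zstacknorm_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
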