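# TIFF image-sequence I/O. Confocal software exports each channel of a
# Z-stack as a directory of single-plane TIFFs, one file per optical section;
# these readers/writers preserve resolution and native bit depth exactly.

#' Load a Z-stack from a directory of per-section TIFF files
#'
#' Reads every TIFF in `directory`, orders the frames by a natural-numeric
#' filename sort (so `s2.tif` precedes `s10.tif`, matching how confocal
#' exports number their frames), converts any multichannel frame to grayscale
#' via [to_grayscale()], and assembles a [zstack()] whose bit depth is taken
#' from the files themselves.
#'
#' @param directory Path to a directory containing one TIFF per section.
#' @param pattern Filename regexp selecting the image files.
#' @return A `ZStack`.
#' @examples
#' d <- tempfile(); dir.create(d)
#' save_stack(zstack(array(7, c(4, 4, 3)), 8), d)
#' zs <- load_stack(d)
#' @export
load_stack <- function(directory, pattern = "\\.tiff?$") {
  if (!dir.exists(directory)) {
    stop_validation("directory does not exist: ", directory)
  }
  files <- list.files(directory, pattern = pattern, ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) stop_validation("no images found in ", directory)
  files <- files[natural_order(basename(files))]

  frames <- vector("list", length(files))
  depths <- integer(length(files))
  for (i in seq_along(files)) {
    frames[[i]] <- to_grayscale(tiff::readTIFF(files[i], as.is = TRUE))
    info <- tiff::readTIFF(files[i], payload = FALSE)
    depths[i] <- as.integer(info$bits.per.sample[1])
  }
  shapes <- unique(lapply(frames, dim))
  if (length(shapes) != 1L) stop_validation("inconsistent section shape")
  if (length(unique(depths)) != 1L) stop_validation("inconsistent bit depth")
  zstack(frames, bit_depth = depths[1])
}

# Order filenames treating digit runs as numbers: s2 < s10.
natural_order <- function(names) {
  pieces <- strsplit(names, "(?<=\\D)(?=\\d)|(?<=\\d)(?=\\D)", perl = TRUE)
  n_keys <- max(lengths(pieces))
  keys <- lapply(seq_len(n_keys), function(k) {
    part <- vapply(pieces, function(p) if (k <= length(p)) p[k] else "",
                   character(1))
    num <- suppressWarnings(as.numeric(part))
    if (all(!is.na(num) | part == "")) {
      num[part == ""] <- -Inf
      num
    } else {
      part
    }
  })
  do.call(order, keys)
}

#' Convert a frame to single-channel grayscale
#'
#' Single-channel frames pass through unchanged. Three-channel (RGB) frames
#' are reduced with the standard luma weights
#' `0.299 R + 0.587 G + 0.114 B`, rounded to the nearest integer.
#'
#' @param frame A 2D matrix or an `H x W x 3` array (channels R, G, B).
#' @return A 2D matrix.
#' @examples
#' to_grayscale(array(c(255, 0, 0), c(1, 1, 3)))  # pure red -> 76
#' @export
to_grayscale <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (is.array(frame) && length(dim(frame)) == 3L) {
    nc <- dim(frame)[3L]
    if (nc == 1L) return(array(frame, dim(frame)[1:2]))
    if (nc == 3L) {
      g <- 0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] + 0.114 * frame[, , 3L]
      return(array(round_half_up(g), dim(frame)[1:2]))
    }
  }
  stop_validation("unsupported channel layout")
}

#' Write a Z-stack as a TIFF image sequence
#'
#' Writes one uncompressed grayscale TIFF per optical section, named
#' `section_000.tif`, `section_001.tif`, ... so that file order equals section
#' order. Integer `ZStack`s round-trip bit-identically through
#' [load_stack()]. A `NormalizedZStack` is clipped to
#' `[0, 2^source_bit_depth - 1]` and rounded to the nearest integer before
#' writing, restoring the native dynamic range of the source acquisition.
#'
#' @param stack A `ZStack` or `NormalizedZStack`.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the character vector of files written, in section order.
#' @export
save_stack <- function(stack, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", directory)
  }
  bd <- bit_depth(stack)
  vmax <- 2^bd - 1
  arr <- unclass(stack)
  arr <- clip(round_half_up(arr), 0, vmax)
  z <- n_sections(stack)
  width <- max(3L, nchar(as.character(z - 1L)))
  paths <- file.path(directory, sprintf(paste0("section_%0", width, "d.tif"),
                                        seq_len(z) - 1L))
  for (i in seq_len(z)) {
    ok <- tiff::writeTIFF(arr[, , i] / vmax, paths[i],
                          bits.per.sample = bd, compression = "none")
    if (!isTRUE(ok == 1L)) stop("failed to write ", paths[i])
  }
  invisible(paths)
}
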