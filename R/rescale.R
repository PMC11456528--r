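# Optional post-normalization brightness/contrast adjustment. Dividing by the
# NS mean lowers pixel values; a linear transform maps a user-selected
# intensity window onto the full dynamic range to restore display contrast.

#' Compute linear brightness/contrast parameters for an intensity window
#'
#' The scale factor is `alpha = dtype_max / (user_max - user_min)` and the
#' offset is `beta = user_min * alpha`, so that `alpha * p - beta` maps
#' `user_min` to 0 and `user_max` to `dtype_max`.
#'
#' @param user_min,user_max Window bounds in native intensity units,
#'   `0 <= user_min < user_max <= dtype_max`.
#' @param dtype_max Top of the target dynamic range (255 or 65535).
#' @return An object of class `ScaleParams`.
#' @examples
#' compute_scale(50, 100, 255)  # alpha = 5.1, beta = 255
#' @export
compute_scale <- function(user_min, user_max, dtype_max = 255) {
  if (!dtype_max %in% c(255, 65535)) {
    stop_validation("dtype_max must be 255 or 65535")
  }
  if (anyNA(c(user_min, user_max)) || user_min >= user_max) {
    stop_validation("empty intensity window")
  }
  if (user_min < 0 || user_max > dtype_max) {
    stop_validation("window bounds outside [0, ", dtype_max, "]")
  }
  alpha <- dtype_max / (user_max - user_min)
  structure(list(alpha = alpha, beta = user_min * alpha,
                 user_min = user_min, user_max = user_max,
                 dtype_max = dtype_max),
            class = "ScaleParams")
}

#' @export
print.ScaleParams <- function(x, ...) {
  cat(sprintf(
    "ScaleParams: window [%g, %g] -> [0, %g]; alpha = %g, beta = %g\n",
    x$user_min, x$user_max, x$dtype_max, x$alpha, x$beta))
  invisible(x)
}

#' Apply a linear brightness/contrast transform to a stack
#'
#' Every pixel is mapped as `clip(round(alpha * p - beta), 0, dtype_max)`
#' (rounding half away from zero): the window minimum maps to 0, the window
#' maximum to `dtype_max`, and values outside the window saturate.
#'
#' @param stack A `ZStack` or `NormalizedZStack`.
#' @param params A [compute_scale()] object.
#' @return An integer-valued `ZStack` at the bit depth implied by
#'   `params$dtype_max`.
#' @export
apply_scale <- function(stack, params) {
  stopifnot(inherits(params, "ScaleParams"))
  arr <- unclass(stack)
  out <- clip(round_half_up(params$alpha * arr - params$beta),
              0, params$dtype_max)
  zstack(array(out, dim = dim(arr)),
         bit_depth = if (params$dtype_max == 255) 8L else 16L)
}

#' Per-section intensity summary to guide window selection
#'
#' Replaces an interactive reference-plane picker: prints the min, max and
#' selected percentiles of the in-threshold, non-zero pixels of every section
#' so a rescaling window can be chosen from the shell.
#'
#' @param stack A `ZStack` or `NormalizedZStack`.
#' @param probs Percentiles to report.
#' @param threshold A [threshold_range()].
#' @return A data.frame with one row per section.
#' @export
window_stats <- function(stack, probs = c(0.01, 0.5, 0.99),
                         threshold = default_threshold(stack)) {
  z <- n_sections(stack)
  rows <- lapply(seq_len(z), function(i) {
    sec <- get_section(stack, i)
    px <- sec[analysis_mask(sec, threshold)]
    if (length(px) == 0L) px <- NA_real_
    qs <- stats::quantile(px, probs, na.rm = TRUE, names = FALSE)
    c(section = i - 1L, n_pixels = sum(!is.na(px)),
      min = suppressWarnings(min(px)), stats::setNames(qs,
        sprintf("p%02d", round(probs * 100))),
      max = suppressWarnings(max(px)))
  })
  as.data.frame(do.call(rbind, rows))
}
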