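# Fixtures and independent brute-force oracles, built in code at test time.

rand_stack <- function(z = 3, h = 4, w = 4, bit_depth = 8, seed = 1,
                       min_val = 0) {
  set.seed(seed)
  vmax <- 2^bit_depth - 1
  zstack(array(sample(min_val:vmax, z * h * w, replace = TRUE),
               dim = c(h, w, z)),
         bit_depth = bit_depth)
}

uniform_stack <- function(values, h = 2, w = 2, bit_depth = 8) {
  zstack(lapply(values, function(v) matrix(v, h, w)), bit_depth = bit_depth)
}

# bare pixel array: drop class and metadata attributes, keep dim
px <- function(x) {
  a <- unclass(x)
  attributes(a) <- list(dim = dim(a))
  a
}

# --- brute-force per-pixel oracles (scalar loops, no vectorized reuse) ---

bf_masked_mean <- function(section, mask) {
  s <- 0; n <- 0
  for (i in seq_len(nrow(section))) {
    for (j in seq_len(ncol(section))) {
      if (mask[i, j]) { s <- s + section[i, j]; n <- n + 1 }
    }
  }
  s / n
}

bf_section_means <- function(ns) {
  vapply(seq_len(n_sections(ns)), function(z) {
    sec <- get_section(ns, z)
    bf_masked_mean(sec, sec != 0)
  }, numeric(1))
}

bf_ssin <- function(soi, means, lo, hi, rescale) {
  h <- stack_height(soi); w <- stack_width(soi); nz <- n_sections(soi)
  out <- array(0, dim = c(h, w, nz))
  mmax <- max(means)
  for (z in seq_len(nz)) {
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        p <- soi[i, j, z]
        if (p != 0 && p >= lo && p <= hi) {
          v <- p / means[z]
          out[i, j, z] <- if (rescale == "max_mean") v * mmax else v
        }
      }
    }
  }
  out
}

bf_projection <- function(stack, axis) {
  h <- stack_height(stack); w <- stack_width(stack); nz <- n_sections(stack)
  arr <- px(stack)
  if (axis == "z") {
    out <- matrix(0, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      out[i, j] <- sum(arr[i, j, ]) / nz
    }
  } else if (axis == "y") {
    out <- matrix(0, nz, w)
    for (z in seq_len(nz)) for (j in seq_len(w)) {
      out[z, j] <- sum(arr[, j, z]) / h
    }
  } else {
    out <- matrix(0, h, nz)
    for (i in seq_len(h)) for (z in seq_len(nz)) {
      out[i, z] <- sum(arr[i, , z]) / w
    }
  }
  out
}

bf_minmax <- function(img) {
  lo <- min(img); hi <- max(img)
  out <- img * 0
  if (hi > lo) {
    for (k in seq_along(img)) {
      out[k] <- floor((img[k] - lo) / (hi - lo) * 255 + 0.5)
    }
  }
  out
}

bf_apply_scale <- function(stack, alpha, beta, dtype_max) {
  arr <- px(stack)
  out <- arr * 0
  for (k in seq_along(arr)) {
    v <- floor(alpha * arr[k] - beta + 0.5)
    out[k] <- min(max(v, 0), dtype_max)
  }
  out
}
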