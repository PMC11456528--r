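# Section-specific intensity normalization: masks, section means, the
# pixel-wise division, and its defining invariants.

test_that("analysis_mask combines the threshold window with zero exclusion", {
  sec <- matrix(c(0, 20, 10, 30), 2, 2)   # [[0,10],[20,30]] row-major
  mask <- analysis_mask(sec, threshold_range(5, 25))
  expect_identical(mask, matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))

  no_zeros <- matrix(1:4, 2, 2)
  expect_true(all(analysis_mask(no_zeros, threshold_range(0, 255))))
  expect_false(any(analysis_mask(matrix(0, 3, 3), threshold_range(0, 255))))
})

test_that("masked_mean averages exactly the masked pixels", {
  sec <- matrix(c(0, 20, 10, 30), 2, 2)
  expect_equal(masked_mean(sec, analysis_mask(sec, threshold_range(5, 25))),
               15)
  u <- matrix(42, 3, 3)
  expect_equal(masked_mean(u, matrix(TRUE, 3, 3)), 42)
  expect_error(masked_mean(matrix(0, 2, 2), matrix(FALSE, 2, 2)),
               "no analyzable pixels")
})

test_that("section_means excludes zeros, scales linearly, flags empty sections", {
  ns <- uniform_stack(c(100, 50))
  expect_equal(as.numeric(section_means(ns)), c(100, 50))

  ns2 <- zstack(list(matrix(c(0, 8, 0, 4), 2, 2)), 8)
  expect_equal(as.numeric(section_means(ns2)), 6)       # (8+4)/2

  zs <- rand_stack(z = 3, h = 5, w = 5, seed = 9, min_val = 1)
  tripled <- zstack(px(zs) * 3, bit_depth = 16)
  expect_equal(as.numeric(section_means(tripled)),
               3 * as.numeric(section_means(zs)))

  bad <- zstack(list(matrix(5, 2, 2), matrix(0, 2, 2)), 8)
  expect_error(section_means(bad), "section 2")
})

test_that("ssin_normalize divides by the depth-matched NS mean", {
  soi <- uniform_stack(c(80, 40))
  ns <- uniform_stack(c(100, 50))
  thr <- threshold_range(0, 255)

  raw <- ssin_normalize(soi, section_means(ns), thr, rescale_mode = "none")
  expect_true(all(abs(px(raw) - 0.8) < 1e-15))

  exported <- ssin_normalize(soi, section_means(ns), thr,
                             rescale_mode = "max_mean")
  expect_true(all(abs(px(exported) - 80) < 1e-12))
  expect_s3_class(exported, "NormalizedZStack")
  expect_equal(bit_depth(exported), 8L)
})

test_that("a depth-flat NS changes nothing beyond thresholding", {
  soi <- rand_stack(z = 3, h = 4, w = 4, seed = 5)
  ns <- uniform_stack(c(60, 60, 60), h = 4, w = 4)
  thr <- threshold_range(10, 200)
  out <- ssin_normalize(soi, section_means(ns), thr)
  keep <- px(soi) >= 10 & px(soi) <= 200 & px(soi) != 0
  expect_equal(px(out), ifelse(keep, px(soi), 0))
})

test_that("ssin output is invariant to rescaling the NS channel", {
  soi <- rand_stack(z = 4, h = 5, w = 5, seed = 2)
  ns <- rand_stack(z = 4, h = 5, w = 5, seed = 3, min_val = 1)
  thr <- threshold_range(0, 255)
  base <- ssin_normalize(soi, section_means(ns), thr)
  scaled_ns <- zstack(px(ns) * 3, bit_depth = 16)
  rescaled <- ssin_normalize(soi, section_means(scaled_ns), thr)
  expect_equal(px(rescaled), px(base), tolerance = 1e-12)
})

test_that("proportional attenuation cancels exactly on continuous channels", {
  # both channels = depth-flat base * shared per-section factor a(z)
  set.seed(31)
  h <- 6; w <- 6; nz <- 5
  soi_base <- matrix(runif(h * w, 10, 200), h, w)
  ns_base <- matrix(runif(h * w, 20, 220), h, w)
  a <- exp(-0.3 * (seq_len(nz) - 1))
  soi <- zstack(array(outer(c(soi_base), a), c(h, w, nz)), 8)
  ns <- zstack(array(outer(c(ns_base), a), c(h, w, nz)), 8)
  out <- ssin_normalize(soi, section_means(ns), threshold_range(0, 255))
  sec_means <- vapply(seq_len(nz),
                      function(z) mean(get_section(out, z)), numeric(1))
  expect_true(all(abs(sec_means / sec_means[1] - 1) < 1e-9))
})

test_that("masked-out pixels are exactly zero and the map is local", {
  soi <- rand_stack(z = 3, h = 4, w = 4, seed = 8)
  ns <- rand_stack(z = 3, h = 4, w = 4, seed = 9, min_val = 1)
  thr <- threshold_range(30, 220)
  out <- ssin_normalize(soi, section_means(ns), thr)
  dropped <- px(soi) < 30 | px(soi) > 220 | px(soi) == 0
  expect_true(all(px(out)[dropped] == 0))

  # permuting pixels within a section permutes outputs identically
  perm <- sample(16)
  soi_p <- px(soi)
  for (z in 1:3) soi_p[, , z] <- array(soi_p[, , z][perm], c(4, 4))
  out_p <- ssin_normalize(zstack(soi_p, 8), section_means(ns), thr)
  for (z in 1:3) {
    expect_identical(c(px(out_p)[, , z]), c(px(out)[, , z])[perm])
  }
})

test_that("ssin_normalize matches a brute-force per-pixel loop exactly", {
  for (seed in 1:10) {
    soi <- rand_stack(z = 3, h = 4, w = 4, seed = seed)
    ns <- rand_stack(z = 3, h = 4, w = 4, seed = seed + 100, min_val = 1)
    means <- section_means(ns)
    expect_identical(as.numeric(bf_section_means(ns)), as.numeric(means))
    for (mode in c("max_mean", "none")) {
      got <- ssin_normalize(soi, means, threshold_range(20, 230), mode)
      want <- bf_ssin(soi, as.numeric(means), 20, 230, mode)
      expect_identical(px(got), want)
    }
  }
})

test_that("misaligned channel stacks are rejected", {
  soi <- uniform_stack(c(80, 40, 20))
  ns <- uniform_stack(c(100, 50))
  expect_error(ssin_normalize(soi, section_means(ns)),
               "channel stacks not aligned")
})
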