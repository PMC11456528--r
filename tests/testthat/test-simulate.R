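# Synthetic phantom generator: ground truth recovery, determinism, expected
# post-normalization profiles.

small_spec <- function(...) phantom_spec(shape = c(8, 32, 32), ...)

test_that("attenuation_model builds valid factor sequences", {
  m <- attenuation_model("exponential", 5, lambda = 0.2)
  expect_equal(m$factors, exp(-0.2 * (0:4)))
  expect_equal(m$factors[1], 1)

  m2 <- attenuation_model("exponential", 40, final_fraction = 0.3)
  expect_equal(m2$factors[40], 0.3)

  m3 <- attenuation_model("linear", 4, slope = 0.1)
  expect_equal(m3$factors, c(1, 0.9, 0.8, 0.7))

  expect_error(attenuation_model("linear", 20, slope = 0.1), "<= 0")
  expect_error(attenuation_model("custom", 3, factors = c(0.9, 1, 1)),
               "a\\(0\\) = 1")
})

test_that("identical seeds give bit-identical phantom pairs", {
  spec <- small_spec(noise_sd = 2, seed = 99)
  m <- attenuation_model("exponential", 8, final_fraction = 0.5)
  p1 <- generate_pair(spec, m)
  p2 <- generate_pair(spec, m)
  expect_identical(px(p1$ns), px(p2$ns))
  expect_identical(px(p1$soi), px(p2$soi))

  p3 <- generate_pair(small_spec(noise_sd = 2, seed = 100), m)
  expect_false(identical(px(p1$soi), px(p3$soi)))
})

test_that("generate_pair restores the caller's RNG state", {
  set.seed(5)
  before <- .Random.seed
  generate_pair(small_spec(noise_sd = 1, seed = 77),
                attenuation_model("exponential", 8, lambda = 0.1))
  expect_identical(.Random.seed, before)
})

test_that("noise-free NS depth profile recovers the attenuation factors", {
  m <- attenuation_model("exponential", 8, final_fraction = 0.4)
  pair <- generate_pair(small_spec(quantize = FALSE, seed = 2), m)
  prof <- depth_profile(pair$ns)
  expect_equal(prof$percent, m$factors / max(m$factors) * 100,
               tolerance = 1e-12)
  # quantized acquisition recovers it to within rounding (percent points)
  pair_q <- generate_pair(small_spec(seed = 2), m)
  expect_lt(max(abs(depth_profile(pair_q$ns)$percent - m$factors * 100)), 0.5)
})

test_that("lambda = 0 gives depth-flat channels and SsIN is a no-op", {
  m <- attenuation_model("exponential", 8, lambda = 0)
  pair <- generate_pair(small_spec(seed = 3), m)
  expect_true(all(depth_profile(pair$soi)$percent == 100))
  out <- ssin_normalize(pair$soi, section_means(pair$ns))
  expect_equal(px(out), px(pair$soi), tolerance = 1e-12)
})

test_that("expected_flat_profile is all-100 for a noise-free uniform SOI", {
  m <- attenuation_model("exponential", 8, final_fraction = 0.3)
  pair <- generate_pair(small_spec(quantize = FALSE, noise_sd = 0, seed = 4), m)
  ef <- expected_flat_profile(pair$truth)
  expect_equal(ef$percent, rep(100, 8))
  expect_equal(ef$tol, 0)

  post <- depth_profile(ssin_normalize(pair$soi, section_means(pair$ns)))
  expect_equal(post$percent, ef$percent, tolerance = 1e-9)
})

test_that("expected_flat_profile tracks shell occupancy for top-shell SOIs", {
  spec <- small_spec(soi_pattern = "top_shell", quantize = FALSE, seed = 5)
  m <- attenuation_model("exponential", 8, final_fraction = 0.3)
  pair <- generate_pair(spec, m)
  ef <- expected_flat_profile(pair$truth)
  # cap sections carry full intensity, deeper ones only the ring + floor
  expect_true(all(ef$percent[1:3] == 100))
  expect_true(all(ef$percent[4:8] < 100))
  post <- depth_profile(ssin_normalize(pair$soi, section_means(pair$ns)))
  expect_equal(post$percent, ef$percent, tolerance = 1e-9)
})

test_that("noisy end-to-end runs stay within the SEM-derived band", {
  m <- attenuation_model("exponential", 10, final_fraction = 0.3)
  spec <- phantom_spec(shape = c(10, 64, 64), noise_sd = 2, seed = 8)
  pair <- generate_pair(spec, m)
  ef <- expected_flat_profile(pair$truth)
  expect_gt(ef$tol, 0)
  post <- depth_profile(ssin_normalize(pair$soi, section_means(pair$ns)))
  expect_true(all(abs(post$percent - ef$percent) < 3 * ef$tol))
})

test_that("phantom validation rejects degenerate shapes", {
  expect_error(phantom_spec(shape = c(4, 2, 64)), "at least 8x8")
  expect_error(phantom_spec(shape = c(0, 32, 32)), "positive")
  expect_error(generate_pair(small_spec(),
                             attenuation_model("exponential", 5,
                                               lambda = 0.1)),
               "disagree")
})
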