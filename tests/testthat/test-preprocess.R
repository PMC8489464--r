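test_that("resampling reaches the target spacing with round-half-to-even sizes", {
  img <- image2d(matrix(runif(200 * 200), 200), spacing = 2)
  out <- resample_to_spacing(img, 1)
  expect_equal(dim(out$pixels), c(400L, 400L))
  expect_equal(out$spacing, 1)

  same <- resample_to_spacing(image2d(matrix(0, 400, 400), 1), 1)
  expect_equal(dim(same$pixels), c(400L, 400L))

  odd <- resample_to_spacing(image2d(matrix(0, 300, 256), 1.4), 1)
  expect_equal(dim(odd$pixels), c(420L, 358L))
  expect_error(resample_to_spacing(img, 0), "positive")
})

test_that("resampling preserves intensities for integer upscale and maps coordinates by the scale factor", {
  set.seed(30)
  img <- image2d(matrix(runif(50 * 50), 50), spacing = 2)
  out <- resample_to_spacing(img, 1)
  m <- cardiomark:::coord_map_of(out)
  # a pixel centre maps to twice its coordinate, and the warped image
  # carries the source intensity there
  expect_equal(apply_map(m, cbind(10, 20)), cbind(20, 40))
  expect_equal(out$pixels[21, 41], img$pixels[11, 21], tolerance = 1e-12)
})

test_that("pad_or_crop centres content with the documented margins", {
  id <- pad_or_crop(image2d(matrix(1, 400, 400), 1), c(400, 400))
  expect_equal(dim(id$pixels), c(400L, 400L))
  expect_true(all(id$pixels == 1))

  small <- pad_or_crop(image2d(matrix(1, 100, 100), 1), c(400, 400))
  expect_equal(dim(small$pixels), c(400L, 400L))
  filled <- which(small$pixels == 1, arr.ind = TRUE)
  expect_equal(range(filled[, 1]), c(151L, 250L))  # rows 150..249, 0-based
  expect_equal(range(filled[, 2]), c(151L, 250L))
  expect_equal(sum(small$pixels), 100 * 100)

  # 420 x 358: rows cropped 10 per side, cols padded 21 per side
  big <- image2d(matrix(seq_len(420 * 358), 420, 358), 1)
  out <- pad_or_crop(big, c(400, 400))
  expect_equal(dim(out$pixels), c(400L, 400L))
  m <- cardiomark:::coord_map_of(out)
  expect_equal(apply_map(m, cbind(10, 0)), cbind(0, 21))
  expect_equal(out$pixels[1, 22], big$pixels[11, 1])
})

test_that("bias-field estimation recovers smooth shading and is floored", {
  const <- estimate_bias_field(matrix(5, 64, 64))
  expect_true(all(const == 1))

  set.seed(31)
  ramp <- outer(seq(0.4, 1, length.out = 96), rep(1, 96))
  flat <- matrix(1, 96, 96)
  field <- estimate_bias_field(flat * ramp, scale = 1 / 4)
  rel <- abs(field / max(field) - ramp / max(ramp)) / (ramp / max(ramp))
  # compare away from the borders where replication bias concentrates
  expect_lt(max(rel[17:80, 17:80]), 0.1)

  spiky <- matrix(1e-9, 32, 32); spiky[16, 16] <- 1
  expect_gte(min(estimate_bias_field(spiky, intensity_floor = 1e-3)), 1e-3)
})

test_that("inhomogeneity correction divides out the field and preserves the mean", {
  set.seed(32)
  img <- image2d(matrix(runif(64 * 64, 0.2, 1), 64), 1)
  flat <- correct_inhomogeneity(img, matrix(1, 64, 64))
  expect_equal(flat$pixels, img$pixels, tolerance = 1e-12)

  f <- estimate_bias_field(img)
  out <- correct_inhomogeneity(img, f)
  expect_lt(abs(mean(out$pixels) - mean(img$pixels)) / mean(img$pixels),
            1e-6)
  expect_error(correct_inhomogeneity(img, matrix(1, 32, 32)), "shape")
  expect_error(correct_inhomogeneity(img, matrix(-1, 64, 64)), "positive")
})

test_that("correction removes phantom shading: background CV drops by at least half", {
  set.seed(33)
  base <- matrix(0.6, 96, 96)
  sh <- apply_shading(image2d(base, 1), 0.5)
  cv <- function(x) sd(x) / mean(x)
  corrected <- correct_inhomogeneity(sh, estimate_bias_field(sh))
  expect_lt(cv(corrected$pixels), 0.5 * cv(sh$pixels))
})

test_that("double correction is idempotent within 1%", {
  set.seed(34)
  s <- generate_short_axis(phantom_config(noise_sd = 0.01,
                                          shading_amplitude = 0.4,
                                          prob_no_landmark_frame = 0))
  once <- correct_inhomogeneity(s$image, estimate_bias_field(s$image))
  twice <- correct_inhomogeneity(once, estimate_bias_field(once))
  expect_lt(max(abs(twice$pixels - once$pixels)) /
              diff(range(once$pixels)), 0.01)
})

test_that("identity augmentation parameters leave the sample unchanged", {
  set.seed(35)
  s <- generate_short_axis(phantom_config(prob_no_landmark_frame = 0))
  cfg <- preprocess_config(p_use_original = 1)
  out <- augment(s$image, s$landmarks, cfg, theta_deg = 0, scale = 1,
                 translate = c(0, 0), gamma = 1)
  expect_equal(out$image$pixels, s$image$pixels, tolerance = 1e-12)
  expect_equal(out$landmarks$coords, s$landmarks$coords)
  expect_identical(out$landmarks$present, s$landmarks$present)
})

test_that("a 90-degree rotation moves landmarks by the closed-form rule", {
  img <- image2d(matrix(0, 400, 400), 1)
  lms <- landmark_set("SAX", rbind(c(100, 100), c(50, 300), c(200, 200)),
                      present = rep(TRUE, 3))
  out <- augment(img, lms, preprocess_config(p_use_original = 1),
                 theta_deg = 90, scale = 1, translate = c(0, 0), gamma = 1)
  expect_equal(unname(out$landmarks$coords[1, ]), c(100, 299))
  # brute-force check of the map on a grid of points
  ctr <- c(199.5, 199.5)
  pts <- cbind(runif(20, 0, 399), runif(20, 0, 399))
  expected <- t(apply(pts, 1, function(p) {
    d <- p - ctr
    ctr + c(d[2], -d[1])
  }))
  expect_equal(apply_map(out$map, pts), expected, tolerance = 1e-9)
})

test_that("augmentation with a fixed seed is reproducible and flags out-of-bounds landmarks absent", {
  s <- generate_short_axis(phantom_config(prob_no_landmark_frame = 0,
                                          seed = 77))
  set.seed(55)
  a <- augment(s$image, s$landmarks)
  set.seed(55)
  b <- augment(s$image, s$landmarks)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$landmarks, b$landmarks)

  pushed <- augment(s$image, s$landmarks,
                    preprocess_config(p_use_original = 1),
                    theta_deg = 0, scale = 1, translate = c(80, 80),
                    gamma = 1)
  expect_true(any(!pushed$landmarks$present))
})

test_that("resample and pad/crop coordinate maps compose with detection", {
  # a synthetic exact peak: encode on the source grid, transform, and
  # check that decoding the transformed heatmap matches transforming
  # the decoded coordinates
  lms <- landmark_set("SAX", rbind(c(30, 40), c(50, 20), c(40, 42)),
                      present = rep(TRUE, 3))
  src <- image2d(encode_heatmap(lms, c(80, 80), 3)[, , 2], spacing = 2)
  rs <- resample_to_spacing(src, 1)
  pc <- pad_or_crop(rs, c(192, 192))
  m <- compose_maps(cardiomark:::coord_map_of(pc),
                    cardiomark:::coord_map_of(rs))
  peak <- which(pc$pixels == max(pc$pixels), arr.ind = TRUE) - 1L
  expected <- apply_map(m, lms$coords[1, , drop = FALSE])
  expect_lt(sqrt(sum((peak[1, ] - expected)^2)), 1)
})

test_that("intensity normalisation maps the robust window onto [0, 1]", {
  set.seed(36)
  px <- matrix(rnorm(96 * 96, 100, 20), 96)
  nm <- normalize_intensity(px)
  expect_gte(min(nm), 0); expect_lte(max(nm), 1)
  expect_true(all(normalize_intensity(matrix(3, 10, 10)) == 0))
})
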