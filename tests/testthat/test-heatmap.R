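test_that("encoding gives a valid per-pixel distribution with the exact Gaussian profile", {
  lms <- landmark_set("SAX", rbind(c(50, 50), c(20, 70), c(48, 48)),
                      present = c(TRUE, TRUE, TRUE))
  hm <- encode_heatmap(lms, c(96, 96), sigma = 4)
  expect_equal(dim(hm), c(96, 96, 4))
  sums <- apply(hm, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_true(all(hm >= 0))

  # pre-normalisation Gaussian value at 1 sigma from an isolated peak:
  # exp(-0.5).  Compare via the ratio to the peak pixel, which the
  # per-pixel normalisation must preserve where background dominates.
  lone <- landmark_set("SAX", rbind(c(50, 50), NA, NA),
                      present = c(TRUE, FALSE, FALSE))
  hml <- encode_heatmap(lone, c(96, 96), sigma = 4)
  g <- function(r, c) exp(-((r - 50)^2 + (c - 50)^2) / (2 * 4^2))
  # reconstruct pre-normalisation value: channel / (its per-pixel sum
  # before normalisation) is what encode stores; at (50, 54) the only
  # mass is this landmark + background (sums to 1), so value = g
  expect_equal(hml[51, 55, 2], g(50, 54), tolerance = 1e-12)
  expect_equal(g(50, 54), exp(-0.5), tolerance = 1e-12)
  # peak is at the landmark pixel
  idx <- which(hml[, , 2] == max(hml[, , 2]), arr.ind = TRUE)
  expect_equal(unname(idx[1, ]), c(51, 51))
})

test_that("empty landmark sets encode to pure background", {
  hm <- encode_heatmap(landmark_set("SAX"), c(64, 64), sigma = 4)
  expect_true(all(hm[, , 1] == 1))
  expect_true(all(hm[, , 2:4] == 0))
})

test_that("encoding rejects present landmarks outside the image", {
  bad <- landmark_set("SAX", rbind(c(200, 10), c(5, 5), c(9, 9)),
                      present = rep(TRUE, 3))
  expect_error(encode_heatmap(bad, c(96, 96)), "outside")
})

test_that("decode(encode(.)) recovers random landmark sets within 1 px for sigma 2, 4, 6", {
  set.seed(11)
  for (sigma in c(2, 4, 6)) {
    dc <- decode_config(subpixel_window = 2 * sigma)
    for (i in 1:25) {
      view <- sample(c("SAX", "CH2", "CH3", "CH4"), 1)
      lms <- random_landmark_set(view)
      # random absences must be reproduced exactly
      lms$present <- runif(3) < 0.8
      hm <- encode_heatmap(lms, c(96, 96), sigma)
      det <- decode_heatmap(hm, dc, view = view)
      expect_identical(det$present, lms$present)
      if (any(lms$present)) {
        err <- sqrt(rowSums((det$coords[lms$present, , drop = FALSE] -
                               lms$coords[lms$present, , drop = FALSE])^2))
        expect_lt(max(err), 1)
      }
    }
  }
})

test_that("uniform predictions decode to all-absent at tau = 0.5", {
  probs <- array(1 / 4, c(32, 32, 4))
  det <- decode_heatmap(probs, decode_config(), view = "SAX")
  expect_false(any(det$present))
})

test_that("equal peaks break ties towards the smallest row-major index", {
  probs <- array(0, c(32, 32, 4))
  probs[, , 1] <- 1
  ch <- matrix(0, 32, 32)
  ch[11, 11] <- 0.9; ch[21, 21] <- 0.9   # (10,10) and (20,20), 0-based
  probs[, , 2] <- ch
  probs[, , 1] <- 1 - apply(probs[, , 2:4], c(1, 2), sum)
  det <- decode_heatmap(probs, decode_config(subpixel_window = 0),
                        view = "SAX")
  expect_true(det$present[1])
  expect_equal(unname(det$coords[1, ]), c(10, 10))
})

test_that("encode is translation-equivariant away from borders", {
  set.seed(5)
  base <- landmark_set("SAX", rbind(c(40, 40), c(30, 60), c(50, 52)),
                       present = rep(TRUE, 3))
  hm <- encode_heatmap(base, c(96, 96), 4)
  shift <- landmark_set("SAX", base$coords + matrix(c(7, -5), 3, 2,
                                                    byrow = TRUE),
                        present = rep(TRUE, 3))
  hms <- encode_heatmap(shift, c(96, 96), 4)
  # compare on an interior window
  expect_equal(hms[(20:80) + 7, (20:80) - 5, 2], hm[20:80, 20:80, 2],
               tolerance = 1e-9)
})

test_that("all-background encodings decode with zero spurious detections", {
  hm <- encode_heatmap(landmark_set("SAX"), c(96, 96), 4)
  det <- decode_heatmap(hm, decode_config(), view = "SAX")
  ce <- count_errors(det, landmark_set("SAX"))
  expect_identical(ce$spurious, 0L)
  expect_true(ce$all_detected)
})

test_that("count_errors tallies missed and spurious landmarks", {
  truth <- random_landmark_set("SAX")
  perfect <- decode_heatmap(encode_heatmap(truth, c(96, 96), 4),
                            decode_config(), view = "SAX")
  expect_equal(count_errors(perfect, truth),
               list(missed = 0L, spurious = 0L, all_detected = TRUE))

  two <- perfect; two$present[2] <- FALSE
  expect_equal(count_errors(two, truth)$missed, 1L)
  expect_false(count_errors(two, truth)$all_detected)

  empty_truth <- landmark_set("SAX")
  one <- perfect; one$present <- c(TRUE, FALSE, FALSE)
  ce <- count_errors(one, empty_truth)
  expect_equal(ce$spurious, 1L)
  expect_true(ce$all_detected)  # vacuously: nothing to find

  ch2 <- random_landmark_set("CH2")
  expect_error(count_errors(perfect, ch2), "view mismatch")
})
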