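test_that("generation is bit-identical under a fixed seed", {
  cfg <- phantom_config(seed = 123)
  a <- generate_short_axis(cfg)
  b <- generate_short_axis(cfg)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$landmarks, b$landmarks)

  cfgl <- phantom_config(view = "CH3", seed = 99)
  expect_identical(generate_long_axis(cfgl)$image$pixels,
                   generate_long_axis(cfgl)$image$pixels)

  expect_identical(
    lapply(phantom_dataset(5, phantom_config(), seed = 4),
           function(s) s$image$pixels),
    lapply(phantom_dataset(5, phantom_config(), seed = 4),
           function(s) s$image$pixels))
})

test_that("views are validated", {
  expect_error(generate_long_axis(phantom_config(view = "SAX")), "view")
  expect_error(generate_short_axis(phantom_config(view = "CH2")), "SAX")
  expect_error(phantom_config(view = "XX"), "invalid view")
})

test_that("present landmarks always lie strictly inside image bounds", {
  set.seed(20)
  cfg <- phantom_config()
  cfgl <- phantom_config(view = "CH4")
  for (i in 1:200) {
    s <- if (i %% 2) generate_short_axis(cfg) else generate_long_axis(cfgl)
    if (any(s$landmarks$present)) {
      co <- s$landmarks$coords[s$landmarks$present, , drop = FALSE]
      expect_true(all(co[, 1] > 0 & co[, 1] < 95 &
                        co[, 2] > 0 & co[, 2] < 95))
    }
  }
})

test_that("emitted long-axis landmarks reproduce the sampled LV length", {
  set.seed(21)
  cfg <- exact_config("CH2")
  for (i in 1:30) {
    s <- generate_long_axis(cfg)
    lms <- s$landmarks
    L <- lv_length(lms$coords[3, ], lms$coords[1, ], lms$coords[2, ],
                   s$image$spacing)
    expect_lt(abs(L - s$geom$L_mm), 1)
  }
})

test_that("short-axis geometry is self-consistent", {
  set.seed(22)
  cfg <- exact_config("SAX")
  for (i in 1:30) {
    s <- generate_short_axis(cfg)
    # C-LV equals the annulus centre used to draw the image
    expect_lt(max(abs(s$landmarks$coords[3, ] - s$geom$center)), 1)
    # insertion points are distinct, at least a wall thickness apart
    sep <- sqrt(sum((s$landmarks$coords[1, ] - s$landmarks$coords[2, ])^2))
    expect_gte(sep, s$geom$t_px)
    # both lie on the epicardial contour
    for (k in 1:2)
      expect_lt(abs(sqrt(sum((s$landmarks$coords[k, ] -
                                s$geom$center)^2)) - s$geom$R_px), 1)
  }
})

test_that("prob_no_landmark_frame = 1 forces landmark-free frames", {
  set.seed(23)
  cfg <- phantom_config(prob_no_landmark_frame = 1)
  for (i in 1:10) {
    s <- generate_short_axis(cfg)
    expect_false(any(s$landmarks$present))
  }
})

test_that("landmark-free frames occur at the configured rate", {
  set.seed(24)
  cfg <- phantom_config(prob_no_landmark_frame = 0.2, noise_sd = 0,
                        shading_amplitude = 0)
  n_empty <- sum(vapply(seq_len(500), function(i)
    !any(generate_short_axis(cfg)$landmarks$present), logical(1)))
  expect_gte(n_empty / 500, 0.15)
  expect_lte(n_empty / 500, 0.25)
})

test_that("cine series contract to (1 - f) of end-diastolic length and close the cycle", {
  set.seed(25)
  cfg <- exact_config("CH2")
  series <- generate_cine_series(cfg, n_phases = 30, contraction_fraction = 0.2)
  expect_length(series, 30)
  L <- vapply(series, function(s) s$geom$L_mm, numeric(1))
  expect_equal(min(L), 0.8 * L[1], tolerance = 1e-12)
  expect_equal(which.min(L), 16)           # mid-series end systole
  expect_lt(abs(L[30] - L[1]) / L[1], 0.01)
  # per-phase ground truth matches each frame's geometry
  for (ph in c(1, 8, 16, 30)) {
    lms <- series[[ph]]$landmarks
    expect_lt(abs(lv_length(lms$coords[3, ], lms$coords[1, ],
                            lms$coords[2, ]) - L[ph]), 1)
  }
  expect_error(generate_cine_series(cfg, n_phases = 1), "n_phases")
  expect_error(generate_cine_series(phantom_config(), 30), "long-axis")
})

test_that("shading is bounded, smooth and disabled at amplitude 0", {
  set.seed(26)
  img <- image2d(matrix(runif(96 * 96, 0.5, 1), 96), 1)
  same <- apply_shading(img, 0)
  expect_identical(same$pixels, img$pixels)

  sh <- apply_shading(img, 0.5)
  ratio <- sh$pixels / img$pixels
  expect_gte(min(ratio), 0.5)
  expect_lte(max(ratio), 1 + 1e-12)

  # the field varies only at coarse scales: autocorrelation at a lag of
  # a quarter extent stays high
  f <- attr(sh, "field")
  lag <- 24
  cc <- cor(as.vector(f[1:(96 - lag), ]), as.vector(f[(lag + 1):96, ]))
  expect_gt(cc, 0.3)
  expect_error(apply_shading(img, 1), "amplitude")
})
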