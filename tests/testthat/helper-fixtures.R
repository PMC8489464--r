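# Shared fixtures.  Everything is generated in code; sizes are kept
# small so the unit suite stays fast.

# quiet phantom config for exact-geometry tests (no annotation jitter)
exact_config <- function(view = "SAX", ...) {
  phantom_config(view = view, landmark_jitter_sd = 0, noise_sd = 0,
                 shading_amplitude = 0, prob_no_landmark_frame = 0, ...)
}

# a random landmark set with all points well inside the grid and, as
# in real anatomy, clearly separated from one another
random_landmark_set <- function(view = "SAX", shape = c(96, 96),
                                margin = 12, min_sep = NULL) {
  if (is.null(min_sep))
    min_sep <- min(16, 0.55 * (min(shape) - 1 - 2 * margin))
  repeat {
    co <- cbind(runif(3, margin, shape[1] - 1 - margin),
                runif(3, margin, shape[2] - 1 - margin))
    if (min(dist(co)) >= min_sep) break
  }
  landmark_set(view, co, present = rep(TRUE, 3))
}

# tiny network for fast training-loop tests
tiny_model <- function(size = 32L) {
  model_config(n_levels = 2L, blocks_per_level = 1L, decoder_blocks = 1L,
               base_channels = 4L, input_size = c(size, size))
}

tiny_samples <- function(n, size = 32L, seed = 1L, view = "SAX") {
  cfg <- phantom_config(image_size = c(size, size), view = view,
                        lv_length_range = c(14, 20),
                        lv_radius_range = c(4, 6),
                        wall_thickness_range = c(2, 3),
                        prob_no_landmark_frame = 0)
  phantom_dataset(n, cfg, seed = seed)
}
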