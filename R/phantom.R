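#' Synthetic cardiac phantom configuration
#'
#' Controls the geometry and appearance of generated phantom images.
#' Defaults produce 96 x 96 images at 1 mm spacing: a desk-scale grid
#' on which the whole training pipeline runs in minutes while keeping
#' the anatomy (ventricle silhouettes, annulus + RV crescent, coil
#' shading, noise) proportionally realistic.  All ranges are sampled
#' uniformly per sample.
#'
#' @param image_size Pixels (rows, cols), each >= 32.
#' @param pixel_spacing mm per pixel (isotropic).
#' @param view One of "CH2", "CH3", "CH4" (long axis) or "SAX".
#' @param lv_length_range LV length (apex to mid-base) range, mm.
#' @param lv_radius_range LV radius range, mm: the silhouette half-width
#'   on long-axis views, the epicardial (outer) radius on short axis.
#' @param wall_thickness_range Myocardial wall thickness range, mm.
#' @param rv_crescent Draw the right-ventricular crescent on short-axis
#'   images.
#' @param shading_amplitude Multiplicative surface-coil shading depth in
#'   [0, 1): the shading field spans [1 - amplitude, 1].
#' @param noise_sd Noise standard deviation as a fraction of the unit
#'   dynamic range (Rician-style magnitude noise).
#' @param landmark_jitter_sd Annotation jitter added to emitted landmark
#'   coordinates, pixels (emulates interreader variability).
#' @param prob_no_landmark_frame Probability that a short-axis sample is
#'   a landmark-free frame (background texture only), as happens beyond
#'   the apical cap of a short-axis stack.
#' @param seed Optional integer; when set, each generator call seeds the
#'   RNG with it (identical calls then reproduce bit-identical samples).
#' @return An object of class \code{phantom_config}.
#' @export
phantom_config <- function(image_size = c(96L, 96L), pixel_spacing = 1,
                           view = "SAX", lv_length_range = c(45, 65),
                           lv_radius_range = c(10, 16),
                           wall_thickness_range = c(5, 8),
                           rv_crescent = TRUE, shading_amplitude = 0.3,
                           noise_sd = 0.03, landmark_jitter_sd = 0.5,
                           prob_no_landmark_frame = 0.1, seed = NULL) {
  image_size <- as.integer(rep(image_size, length.out = 2L))
  if (any(image_size < 32L)) stop("image_size must be >= 32 per dimension")
  chk_range <- function(r, nm) {
    if (length(r) != 2L || r[1] > r[2] || any(r <= 0))
      stop(nm, " must be a positive (min, max) range")
    as.numeric(r)
  }
  if (!view %in% c(.LONG_AXIS_VIEWS, "SAX")) stop("invalid view: ", view)
  if (shading_amplitude < 0 || shading_amplitude >= 1)
    stop("shading_amplitude must be in [0, 1)")
  if (prob_no_landmark_frame < 0 || prob_no_landmark_frame > 1)
    stop("prob_no_landmark_frame must be a probability")
  structure(list(image_size = image_size,
                 pixel_spacing = as.numeric(pixel_spacing), view = view,
                 lv_length_range = chk_range(lv_length_range, "lv_length_range"),
                 lv_radius_range = chk_range(lv_radius_range, "lv_radius_range"),
                 wall_thickness_range = chk_range(wall_thickness_range,
                                                  "wall_thickness_range"),
                 rv_crescent = isTRUE(rv_crescent),
                 shading_amplitude = shading_amplitude,
                 noise_sd = as.numeric(noise_sd),
                 landmark_jitter_sd = as.numeric(landmark_jitter_sd),
                 prob_no_landmark_frame = prob_no_landmark_frame,
                 seed = seed),
            class = "phantom_config")
}

# ----------------------------------------------------------------------
# internals

.pixel_grid <- function(H, W) {
  list(r = matrix(0:(H - 1), H, W), c = matrix(0:(W - 1), H, W, byrow = TRUE))
}

.smooth_mask <- function(mask, sigma = 1.2) {
  .gblur_safe(mask, sigma = sigma)
}

# magnitude (Rician-style) noise on a roughly unit-range image
.add_noise <- function(px, sd) {
  if (sd <= 0) return(px)
  n1 <- matrix(rnorm(length(px), sd = sd), nrow(px))
  n2 <- matrix(rnorm(length(px), sd = sd), nrow(px))
  sqrt((px + n1)^2 + n2^2)
}

.jitter_clamp <- function(coords, sd, H, W) {
  if (sd > 0) coords <- coords + matrix(rnorm(length(coords), sd = sd),
                                        ncol = 2L)
  coords[, 1] <- pmin(pmax(coords[, 1], 0.01), H - 1.01)
  coords[, 2] <- pmin(pmax(coords[, 2], 0.01), W - 1.01)
  coords
}

.runif1 <- function(range) runif(1, range[1], range[2])

.phantom_sample <- function(image, landmarks, view, id, patient_id, geom) {
  structure(list(image = image, landmarks = landmarks, view = view,
                 id = id, patient_id = patient_id, geom = geom),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat("phantom_sample", x$id %||% "", "(", x$view, "),",
      sum(x$landmarks$present), "landmarks present\n")
  invisible(x)
}

# ----------------------------------------------------------------------

#' Apply multiplicative low-frequency shading
#'
#' Emulates surface-coil receive-sensitivity shading: the image is
#' multiplied by a smooth random field with values in
#' [1 - amplitude, 1] that varies only at spatial scales of about a
#' quarter of the image extent and larger.
#'
#' @param image An [image2d()] (or plain matrix).
#' @param amplitude Shading depth in [0, 1); 0 returns the input
#'   unchanged.
#' @return The shaded [image2d()]; the field used is attached as
#'   attribute \code{"field"}.
#' @export
apply_shading <- function(image, amplitude) {
  img <- as_image2d(image)
  if (amplitude < 0 || amplitude >= 1) stop("amplitude must be in [0, 1)")
  H <- nrow(img$pixels); W <- ncol(img$pixels)
  if (amplitude == 0) {
    attr(img, "field") <- matrix(1, H, W)
    return(img)
  }
  raw <- matrix(rnorm(H * W), H, W)
  sm <- .gblur_safe(raw, sigma = mean(c(H, W)) / 4)
  sm <- (sm - min(sm)) / (max(sm) - min(sm))      # exactly [0, 1]
  field <- 1 - amplitude * sm                      # exactly [1 - a, 1]
  out <- image2d(img$pixels * field, img$spacing, id = img$meta$id,
                 view = img$meta$view)
  attr(out, "field") <- field
  out
}

.finish_image <- function(px, config, id, view) {
  img <- image2d(px, config$pixel_spacing, id = id, view = view)
  img <- apply_shading(img, config$shading_amplitude)
  img$pixels <- .add_noise(img$pixels, config$noise_sd)
  img
}

# shared long-axis renderer so cine series reuse one sampled geometry
.render_long_axis <- function(config, geom, id) {
  H <- config$image_size[1]; W <- config$image_size[2]
  g <- .pixel_grid(H, W)
  u <- c(cos(geom$theta), sin(geom$theta))
  v <- c(-sin(geom$theta), cos(geom$theta))
  pr <- (g$r - geom$center[1]) * u[1] + (g$c - geom$center[2]) * u[2]
  pp <- (g$r - geom$center[1]) * v[1] + (g$c - geom$center[2]) * v[2]
  A <- geom$A_px; r <- geom$r_px
  mask <- ((pr / A)^2 + (pp / r)^2 <= 1) & (pr >= -0.8 * A)
  px <- 0.12 + 0.83 * .smooth_mask(mask * 1.0)
  img <- .finish_image(px, config, id, config$view)

  apex <- geom$center + A * u
  base_mid <- geom$center - 0.8 * A * u
  half_w <- 0.6 * r
  valve_a <- base_mid + half_w * v
  valve_b <- base_mid - half_w * v
  truth <- rbind(valve_a, valve_b, apex)
  coords <- .jitter_clamp(truth, config$landmark_jitter_sd, H, W)
  lms <- landmark_set(config$view, coords, present = rep(TRUE, 3L))
  geom$apex <- apex; geom$base_mid <- base_mid
  geom$valve_a <- valve_a; geom$valve_b <- valve_b
  list(image = img, landmarks = lms, geom = geom)
}

.sample_long_axis_geom <- function(config) {
  H <- config$image_size[1]; W <- config$image_size[2]
  sp <- config$pixel_spacing
  L_mm <- .runif1(config$lv_length_range)
  r_mm <- .runif1(config$lv_radius_range)
  list(L_mm = L_mm,
       A_px = (L_mm / sp) / 1.8,        # ellipse semi-major; base plane at -0.8 A
       r_px = r_mm / sp,
       center = c((H - 1) / 2, (W - 1) / 2) + rnorm(2, sd = 2),
       theta = runif(1, 0, 2 * pi))
}

#' Generate a long-axis phantom sample
#'
#' Draws a bright elongated ventricle silhouette (an ellipse truncated
#' at the base plane) at random orientation, with the two valve points
#' flanking the base and the apex at the opposite pole.  The emitted
#' landmark coordinates carry annotation jitter
#' (\code{landmark_jitter_sd}); the exact sampled geometry is kept in
#' the \code{geom} field.
#'
#' @param config A [phantom_config()] with a long-axis \code{view}.
#' @param id Optional sample id.
#' @param patient_id Optional patient id (for patient-wise splitting).
#' @return A \code{phantom_sample}: \code{image}, \code{landmarks},
#'   \code{view}, \code{geom}.
#' @export
generate_long_axis <- function(config, id = NULL, patient_id = NULL) {
  if (!config$view %in% .LONG_AXIS_VIEWS)
    stop("config$view must be CH2, CH3 or CH4 for long-axis phantoms")
  if (!is.null(config$seed)) set.seed(config$seed)
  geom <- .sample_long_axis_geom(config)
  r <- .render_long_axis(config, geom, id)
  .phantom_sample(r$image, r$landmarks, config$view, id, patient_id, r$geom)
}

#' Generate a short-axis phantom sample
#'
#' Draws the LV as a bright blood pool inside a darker myocardial
#' annulus, with a right-ventricular crescent attached; the RV
#' insertion points are the exact circle-intersection junctions of the
#' crescent with the epicardial contour and C-LV is the annulus centre.
#' With probability \code{prob_no_landmark_frame} the sample is a
#' landmark-free frame of plain background texture.
#'
#' @inheritParams generate_long_axis
#' @param config A [phantom_config()] with \code{view = "SAX"}.
#' @export
generate_short_axis <- function(config, id = NULL, patient_id = NULL) {
  if (config$view != "SAX") stop("config$view must be SAX")
  if (!is.null(config$seed)) set.seed(config$seed)
  H <- config$image_size[1]; W <- config$image_size[2]
  sp <- config$pixel_spacing

  if (runif(1) < config$prob_no_landmark_frame) {
    img <- .finish_image(matrix(0.15, H, W), config, id, "SAX")
    lms <- landmark_set("SAX")  # all absent
    return(.phantom_sample(img, lms, "SAX", id, patient_id,
                           list(no_landmarks = TRUE)))
  }

  ctr <- c((H - 1) / 2, (W - 1) / 2) + rnorm(2, sd = 2)
  R <- .runif1(config$lv_radius_range) / sp       # epicardial radius, px
  t <- .runif1(config$wall_thickness_range) / sp  # wall thickness, px
  phi0 <- runif(1, 0, 2 * pi)
  D <- R * runif(1, 1.25, 1.45)                   # RV centre distance
  R2 <- R * runif(1, 0.85, 1.05)                  # RV radius
  alpha <- acos((D^2 + R^2 - R2^2) / (2 * D * R))

  g <- .pixel_grid(H, W)
  dist_lv <- sqrt((g$r - ctr[1])^2 + (g$c - ctr[2])^2)
  rv_ctr <- ctr + D * c(cos(phi0), sin(phi0))
  px <- matrix(0.12, H, W)
  px[dist_lv <= R] <- 0.45                          # myocardium
  px[dist_lv <= R - t] <- 0.95                      # blood pool
  if (config$rv_crescent) {
    dist_rv <- sqrt((g$r - rv_ctr[1])^2 + (g$c - rv_ctr[2])^2)
    px[dist_rv <= R2 & dist_lv > R] <- 0.85         # RV crescent
  }
  px <- .smooth_mask(px)
  img <- .finish_image(px, config, id, "SAX")

  e <- function(phi) c(cos(phi), sin(phi))
  a_rvi <- ctr + R * e(phi0 + alpha)
  p_rvi <- ctr + R * e(phi0 - alpha)
  truth <- rbind(a_rvi, p_rvi, ctr)
  coords <- .jitter_clamp(truth, config$landmark_jitter_sd, H, W)
  lms <- landmark_set("SAX", coords, present = rep(TRUE, 3L))
  geom <- list(center = ctr, R_px = R, t_px = t, phi0 = phi0,
               alpha = alpha, a_rvi = a_rvi, p_rvi = p_rvi,
               rv_center = rv_ctr, R2_px = R2)
  .phantom_sample(img, lms, "SAX", id, patient_id, geom)
}

#' Generate a contracting cine phantom series
#'
#' One long-axis geometry is sampled and rendered over a smooth cardiac
#' cycle: the LV length follows
#' \eqn{L(t) = L_{ED} (1 - f \cdot s(t))} with
#' \eqn{s(t) = (1 - \cos(2\pi (t-1)/n)) / 2}, so phase 1 is end
#' diastole, the mid-series phase reaches \eqn{(1 - f) L_{ED}} (end
#' systole) and the cycle closes on itself.  The radius co-contracts at
#' half the fractional rate.  Noise, shading and annotation jitter are
#' drawn fresh per phase.
#'
#' @param config A long-axis [phantom_config()].
#' @param n_phases Number of cardiac phases (>= 2; cine protocols
#'   typically reconstruct 30).
#' @param contraction_fraction Peak fractional shortening f in (0, 1).
#' @param id Optional series id (phase index appended per frame).
#' @param patient_id Optional patient id shared by all phases.
#' @return List of \code{phantom_sample}, one per phase.
#' @export
generate_cine_series <- function(config, n_phases = 30L,
                                 contraction_fraction = 0.2, id = NULL,
                                 patient_id = NULL) {
  if (!config$view %in% .LONG_AXIS_VIEWS)
    stop("cine series are generated on long-axis views")
  if (n_phases < 2L) stop("n_phases must be >= 2")
  if (contraction_fraction <= 0 || contraction_fraction >= 1)
    stop("contraction_fraction must be in (0, 1)")
  if (!is.null(config$seed)) set.seed(config$seed)
  base <- .sample_long_axis_geom(config)
  out <- vector("list", n_phases)
  for (ph in seq_len(n_phases)) {
    s <- (1 - cos(2 * pi * (ph - 1) / n_phases)) / 2
    geom <- base
    geom$L_mm <- base$L_mm * (1 - contraction_fraction * s)
    geom$A_px <- base$A_px * (1 - contraction_fraction * s)
    geom$r_px <- base$r_px * (1 - 0.5 * contraction_fraction * s)
    geom$phase <- ph
    r <- .render_long_axis(config, geom,
                           if (is.null(id)) NULL else paste0(id, "_ph", ph))
    out[[ph]] <- .phantom_sample(r$image, r$landmarks, config$view,
                                 r$image$meta$id, patient_id, r$geom)
  }
  out
}

#' Generate a phantom dataset
#'
#' Repeatedly draws independent samples with sequential ids.  Each
#' sample is assigned its own patient id (phantoms are exchangeable, so
#' one "patient" per sample keeps patient-wise splitting meaningful).
#'
#' @param n Number of samples.
#' @param config A [phantom_config()]; its per-call \code{seed} is
#'   ignored in favour of \code{seed} below.
#' @param seed Integer seed for the whole dataset.
#' @return List of \code{phantom_sample}.
#' @export
phantom_dataset <- function(n, config = phantom_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  cfg$seed <- NULL
  gen <- if (cfg$view == "SAX") generate_short_axis else generate_long_axis
  lapply(seq_len(n), function(i)
    gen(cfg, id = sprintf("S%04d", i), patient_id = sprintf("P%04d", i)))
}
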