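#' Preprocessing configuration
#'
#' @param target_spacing Detector grid spacing in mm.
#' @param target_size Detector grid size in pixels (rows, cols), both
#'   even.
#' @param p_use_original Probability, during augmentation, of feeding
#'   the original rather than the shading-corrected image.
#' @param field_smoothing_scale Bias-field smoothing kernel width as a
#'   fraction of the image extent.
#' @param intensity_floor Lower bound applied to the estimated bias
#'   field before division.
#' @param aug_rotate_deg,aug_scale_frac,aug_translate_frac,aug_gamma_range
#'   Augmentation ranges: rotation (+- degrees), isotropic scale
#'   (+- fraction), translation (+- fraction of extent; 0.05 of a
#'   400 px grid is +-20 px) and intensity gamma.
#' @export
preprocess_config <- function(target_spacing = 1, target_size = c(400L, 400L),
                              p_use_original = 0.5,
                              field_smoothing_scale = 1 / 8,
                              intensity_floor = 1e-3,
                              aug_rotate_deg = 30, aug_scale_frac = 0.1,
                              aug_translate_frac = 0.05,
                              aug_gamma_range = c(0.8, 1.2)) {
  target_size <- as.integer(rep(target_size, length.out = 2L))
  if (any(target_size %% 2L != 0L)) stop("target_size must be even")
  if (p_use_original < 0 || p_use_original > 1)
    stop("p_use_original must be a probability")
  structure(list(target_spacing = as.numeric(target_spacing),
                 target_size = target_size,
                 p_use_original = p_use_original,
                 field_smoothing_scale = field_smoothing_scale,
                 intensity_floor = intensity_floor,
                 aug_rotate_deg = aug_rotate_deg,
                 aug_scale_frac = aug_scale_frac,
                 aug_translate_frac = aug_translate_frac,
                 aug_gamma_range = aug_gamma_range),
            class = "preprocess_config")
}

#' Resample an image to a target pixel spacing
#'
#' Bilinear resampling onto an isotropic grid.  The output size is
#' \code{round(size * spacing / target_spacing)} (round half to even,
#' for platform-stable sizes).  The returned image carries a
#' \code{coord_map} attribute: landmark coordinates transform by the
#' scale factor \code{spacing / target_spacing}.
#'
#' @param image An [image2d()].
#' @param target_spacing New spacing in mm (> 0).
#' @export
resample_to_spacing <- function(image, target_spacing = 1) {
  img <- as_image2d(image)
  if (target_spacing <= 0) stop("target_spacing must be positive")
  s <- img$spacing / target_spacing
  H <- nrow(img$pixels); W <- ncol(img$pixels)
  newH <- as.integer(round(H * s)); newW <- as.integer(round(W * s))
  if (s == 1) {
    out <- img
  } else {
    # output pixel (r, c) samples input at (r / s, c / s)
    px <- .warp_affine_cpp(img$pixels, diag(2) / s, c(0, 0), newH, newW)
    out <- image2d(px, target_spacing, id = img$meta$id, view = img$meta$view)
  }
  attr(out, "coord_map") <- coord_map(diag(2) * s, c(0, 0))
  out
}

#' Pad or crop an image to a fixed grid size
#'
#' Content is kept centred: padding (value 0) is split evenly between
#' the two sides (extra pixel on the high-index side), cropping removes
#' equal margins (extra pixel from the high-index side).
#'
#' @param image An [image2d()].
#' @param target_size Pixels (rows, cols).
#' @export
pad_or_crop <- function(image, target_size = c(400L, 400L)) {
  img <- as_image2d(image)
  target_size <- as.integer(rep(target_size, length.out = 2L))
  px <- img$pixels
  off <- numeric(2)
  for (ax in 1:2) {
    n <- dim(px)[ax]; Tn <- target_size[ax]
    if (n == Tn) next
    if (n < Tn) {
      lo <- (Tn - n) %/% 2L
      if (ax == 1) {
        out <- matrix(0, Tn, ncol(px)); out[lo + seq_len(n), ] <- px
      } else {
        out <- matrix(0, nrow(px), Tn); out[, lo + seq_len(n)] <- px
      }
      px <- out
      off[ax] <- lo
    } else {
      lo <- (n - Tn) %/% 2L
      px <- if (ax == 1) px[lo + seq_len(Tn), , drop = FALSE]
            else px[, lo + seq_len(Tn), drop = FALSE]
      off[ax] <- -lo
    }
  }
  out <- image2d(px, img$spacing, id = img$meta$id, view = img$meta$view)
  attr(out, "coord_map") <- coord_map(diag(2), off)
  out
}

# Gaussian smoothing with the kernel radius capped at the image size
# (EBImage's default radius of 3 sigma can exceed small images).
.gblur_safe <- function(x, sigma) {
  r_max <- 2L * ((min(dim(x)) - 1L) %/% 2L) + 1L
  radius <- min(2L * as.integer(ceiling(3 * sigma)) + 1L, r_max)
  EBImage::gblur(x, sigma = sigma, radius = radius, boundary = "replicate")
}

#' Estimate a multiplicative bias field
#'
#' The slowly varying surface-coil sensitivity is modelled as a smooth
#' parametric surface: a low-order polynomial (Legendre-type tensor
#' basis) is fitted to the log-intensities by least squares and
#' exponentiated.  The polynomial order is tied to \code{scale} (order
#' \code{round(1 / (2 * scale))}, so the default 1/8 gives a 4th-order
#' surface with features no finer than about a quarter of the image
#' extent).  Because the fit is a linear projection in the log domain,
#' dividing the field out and re-estimating returns a constant field:
#' the correction is idempotent.  The field is normalised to a maximum
#' of 1 and floored at \code{intensity_floor}.
#'
#' @param image An [image2d()] or matrix.
#' @param scale Field smoothness as a fraction of the image extent.
#' @param intensity_floor Lower bound for the field.
#' @return Strictly positive matrix of the image size, max 1.
#' @export
estimate_bias_field <- function(image, scale = 1 / 8,
                                intensity_floor = 1e-3) {
  px <- as_image2d(image)$pixels
  if (max(px) <= min(px)) return(matrix(1, nrow(px), ncol(px)))
  H <- nrow(px); W <- ncol(px)
  degree <- max(2L, as.integer(round(1 / (2 * scale))))
  lp <- as.vector(log(pmax(px, intensity_floor * max(px))))
  B <- .poly_basis(H, W, degree)
  # robust fit: anatomy appears as coherent *bright* outliers over the
  # slowly varying coil profile, so the bisquare reweighting clips
  # positive residuals much harder than negative ones
  w <- rep(1, length(lp))
  fitted <- lp
  for (it in 1:6) {
    fit <- stats::lm.wfit(B, lp, w)
    fitted <- lp - fit$residuals
    s <- stats::median(abs(fit$residuals)) / 0.6745
    if (s <= 0) break
    u <- fit$residuals / (ifelse(fit$residuals > 0, 2.5, 8) * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  }
  f <- exp(matrix(fitted, H, W))
  f <- f / max(f)
  pmax(f, intensity_floor)
}

# tensor polynomial basis on [-1, 1]^2, total degree <= degree
.poly_basis <- function(H, W, degree) {
  r <- 2 * (0:(H - 1)) / (H - 1) - 1
  cc <- 2 * (0:(W - 1)) / (W - 1) - 1
  cols <- list()
  for (i in 0:degree)
    for (j in 0:(degree - i))
      cols[[length(cols) + 1L]] <- as.vector(outer(r^i, cc^j))
  do.call(cbind, cols)
}

#' Correct multiplicative intensity inhomogeneity
#'
#' Divides the image by the bias field and rescales so the mean
#' intensity of the input is preserved.
#'
#' @param image An [image2d()].
#' @param field Positive matrix matching the image size (default:
#'   estimated from the image).
#' @export
correct_inhomogeneity <- function(image, field = NULL) {
  img <- as_image2d(image)
  if (is.null(field)) field <- estimate_bias_field(img)
  if (!identical(dim(field), dim(img$pixels)))
    stop("field shape does not match image")
  if (any(field <= 0)) stop("field must be strictly positive")
  out <- img$pixels / field
  m_out <- mean(out)
  if (m_out > 0) out <- out * (mean(img$pixels) / m_out)
  image2d(out, img$spacing, id = img$meta$id, view = img$meta$view)
}

#' Rescale intensities to [0, 1] by a robust percentile window
#'
#' Maps the 1st..99th intensity percentiles onto [0, 1] and clamps.
#' Applied to every image before it enters the network.
#'
#' @param px Numeric matrix.
#' @export
normalize_intensity <- function(px) {
  qs <- stats::quantile(px, c(0.01, 0.99), names = FALSE)
  if (qs[2] <= qs[1]) return(px * 0)
  pmin(pmax((px - qs[1]) / (qs[2] - qs[1]), 0), 1)
}

#' Training-time augmentation
#'
#' With probability \code{p_use_original} the original image is used,
#' otherwise the shading-corrected one; a random rotation, isotropic
#' scale, translation and intensity gamma are then applied jointly to
#' the image and the landmark coordinates.  Landmarks pushed outside
#' the image bounds are marked absent.  No mirror flips are applied:
#' flips would invert anterior/posterior landmark semantics.
#'
#' @param image An [image2d()].
#' @param landmarks The matching [landmark_set()].
#' @param config A [preprocess_config()].
#' @param theta_deg,scale,translate,gamma Optional fixed transform
#'   parameters (otherwise drawn from the config ranges); rotation in
#'   degrees counterclockwise in the displayed image (row axis down).
#' @return List with \code{image}, \code{landmarks} and the applied
#'   \code{map} ([coord_map()]).
#' @export
augment <- function(image, landmarks, config = preprocess_config(),
                    theta_deg = NULL, scale = NULL, translate = NULL,
                    gamma = NULL) {
  img <- as_image2d(image)
  if (runif(1) >= config$p_use_original)
    img <- correct_inhomogeneity(
      img, estimate_bias_field(img, config$field_smoothing_scale,
                               config$intensity_floor))
  H <- nrow(img$pixels); W <- ncol(img$pixels)
  theta <- (theta_deg %||%
              runif(1, -config$aug_rotate_deg, config$aug_rotate_deg)) *
    pi / 180
  sc <- scale %||% (1 + runif(1, -config$aug_scale_frac,
                              config$aug_scale_frac))
  tr <- translate %||%
    (runif(2, -config$aug_translate_frac, config$aug_translate_frac) *
       c(H, W))
  gam <- gamma %||% runif(1, config$aug_gamma_range[1],
                          config$aug_gamma_range[2])

  ctr <- c((H - 1) / 2, (W - 1) / 2)
  # forward map (for landmarks): x' = sc * R(theta) (x - ctr) + ctr + tr,
  # where R acts on (row, col) with the row axis pointing down
  Rm <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  A <- sc * Rm
  b <- ctr + tr - A %*% ctr
  map <- coord_map(A, b)
  # inverse map feeds the warp (output pixel -> source location)
  Ainv <- solve(A)
  px <- .warp_affine_cpp(img$pixels, Ainv, -Ainv %*% b, H, W)

  rng <- range(px)
  if (rng[2] > rng[1])
    px <- rng[1] + (rng[2] - rng[1]) *
      ((px - rng[1]) / (rng[2] - rng[1]))^gam

  out_img <- image2d(px, img$spacing, id = img$meta$id, view = img$meta$view)
  out_lms <- transform_landmarks(landmarks, map, c(H, W))
  list(image = out_img, landmarks = out_lms, map = map)
}

#' Full preprocessing chain to the detector grid
#'
#' Resample to the target spacing, pad/crop to the target size and
#' normalise intensities; optionally apply bias-field correction first
#' (at inference the correction is always applied, matching its
#' expected value under the p = 0.5 training augmentation).
#'
#' @param image An [image2d()].
#' @param config A [preprocess_config()].
#' @param correct Apply inhomogeneity correction.
#' @return List with \code{image} (normalised, on the detector grid)
#'   and \code{map}, the composed [coord_map()] from input to detector
#'   coordinates.
#' @export
preprocess_image <- function(image, config = preprocess_config(),
                             correct = TRUE) {
  img <- as_image2d(image)
  if (correct)
    img <- correct_inhomogeneity(
      img, estimate_bias_field(img, config$field_smoothing_scale,
                               config$intensity_floor))
  rs <- resample_to_spacing(img, config$target_spacing)
  m1 <- coord_map_of(rs)
  pc <- pad_or_crop(rs, config$target_size)
  m2 <- coord_map_of(pc)
  pc$pixels <- normalize_intensity(pc$pixels)
  list(image = pc, map = compose_maps(m2, m1))
}
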