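#' 2D grayscale image with physical pixel spacing
#'
#' The basic image container: a numeric matrix of nonnegative
#' intensities plus the isotropic pixel spacing in millimetres.  All
#' geometry in the package uses 0-based (row, col) pixel coordinates
#' with pixel centres at integer positions; multiply by \code{spacing}
#' to convert to millimetres.
#'
#' @param pixels Numeric matrix (rows x cols) of finite intensities.
#' @param spacing Pixel spacing in mm (> 0), isotropic.
#' @param id Optional sample identifier.
#' @param view Optional view tag ("CH2", "CH3", "CH4", "SAX").
#' @return An object of class \code{image2d}.
#' @export
image2d <- function(pixels, spacing = 1, id = NULL, view = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (!all(is.finite(pixels))) stop("pixels must be finite")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a single positive number (mm)")
  structure(list(pixels = pixels, spacing = as.numeric(spacing),
                 meta = list(id = id, view = view)),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("image2d: %d x %d pixels @ %g mm", nrow(x$pixels),
              ncol(x$pixels), x$spacing))
  if (!is.null(x$meta$id)) cat(", id =", x$meta$id)
  if (!is.null(x$meta$view)) cat(", view =", x$meta$view)
  cat("\n")
  invisible(x)
}

#' @export
dim.image2d <- function(x) dim(x$pixels)

as_image2d <- function(x, spacing = 1) {
  if (inherits(x, "image2d")) x else image2d(as.matrix(x), spacing)
}

#' @export
plot.image2d <- function(x, landmarks = NULL, main = NULL, ...) {
  px <- x$pixels
  # display with row 0 at the top, matching the (row, col) convention
  graphics::image(t(px)[, nrow(px):1, drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  main = main %||% x$meta$id, asp = nrow(px) / ncol(px), ...)
  if (!is.null(landmarks)) {
    pres <- landmarks$present
    if (any(pres)) {
      co <- landmarks$coords[pres, , drop = FALSE]
      graphics::points(co[, 2] / (ncol(px) - 1),
                       1 - co[, 1] / (nrow(px) - 1),
                       pch = 4, col = "red", cex = 1.4, lwd = 2)
    }
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ----------------------------------------------------------------------
# affine coordinate maps: new = A %*% c(row, col) + b.  Companion objects
# for the preprocessing chain so landmark coordinates transform exactly
# as the image grid does.

#' Affine coordinate map
#'
#' Represents the (row, col) coordinate transform that accompanies an
#' image-grid operation, so landmark coordinates can be moved through
#' the same geometry as the pixels.
#'
#' @param A 2x2 matrix; @param b length-2 offset.
#' @return An object of class \code{coord_map}.
#' @export
coord_map <- function(A = diag(2), b = c(0, 0)) {
  structure(list(A = matrix(as.numeric(A), 2, 2), b = as.numeric(b)),
            class = "coord_map")
}

#' Apply a coordinate map to (row, col) points
#' @param map A [coord_map()]. @param coords n x 2 matrix of (row, col).
#' @export
apply_map <- function(map, coords) {
  coords <- matrix(as.numeric(coords), ncol = 2L)
  t(map$A %*% t(coords) + map$b)
}

#' Compose coordinate maps (apply \code{first}, then \code{second})
#' @param second,first [coord_map()] objects.
#' @export
compose_maps <- function(second, first) {
  coord_map(second$A %*% first$A, as.vector(second$A %*% first$b) + second$b)
}

coord_map_of <- function(img) attr(img, "coord_map") %||% coord_map()

#' Transform a landmark set through a coordinate map
#'
#' Landmarks that land outside the target image bounds are marked
#' absent (their coordinates are kept for reference).
#'
#' @param landmarks A [landmark_set()]. @param map A [coord_map()].
#' @param shape Target image size (rows, cols).
#' @export
transform_landmarks <- function(landmarks, map, shape) {
  out <- landmarks
  if (any(landmarks$present)) {
    co <- apply_map(map, landmarks$coords)
    rownames(co) <- landmarks$roles
    out$coords <- co
    inb <- co[, 1] >= 0 & co[, 1] <= shape[1] - 1 &
           co[, 2] >= 0 & co[, 2] <= shape[2] - 1
    out$present <- unname(landmarks$present & inb)
  }
  out
}
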