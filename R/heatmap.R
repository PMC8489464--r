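#' Landmark roles for each cardiac view
#'
#' Every supported view carries exactly three landmarks, in a fixed
#' channel order so that one long-axis model can serve the two-, three-
#' and four-chamber views with shared output channels:
#' \itemize{
#'   \item CH2: anterior, inferior, apex
#'   \item CH3: inferolateral, anteroseptal, apex
#'   \item CH4: inferoseptal, anterolateral, apex
#'   \item SAX: A-RVI, P-RVI, C-LV
#' }
#' @param view View tag.
#' @return Character vector of the three role names.
#' @export
view_roles <- function(view) {
  switch(view,
         CH2 = c("anterior", "inferior", "apex"),
         CH3 = c("inferolateral", "anteroseptal", "apex"),
         CH4 = c("inferoseptal", "anterolateral", "apex"),
         SAX = c("A-RVI", "P-RVI", "C-LV"),
         stop("unsupported view: ", view))
}

.LONG_AXIS_VIEWS <- c("CH2", "CH3", "CH4")

#' Ordered landmark set for one image
#'
#' @param view View tag ("CH2", "CH3", "CH4", "SAX").
#' @param coords 3 x 2 matrix of 0-based (row, col) pixel coordinates;
#'   rows follow [view_roles()] order.  May contain NA for absent
#'   landmarks.
#' @param present Logical vector of length 3.
#' @return An object of class \code{landmark_set}.
#' @export
landmark_set <- function(view, coords = matrix(NA_real_, 3, 2),
                         present = rep(FALSE, 3L)) {
  roles <- view_roles(view)
  coords <- matrix(as.numeric(coords), ncol = 2L)
  if (nrow(coords) != 3L) stop("coords must have one row per role")
  present <- as.logical(present)
  if (length(present) != 3L) stop("present must have length 3")
  if (any(present & (!is.finite(coords[, 1]) | !is.finite(coords[, 2]))))
    stop("present landmarks must have finite coordinates")
  rownames(coords) <- roles
  structure(list(view = view, roles = roles, coords = coords,
                 present = present),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set (", x$view, ")\n", sep = "")
  for (i in seq_along(x$roles)) {
    if (x$present[i])
      cat(sprintf("  %-14s (%.2f, %.2f)\n", x$roles[i],
                  x$coords[i, 1], x$coords[i, 2]))
    else
      cat(sprintf("  %-14s absent\n", x$roles[i]))
  }
  invisible(x)
}

#' Decoding configuration
#'
#' @param presence_threshold Peak probability below which a landmark is
#'   declared absent (0 < tau < 1).
#' @param subpixel_window Half-width (pixels) of the box around the peak
#'   used for the probability-weighted centroid; the natural choice is
#'   2 * sigma of the encoding kernel.
#' @export
decode_config <- function(presence_threshold = 0.5, subpixel_window = 8) {
  if (presence_threshold <= 0 || presence_threshold >= 1)
    stop("presence_threshold must be in (0, 1)")
  structure(list(presence_threshold = presence_threshold,
                 subpixel_window = as.integer(round(subpixel_window))),
            class = "decode_config")
}

#' Encode landmarks as a spatial-probability heatmap
#'
#' Each present landmark becomes a Gaussian blob
#' \eqn{\exp(-d^2 / 2\sigma^2)} (peak 1 at the landmark) in its own
#' channel; the background channel takes the remaining probability
#' (clamped at 0) and every pixel is renormalised so the channels form a
#' distribution.  Channel 1 is background; channels 2..4 follow
#' [view_roles()] order.  As with discrete convolution by a finite
#' Gaussian kernel, the blob has compact support: it is truncated to
#' zero beyond a radius of 4 sigma, so landmark channels are exactly
#' zero far from the landmark.
#'
#' @param landmarks A [landmark_set()].
#' @param shape Image size (rows, cols).
#' @param sigma Gaussian kernel width in pixels (> 0).
#' @return Array (rows, cols, 4) with per-pixel channel sums of 1;
#'   attribute \code{sigma} records the kernel width.
#' @export
encode_heatmap <- function(landmarks, shape, sigma = 4) {
  stopifnot(sigma > 0, length(shape) == 2L, all(shape > 0))
  H <- shape[1]; W <- shape[2]
  L <- length(landmarks$roles)
  hm <- array(0, dim = c(H, W, L + 1L))
  for (k in seq_len(L)) {
    if (!landmarks$present[k]) next
    r0 <- landmarks$coords[k, 1]; c0 <- landmarks$coords[k, 2]
    if (r0 < 0 || r0 > H - 1 || c0 < 0 || c0 > W - 1)
      stop("present landmark '", landmarks$roles[k], "' outside the image")
    d2 <- outer(((0:(H - 1)) - r0)^2, ((0:(W - 1)) - c0)^2, `+`)
    g <- exp(-d2 / (2 * sigma^2))
    g[d2 > (4 * sigma)^2] <- 0     # finite kernel support
    hm[, , k + 1L] <- g
  }
  fg <- apply(hm[, , -1L, drop = FALSE], c(1, 2), sum)
  hm[, , 1L] <- pmax(0, 1 - fg)
  tot <- apply(hm, c(1, 2), sum)
  hm <- hm / as.vector(tot)
  attr(hm, "sigma") <- sigma
  attr(hm, "view") <- landmarks$view
  hm
}

#' Decode a heatmap prediction into landmark coordinates
#'
#' For every landmark channel the peak probability is located; the
#' landmark is declared present when the peak reaches the presence
#' threshold, and its coordinate is refined to the probability-weighted
#' centroid inside a box around the peak.  Ties in the maximum are
#' broken towards the smallest row-major (row, then col) index.
#'
#' @param probs Array (rows, cols, L+1) of per-pixel class
#'   probabilities (channel 1 = background).
#' @param config A [decode_config()].
#' @param view View tag used to label the roles (default from the
#'   \code{view} attribute of \code{probs}, else "SAX").
#' @return A \code{detection_result}: per-role presence flag, (row, col)
#'   estimate and peak probability.
#' @export
decode_heatmap <- function(probs, config = decode_config(), view = NULL) {
  d <- dim(probs)
  if (length(d) != 3L || d[3] < 2L) stop("probs must be a (H, W, C) array")
  sums <- apply(probs, c(1, 2), sum)
  if (max(abs(sums - 1)) > 1e-3)
    stop("probs channels must sum to 1 at every pixel")
  view <- view %||% attr(probs, "view") %||% "SAX"
  roles <- view_roles(view)
  H <- d[1]; W <- d[2]; L <- d[3] - 1L
  present <- logical(L)
  coords <- matrix(NA_real_, L, 2L)
  peaks <- numeric(L)
  w <- config$subpixel_window
  for (k in seq_len(L)) {
    ch <- probs[, , k + 1L]
    pk <- max(ch)
    peaks[k] <- pk
    if (pk < config$presence_threshold) next
    idx <- which(ch == pk)
    # row-major tie-break: smallest (row * W + col), 0-based
    rows0 <- (idx - 1L) %% H
    cols0 <- (idx - 1L) %/% H
    sel <- which.min(rows0 * W + cols0)
    r0 <- rows0[sel]; c0 <- cols0[sel]
    rr <- max(0, r0 - w):min(H - 1, r0 + w)
    cc <- max(0, c0 - w):min(W - 1, c0 + w)
    win <- ch[rr + 1L, cc + 1L, drop = FALSE]
    tot <- sum(win)
    coords[k, ] <- c(sum(rowSums(win) * rr), sum(colSums(win) * cc)) / tot
    present[k] <- TRUE
  }
  structure(list(view = view, roles = roles, present = present,
                 coords = structure(coords, dimnames = list(roles, NULL)),
                 peak = setNames(peaks, roles)),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat("detection_result (", x$view, ")\n", sep = "")
  for (i in seq_along(x$roles)) {
    if (x$present[i])
      cat(sprintf("  %-14s (%.2f, %.2f)  peak %.3f\n", x$roles[i],
                  x$coords[i, 1], x$coords[i, 2], x$peak[i]))
    else
      cat(sprintf("  %-14s absent  (peak %.3f)\n", x$roles[i], x$peak[i]))
  }
  invisible(x)
}

#' Count detection errors against a reference
#'
#' @param pred A \code{detection_result} (or \code{landmark_set}).
#' @param truth The reference [landmark_set()] for the same view.
#' @return List with \code{missed} (truth-present but predicted absent),
#'   \code{spurious} (truth-absent but predicted present) and
#'   \code{all_detected} (every truth-present landmark found).
#' @export
count_errors <- function(pred, truth) {
  if (!identical(pred$view, truth$view))
    stop("view mismatch: ", pred$view, " vs ", truth$view)
  missed <- sum(truth$present & !pred$present)
  spurious <- sum(!truth$present & pred$present)
  list(missed = missed, spurious = spurious,
       all_detected = missed == 0L)
}
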