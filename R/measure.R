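#' Euclidean distance between two pixel points in millimetres
#'
#' @param p,q Length-2 (row, col) pixel coordinates.
#' @param spacing Pixel spacing in mm.
#' @export
euclidean_distance_mm <- function(p, q, spacing = 1) {
  stopifnot(spacing > 0, all(is.finite(p)), all(is.finite(q)))
  spacing * sqrt(sum((as.numeric(p) - as.numeric(q))^2))
}

#' Left-ventricular length
#'
#' Distance from the apical point to the midpoint of the two
#' valve-plane points, in millimetres.  Returns NA when any of the
#' three landmarks is unavailable.
#'
#' @param apex,valve_a,valve_b (row, col) pixel coordinates.
#' @param spacing Pixel spacing in mm.
#' @export
lv_length <- function(apex, valve_a, valve_b, spacing = 1) {
  if (anyNA(c(apex, valve_a, valve_b))) return(NA_real_)
  mid <- (as.numeric(valve_a) + as.numeric(valve_b)) / 2
  euclidean_distance_mm(apex, mid, spacing)
}

.lv_length_of <- function(lms, spacing = 1) {
  if (!all(lms$present)) return(NA_real_)
  lv_length(lms$coords[3, ], lms$coords[1, ], lms$coords[2, ], spacing)
}

#' Anterior RV-insertion angle
#'
#' Angle of the vector from the LV centre (C-LV) to the anterior RV
#' insertion point (A-RVI), measured counterclockwise from the +col
#' axis in the image frame (the row axis points down), in [0, 360)
#' degrees.  The reference frame is a package convention, recorded
#' here; any fixed frame supports comparisons between label sources.
#'
#' @param a_rvi,c_lv (row, col) pixel coordinates.
#' @export
a_rvi_angle <- function(a_rvi, c_lv) {
  if (anyNA(c(a_rvi, c_lv))) return(NA_real_)
  d <- as.numeric(a_rvi) - as.numeric(c_lv)
  if (all(d == 0)) return(NA_real_)
  ang <- atan2(-d[1], d[2]) * 180 / pi
  ang %% 360
}

#' Global longitudinal shortening curve
#'
#' Per-phase fractional LV shortening relative to the first phase
#' (end diastole): \eqn{(L(1) - L(t)) / L(1)}.  Phases with missing
#' landmarks yield NA gaps.
#'
#' @param series List of \code{detection_result} or
#'   \code{landmark_set} objects for consecutive cardiac phases
#'   (long-axis view).
#' @param spacing Pixel spacing in mm.
#' @return Numeric vector of per-phase ratios; ratio(1) = 0.
#' @export
shortening_curve <- function(series, spacing = 1) {
  if (length(series) < 2L) stop("need at least 2 phases")
  L <- vapply(series, .lv_length_of, numeric(1), spacing = spacing)
  if (is.na(L[1]) || !all(series[[1]]$present))
    stop("all landmarks must be present in phase 1")
  if (L[1] == 0) stop("zero LV length at phase 1")
  (L[1] - L) / L[1]
}

#' Detection rate and distance report
#'
#' The detection (success) rate is the percentage of images on which
#' every truth-present landmark was detected.  False positives are
#' landmarks detected where the truth has none.  Euclidean distances
#' to the reference labels are aggregated (mean +- SD, in mm) over
#' successfully detected images only, per landmark role.
#'
#' @param preds List of \code{detection_result}s.
#' @param truths List of matching reference [landmark_set()]s.
#' @param spacing Pixel spacing in mm (scalar or per-image vector).
#' @return An object of class \code{eval_report}.
#' @export
detection_rate <- function(preds, truths, spacing = 1) {
  n <- length(preds)
  if (n == 0L || n != length(truths)) stop("empty or mismatched inputs")
  spacing <- rep(spacing, length.out = n)
  success <- logical(n)
  fp <- 0L
  dist_rows <- list()
  for (i in seq_len(n)) {
    ce <- count_errors(preds[[i]], truths[[i]])
    success[i] <- ce$all_detected
    fp <- fp + ce$spurious
    if (ce$all_detected) {
      both <- truths[[i]]$present & preds[[i]]$present
      for (k in which(both)) {
        dist_rows[[length(dist_rows) + 1L]] <- data.frame(
          view = truths[[i]]$view, role = truths[[i]]$roles[k],
          dist_mm = euclidean_distance_mm(preds[[i]]$coords[k, ],
                                          truths[[i]]$coords[k, ],
                                          spacing[i]))
      }
    }
  }
  dists <- if (length(dist_rows)) do.call(rbind, dist_rows)
           else data.frame(view = character(), role = character(),
                           dist_mm = numeric())
  per_landmark <- if (nrow(dists)) {
    agg <- aggregate(dist_mm ~ view + role, dists, function(v)
      c(n = length(v), mean = mean(v), sd = stats::sd(v)))
    data.frame(view = agg$view, role = agg$role,
               n = agg$dist_mm[, "n"], mean_mm = agg$dist_mm[, "mean"],
               sd_mm = agg$dist_mm[, "sd"])
  } else {
    data.frame(view = character(), role = character(), n = numeric(),
               mean_mm = numeric(), sd_mm = numeric())
  }
  structure(list(n_images = n, n_success = sum(success),
                 detection_rate = 100 * sum(success) / n,
                 false_positives = fp, per_landmark = per_landmark,
                 mean_distance_mm = if (nrow(dists)) mean(dists$dist_mm)
                                    else NA_real_,
                 distances = dists),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Detection rate: %.1f%% (%d of %d images); %d false positive(s)\n",
              x$detection_rate, x$n_success, x$n_images,
              x$false_positives))
  if (nrow(x$per_landmark)) {
    cat("Distances over successful detections (mm, mean +- SD):\n")
    pl <- x$per_landmark
    for (i in seq_len(nrow(pl)))
      cat(sprintf("  %-4s %-14s %5.2f +- %.2f  (n = %d)\n", pl$view[i],
                  pl$role[i], pl$mean_mm[i], pl$sd_mm[i], pl$n[i]))
  }
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) x$per_landmark

#' @importFrom stats aggregate
NULL
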