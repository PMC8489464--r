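#' Landmark tables as data frames / CSV
#'
#' The shared annotation schema: one row per (sample, role) with
#' columns \code{sample_id, view, landmark_role, row, col, present}
#' (0-based pixel coordinates; NA coordinates for absent landmarks).
#' Detection results additionally carry \code{peak}.
#'
#' @param landmarks A [landmark_set()] or \code{detection_result}.
#' @param sample_id Sample identifier.
#' @return data.frame in the annotation schema.
#' @export
landmarks_to_df <- function(landmarks, sample_id = "sample") {
  df <- data.frame(sample_id = sample_id, view = landmarks$view,
                   landmark_role = landmarks$roles,
                   row = ifelse(landmarks$present, landmarks$coords[, 1], NA),
                   col = ifelse(landmarks$present, landmarks$coords[, 2], NA),
                   present = landmarks$present)
  if (!is.null(landmarks$peak)) df$peak <- as.numeric(landmarks$peak)
  df
}

#' @rdname landmarks_to_df
#' @param df data.frame in the annotation schema (rows for one sample).
#' @export
df_to_landmarks <- function(df) {
  view <- as.character(df$view[1])
  roles <- view_roles(view)
  ord <- match(roles, as.character(df$landmark_role))
  if (anyNA(ord)) stop("missing roles for view ", view)
  co <- cbind(df$row[ord], df$col[ord])
  landmark_set(view, co, present = as.logical(df$present[ord]))
}

#' Write / read a landmark CSV table
#'
#' @param x Named list of [landmark_set()]/\code{detection_result}
#'   objects (names are sample ids), or a list of
#'   \code{phantom_sample}s.
#' @param path CSV file path.
#' @export
write_landmark_csv <- function(x, path) {
  rows <- lapply(seq_along(x), function(i) {
    it <- x[[i]]
    if (inherits(it, "phantom_sample"))
      landmarks_to_df(it$landmarks, it$id %||% sprintf("S%04d", i))
    else
      landmarks_to_df(it, names(x)[i] %||% sprintf("S%04d", i))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmark_csv
#' @return \code{read_landmark_csv}: named list of [landmark_set()]s.
#' @export
read_landmark_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$sample_id), df_to_landmarks)
  out[unique(df$sample_id)]
}

# ----------------------------------------------------------------------
# image files

#' Read a 2D grayscale image from common formats
#'
#' Supports NIfTI (\code{.nii}, \code{.nii.gz}; spacing from the
#' header), PNG and TIFF (spacing must be supplied), and plain CSV
#' matrices.  Multichannel inputs are averaged to grayscale.
#'
#' @param path Input file.
#' @param spacing Pixel spacing in mm; required when the format carries
#'   no spacing metadata.
#' @return An [image2d()].
#' @export
read_image <- function(path, spacing = NULL) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI requires the RNifti package")
    v <- RNifti::readNifti(path)
    a <- as.array(v)
    px <- if (length(dim(a)) >= 3L) a[, , 1] else a
    px <- matrix(as.numeric(px), nrow(px), ncol(px))
    sp <- spacing %||% RNifti::pixdim(v)[1]
    return(image2d(px, sp, id = basename(path)))
  }
  if (is.null(spacing))
    stop("spacing metadata not available for .", ext,
         " files; supply `spacing`")
  px <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG requires the png package")
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)
      a
    },
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the tiff package")
      a <- tiff::readTIFF(path)
      if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)
      a
    },
    csv = as.matrix(read.csv(path, header = FALSE)),
    stop("unsupported image format: .", ext))
  image2d(unname(px), spacing, id = basename(path))
}

#' Write a 2D image
#'
#' PNG (8-bit) and TIFF (16-bit) intensities are rescaled to [0, 1];
#' CSV keeps raw values.
#' @param image An [image2d()] or matrix. @param path Output file.
#' @export
write_image <- function(image, path) {
  px <- as_image2d(image)$pixels
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("writing PNG requires the png package")
    rng <- range(px)
    sc <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1]) else px * 0
    png::writePNG(sc, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("writing TIFF requires the tiff package")
    rng <- range(px)
    sc <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1]) else px * 0
    tiff::writeTIFF(sc, path, bits.per.sample = 16L)
  } else if (ext == "csv") {
    utils::write.table(px, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

# ----------------------------------------------------------------------
# phantom dataset on disk: images + landmark CSV + manifest

#' Export / import a phantom dataset
#'
#' Writes one image file per sample, a landmark CSV in the shared
#' annotation schema and a JSON manifest recording the generator
#' configuration, seed and per-image intensity ranges (so the CSV/PNG
#' round trip reproduces intensities).
#'
#' @param samples List of \code{phantom_sample}s.
#' @param dir Output directory (created if needed).
#' @param format "csv" (lossless) or "png".
#' @param config,seed Recorded in the manifest.
#' @export
write_phantom_dataset <- function(samples, dir, format = c("csv", "png"),
                                  config = NULL, seed = NULL) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(seq_along(samples), function(i)
    samples[[i]]$id %||% sprintf("S%04d", i), character(1))
  rngs <- matrix(0, length(samples), 2)
  for (i in seq_along(samples)) {
    px <- samples[[i]]$image$pixels
    rngs[i, ] <- range(px)
    write_image(samples[[i]]$image,
                file.path(dir, paste0(ids[i], ".", format)))
  }
  write_landmark_csv(samples, file.path(dir, "landmarks.csv"))
  manifest <- list(n = length(samples), ids = ids, format = format,
                   spacing = samples[[1]]$image$spacing,
                   view = samples[[1]]$view,
                   intensity_range = rngs, seed = seed,
                   config = config[setdiff(names(config), "seed")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_phantom_dataset
#' @export
read_phantom_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lms <- read_landmark_csv(file.path(dir, "landmarks.csv"))
  out <- vector("list", manifest$n)
  for (i in seq_len(manifest$n)) {
    id <- manifest$ids[i]
    img <- read_image(file.path(dir, paste0(id, ".", manifest$format)),
                      spacing = manifest$spacing)
    rng <- manifest$intensity_range[i, ]
    if (manifest$format != "csv" && rng[2] > rng[1])
      img$pixels <- rng[1] + img$pixels * (rng[2] - rng[1])
    img$meta$view <- manifest$view
    out[[i]] <- .phantom_sample(img, lms[[id]], manifest$view, id,
                                patient_id = id, geom = NULL)
  }
  out
}

# ----------------------------------------------------------------------
# detector checkpoints

.CHECKPOINT_VERSION <- 1L

#' Save / load a trained detector
#'
#' Checkpoints embed the model and training configuration plus a
#' format version for compatibility checks.
#'
#' @param object A \code{landmark_detector}. @param path File path.
#' @export
save_detector <- function(object, path) {
  stopifnot(inherits(object, "landmark_detector"))
  saveRDS(list(version = .CHECKPOINT_VERSION, detector = object), path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$version, .CHECKPOINT_VERSION))
    stop("unsupported checkpoint version: ", ck$version)
  ck$detector
}
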