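#' Train a heatmap landmark detector
#'
#' The main fitting function.  Landmark detection is cast as semantic
#' segmentation: each annotated sample is encoded as a per-pixel class
#' distribution (background + one Gaussian heatmap channel per
#' landmark), a U-Net is trained on the combined Kullback-Leibler +
#' soft-Dice loss with Adam, and the checkpoint with the lowest
#' validation loss is kept.  Samples are split patient-wise into
#' training and validation sets; long-axis views (CH2/CH3/CH4) are
#' pooled and trained as one multitask model.
#'
#' @param samples List of training samples (\code{phantom_sample}
#'   objects, or lists with \code{image}, \code{landmarks} and
#'   optionally \code{patient_id}).
#' @param sigma Gaussian heatmap kernel width in pixels (default 4).
#' @param model A [model_config()]; defaults to the standard backbone
#'   sized to the samples.
#' @param train A [train_config()].
#' @param augment_n Augmented copies per training sample (0 disables
#'   augmentation; phantom datasets already vary geometry per sample).
#' @param invert_contrast Train on inverted intensities (used for the
#'   LGE-like transfer domain).
#' @param verbose Print per-epoch progress.
#' @return An object of class \code{landmark_detector} with components
#'   \code{net}, \code{history}, \code{sigma}, \code{views},
#'   \code{decode} and the configurations used.
#' @seealso [predict.landmark_detector()], [fine_tune()],
#'   [evaluate_detector()]
#' @export
landmark_detector <- function(samples, sigma = 4, model = NULL,
                              train = train_config(), augment_n = 0L,
                              invert_contrast = FALSE, verbose = FALSE) {
  if (length(samples) < 2L) stop("need at least two samples")
  views <- unique(vapply(samples, function(s) s$landmarks$view, character(1)))
  if ("SAX" %in% views && length(views) > 1L)
    stop("cannot mix SAX with long-axis views in one model")
  sz <- dim(samples[[1]]$image$pixels)
  if (is.null(model)) model <- model_config(input_size = sz)
  if (!identical(as.integer(model$input_size), as.integer(sz)))
    stop("model input_size does not match the sample image size")

  pids <- vapply(seq_along(samples), function(i)
    samples[[i]]$patient_id %||% sprintf("P%05d", i), character(1))
  sp <- split_by_patient(pids, train$val_fraction, train$seed)

  prepped <- prepare_samples(samples, sigma = sigma,
                             invert_contrast = invert_contrast,
                             augment_n = augment_n)
  # augmentation multiplies samples; map split indices accordingly
  rep_factor <- length(prepped) / length(samples)
  expand <- function(idx) {
    base <- rep((idx - 1L) * rep_factor, each = rep_factor)
    base + seq_len(rep_factor)
  }
  tr <- prepped[expand(sp$train)]
  va <- prepped[expand(sp$val)]

  set.seed(train$seed + 1L)
  net <- build_unet(model)
  fitted <- fit_unet(net, tr, va, train, verbose = verbose)

  structure(list(net = fitted$net, history = fitted$history,
                 sigma = sigma, views = views,
                 decode = decode_config(subpixel_window = 2 * sigma),
                 model_config = model, train_config = train,
                 invert_contrast = invert_contrast,
                 split = sp[c("train_patients", "val_patients")],
                 call = match.call()),
            class = "landmark_detector")
}

.detector_input <- function(object, image) {
  if (inherits(image, "phantom_sample")) image <- image$image
  img <- as_image2d(image)
  sz <- object$model_config$input_size
  if (identical(as.integer(dim(img$pixels)), as.integer(sz))) {
    x <- normalize_intensity(img$pixels)
    if (isTRUE(object$invert_contrast)) x <- 1 - x
    return(list(x = x, map = coord_map()))
  }
  pp <- preprocess_image(img, preprocess_config(target_size = sz))
  x <- pp$image$pixels
  if (isTRUE(object$invert_contrast)) x <- 1 - x
  list(x = x, map = pp$map)
}

#' Predict landmarks on new images
#'
#' Runs the network on each image and decodes the per-pixel class
#' probabilities into landmark coordinates with presence decisions.
#' Images that are not already on the detector grid are preprocessed
#' (bias-field correction, resampling, pad/crop) and the decoded
#' coordinates are mapped back to the input frame.
#'
#' @param object A \code{landmark_detector}.
#' @param newdata An [image2d()], \code{phantom_sample}, matrix, or a
#'   list of these.
#' @param type "landmarks" for decoded \code{detection_result}s,
#'   "probs" for softmax heatmaps, "scores" for raw scores.
#' @param view View tag for labelling decoded roles (defaults to the
#'   image's tag, else the detector's first view).
#' @param ... Unused.
#' @export
predict.landmark_detector <- function(object, newdata,
                                      type = c("landmarks", "probs",
                                               "scores"),
                                      view = NULL, ...) {
  type <- match.arg(type)
  single <- inherits(newdata, c("image2d", "phantom_sample")) ||
    is.matrix(newdata)
  items <- if (single) list(newdata) else newdata
  out <- lapply(items, function(it) {
    it_view <- view
    if (is.null(it_view)) {
      if (inherits(it, "phantom_sample")) it_view <- it$landmarks$view
      else if (inherits(it, "image2d")) it_view <- it$meta$view
    }
    if (is.null(it_view)) it_view <- object$views[1]
    inp <- .detector_input(object, it)
    sc <- unet_forward(object$net, inp$x)
    sc <- array(sc, dim(sc)[1:3])
    if (type == "scores") return(sc)
    probs <- softmax_probs(sc)
    if (type == "probs") return(probs)
    det <- decode_heatmap(probs, object$decode, view = it_view)
    # map back to the input frame if preprocessing moved coordinates
    Ainv <- solve(inp$map$A)
    if (any(det$present)) {
      co <- det$coords
      co[det$present, ] <- t(Ainv %*% (t(co[det$present, , drop = FALSE]) -
                                         inp$map$b))
      det$coords <- co
    }
    det
  })
  if (single) out[[1]] else out
}

#' @export
print.landmark_detector <- function(x, ...) {
  cat("Heatmap landmark detector\n")
  cat("  views:", paste(x$views, collapse = "/"),
      " sigma:", x$sigma, "px\n")
  print(x$net)
  h <- x$history
  if (nrow(h))
    cat(sprintf("  trained %d epochs; best epoch %d (val loss %.5f)\n",
                nrow(h), attr(h, "best_epoch"),
                min(h$val_loss)))
  invisible(x)
}

#' @export
summary.landmark_detector <- function(object, ...) {
  h <- object$history
  structure(list(views = object$views, sigma = object$sigma,
                 n_parameters = n_parameters(object$net),
                 epochs = nrow(h), best_epoch = attr(h, "best_epoch"),
                 best_val_loss = if (nrow(h)) min(h$val_loss) else NA,
                 final_lr = if (nrow(h)) h$lr[nrow(h)] else NA,
                 history = h),
            class = "summary.landmark_detector")
}

#' @export
print.summary.landmark_detector <- function(x, ...) {
  cat("Heatmap landmark detector —", paste(x$views, collapse = "/"), "\n")
  cat(sprintf("  parameters: %s   sigma: %g px\n",
              format(x$n_parameters, big.mark = ","), x$sigma))
  cat(sprintf("  epochs: %d   best: %d   val loss: %.5f   final lr: %.2e\n",
              x$epochs, x$best_epoch, x$best_val_loss, x$final_lr))
  invisible(x)
}

#' @export
plot.landmark_detector <- function(x, sample = NULL, ...) {
  if (is.null(sample)) {
    h <- x$history
    graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                   ylab = "loss", main = "training history", ...)
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2,
                     bty = "n")
    return(invisible(x))
  }
  det <- predict(x, sample)
  img <- if (inherits(sample, "phantom_sample")) sample$image
         else as_image2d(sample)
  plot(img, landmarks = det, main = "detected landmarks", ...)
  invisible(x)
}

#' Fine-tune a trained detector on a new image domain
#'
#' Transfer learning: keeps the architecture and weights, retrains all
#' layers briefly at the reduced fine-tuning learning rate on the new
#' samples (e.g. a different image contrast).
#'
#' @param object A \code{landmark_detector} (or a bare \code{unet}).
#' @param ... Passed on to methods.
#' @export
fine_tune <- function(object, ...) UseMethod("fine_tune")

#' @rdname fine_tune
#' @param samples New-domain training samples.
#' @param train Optional [train_config()] override.
#' @param invert_contrast Whether the new domain has inverted contrast.
#' @export
fine_tune.landmark_detector <- function(object, samples, train = NULL,
                                        invert_contrast = FALSE,
                                        verbose = FALSE, ...) {
  cfg <- train %||% object$train_config
  pids <- vapply(seq_along(samples), function(i)
    samples[[i]]$patient_id %||% sprintf("P%05d", i), character(1))
  sp <- split_by_patient(pids, cfg$val_fraction, cfg$seed)
  prepped <- prepare_samples(samples, sigma = object$sigma,
                             invert_contrast = invert_contrast)
  ft <- fine_tune_unet(object$net, prepped[sp$train], prepped[sp$val],
                       cfg, verbose = verbose)
  out <- object
  out$net <- ft$net
  out$history <- ft$history
  out$invert_contrast <- invert_contrast
  out
}

#' Saliency map: loss gradient with respect to the input image
#'
#' Computes the magnitude of the derivative of the combined training
#' loss with respect to every input pixel; large values mark image
#' regions the trained model weights heavily.
#'
#' @param object A \code{landmark_detector}.
#' @param image Input image (detector grid).
#' @param landmarks Ground-truth [landmark_set()] defining the loss
#'   target (for a \code{phantom_sample}, taken from the sample).
#' @return Matrix of |d loss / d pixel|, same shape as the image.
#' @export
saliency_map <- function(object, image, landmarks = NULL) {
  if (inherits(image, "phantom_sample")) {
    landmarks <- landmarks %||% image$landmarks
    image <- image$image
  }
  if (is.null(landmarks)) stop("landmarks are required for the loss target")
  inp <- .detector_input(object, image)
  p <- encode_heatmap(landmarks, dim(inp$x), object$sigma)
  r <- unet_step(object$net, inp$x, p, want_grads = FALSE,
                 want_input_grad = TRUE)
  abs(matrix(r$input_grad, nrow(inp$x), ncol(inp$x)))
}

#' Evaluate a detector on labelled samples
#'
#' Predicts every sample and aggregates detection rate, false
#' positives and per-landmark distances against the ground truth.
#'
#' @param object A \code{landmark_detector}.
#' @param samples Labelled samples (\code{phantom_sample} or lists with
#'   \code{image} + \code{landmarks}).
#' @return An [detection_rate()] report.
#' @export
evaluate_detector <- function(object, samples) {
  preds <- predict(object, samples)
  truths <- lapply(samples, function(s) s$landmarks)
  spacing <- vapply(samples, function(s) s$image$spacing, numeric(1))
  detection_rate(preds, truths, spacing)
}
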