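#' Training configuration
#'
#' Optimisation hyperparameters for heatmap-detector training: Adam
#' (lr 0.001, beta 0.9/0.999, eps 1e-8), learning rate divided by
#' \code{plateau_factor} whenever the validation loss fails to improve
#' by a relative \code{plateau_rel_tol} for \code{plateau_patience}
#' epochs, and transfer-learning fine-tuning at a reduced rate (lr
#' 0.0005, 10 epochs).
#'
#' @param lr Initial learning rate.
#' @param betas Adam first/second-moment decay rates.
#' @param eps Adam stabiliser.
#' @param plateau_factor Divide the learning rate by this on plateau.
#' @param plateau_patience Epochs without improvement before reducing.
#' @param plateau_rel_tol Relative improvement that counts as progress.
#' @param n_epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param val_fraction Fraction of patients held out for validation.
#' @param seed Master seed covering split, batching and weight init.
#' @param fine_tune_lr Learning rate for fine-tuning.
#' @param fine_tune_epochs Epochs for fine-tuning.
#' @export
train_config <- function(lr = 0.001, betas = c(0.9, 0.999), eps = 1e-8,
                         plateau_factor = 2, plateau_patience = 5L,
                         plateau_rel_tol = 1e-3, n_epochs = 50L,
                         batch_size = 8L, val_fraction = 0.10, seed = 1L,
                         fine_tune_lr = 0.0005, fine_tune_epochs = 10L) {
  if (lr <= 0) stop("lr must be positive")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  structure(list(lr = lr, betas = betas, eps = eps,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_rel_tol = plateau_rel_tol,
                 n_epochs = as.integer(n_epochs),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 fine_tune_lr = fine_tune_lr,
                 fine_tune_epochs = as.integer(fine_tune_epochs)),
            class = "train_config")
}

#' Patient-wise train/validation split
#'
#' Partitions patients (never individual images) between training and
#' validation so no patient contributes to both sets.
#'
#' @param patient_ids Character/factor vector, one entry per sample.
#' @param val_fraction Fraction of patients assigned to validation.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return List with integer sample indices \code{train} and \code{val}
#'   plus the patient id partition.
#' @export
split_by_patient <- function(patient_ids, val_fraction = 0.10, seed = 1L) {
  patients <- unique(as.character(patient_ids))
  if (length(patients) < 2L) stop("need at least 2 patients to split")
  n_val <- max(1L, round(val_fraction * length(patients)))
  if (n_val >= length(patients)) n_val <- length(patients) - 1L
  set.seed(seed)
  val_patients <- sample(patients, n_val)
  val <- which(as.character(patient_ids) %in% val_patients)
  list(train = setdiff(seq_along(patient_ids), val), val = val,
       train_patients = setdiff(patients, val_patients),
       val_patients = val_patients)
}

#' Multitask minibatch stream over pooled views
#'
#' Long-axis training mixes the two-, three- and four-chamber views in
#' one model: samples from all views are pooled, one epoch visits every
#' sample exactly once in random order, and no per-view rebalancing is
#' applied, so the within-batch view mixture follows the pool
#' proportions.
#'
#' @param view_datasets Named list of per-view sample lists.
#' @param batch_size Samples per batch (>= 1).
#' @return List with \code{pool} (the concatenated samples),
#'   \code{view} (view tag per pooled sample) and \code{batches}
#'   (list of index vectors into the pool).
#' @export
multitask_batches <- function(view_datasets, batch_size = 8L) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  lens <- vapply(view_datasets, length, integer(1))
  if (sum(lens) == 0L) stop("no samples provided")
  pool <- do.call(c, unname(view_datasets))
  view <- rep(names(view_datasets) %||% as.character(seq_along(lens)), lens)
  list(pool = pool, view = view,
       batches = .epoch_batches(length(pool), batch_size))
}

.epoch_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# stack a list of samples (x: H x W matrix, p: H x W x C array) into
# batch arrays
.stack_batch <- function(samples, idx) {
  H <- nrow(samples[[idx[1]]]$x); W <- ncol(samples[[idx[1]]]$x)
  C <- dim(samples[[idx[1]]]$p)[3]
  nb <- length(idx)
  x <- array(0, c(H, W, nb)); p <- array(0, c(H, W, C, nb))
  for (j in seq_along(idx)) {
    x[, , j] <- samples[[idx[j]]]$x
    p[, , , j] <- samples[[idx[j]]]$p
  }
  list(x = x, p = p)
}

.adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0), t = 0L)
}

.adam_update <- function(weights, grads, state, lr, betas, eps) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (i in seq_along(weights)) {
    g <- grads[[i]]
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * g * g
    weights[[i]] <- weights[[i]] -
      lr * (state$m[[i]] / c1) / (sqrt(state$v[[i]] / c2) + eps)
  }
  list(weights = weights, state = state)
}

.eval_loss <- function(net, samples, batch_size = 8L) {
  total <- 0; kl <- 0; dc <- 0; n <- length(samples)
  idx <- seq_len(n)
  for (b in split(idx, ceiling(idx / batch_size))) {
    bt <- .stack_batch(samples, b)
    r <- .unet_step_cpp(net$weights, bt$x, dim(bt$x), bt$p, dim(bt$p),
                        net$plan, FALSE, FALSE)
    w <- length(b) / n
    total <- total + r$total * w; kl <- kl + r$kl * w; dc <- dc + r$dice * w
  }
  list(total = total, kl = kl, dice = dc)
}

#' Fit a U-Net to encoded heatmap samples
#'
#' Runs Adam over minibatches of the training samples, evaluates the
#' validation loss each epoch, reduces the learning rate on plateaus
#' and returns the weights of the epoch with the lowest validation
#' loss.  Fully reproducible given \code{config$seed}.
#'
#' @param net A network from [build_unet()].
#' @param train_samples,val_samples Lists of \code{list(x = matrix,
#'   p = heatmap array)} pairs, e.g. from [prepare_samples()].
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with \code{net} (best weights) and \code{history}
#'   (data.frame: epoch, train_loss, val_loss, lr; attribute
#'   \code{best_epoch}).
#' @export
fit_unet <- function(net, train_samples, val_samples,
                     config = train_config(), verbose = FALSE) {
  if (length(train_samples) == 0L) stop("empty training set")
  set.seed(config$seed)
  state <- .adam_init(net$weights)
  lr <- config$lr
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())
  best_val <- Inf; best_weights <- net$weights; best_epoch <- 0L
  stall <- 0L
  for (ep in seq_len(config$n_epochs)) {
    tl <- 0
    batches <- .epoch_batches(length(train_samples), config$batch_size)
    for (b in batches) {
      bt <- .stack_batch(train_samples, b)
      r <- .unet_step_cpp(net$weights, bt$x, dim(bt$x), bt$p, dim(bt$p),
                          net$plan, TRUE, FALSE)
      up <- .adam_update(net$weights, r$grads, state, lr, config$betas,
                         config$eps)
      net$weights <- up$weights
      state <- up$state
      tl <- tl + r$total * length(b)
    }
    tl <- tl / length(train_samples)
    vl <- if (length(val_samples))
      .eval_loss(net, val_samples, config$batch_size)$total else tl
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl,
                                   val_loss = vl, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2e",
                      ep, tl, vl, lr))
    if (vl < best_val * (1 - config$plateau_rel_tol)) {
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$plateau_patience) {
        lr <- lr / config$plateau_factor
        stall <- 0L
      }
    }
    if (vl < best_val) {
      best_val <- vl; best_weights <- net$weights; best_epoch <- ep
    }
  }
  net$weights <- best_weights
  attr(hist, "best_epoch") <- best_epoch
  list(net = net, history = hist)
}

#' Fine-tune a pretrained network on a new domain
#'
#' Same loop as [fit_unet()] but starting from the pretrained weights
#' with the reduced fine-tuning learning rate and epoch budget; all
#' layers remain trainable.  With \code{fine_tune_epochs = 0} the
#' pretrained network is returned unchanged.
#'
#' @param net Pretrained network ([build_unet()] structure).
#' @param train_samples,val_samples As in [fit_unet()].
#' @param config A [train_config()]; \code{fine_tune_lr} and
#'   \code{fine_tune_epochs} are used.
#' @export
fine_tune_unet <- function(net, train_samples, val_samples,
                           config = train_config(), verbose = FALSE) {
  if (config$fine_tune_epochs == 0L)
    return(list(net = net,
                history = data.frame(epoch = integer(),
                                     train_loss = numeric(),
                                     val_loss = numeric(), lr = numeric())))
  cfg <- config
  cfg$lr <- config$fine_tune_lr
  cfg$n_epochs <- config$fine_tune_epochs
  fit_unet(net, train_samples, val_samples, cfg, verbose = verbose)
}

#' Encode phantom/annotated samples for training
#'
#' Normalises each image and encodes its landmark set as the target
#' heatmap.  When \code{augment_n > 0}, that many additionally
#' augmented copies of each sample are appended.
#'
#' @param samples List of \code{phantom_sample} (or lists with
#'   \code{image} and \code{landmarks}).
#' @param sigma Gaussian kernel width in pixels.
#' @param invert_contrast Invert intensities (an LGE-like appearance
#'   domain for transfer-learning experiments).
#' @param augment_n Augmented copies per sample.
#' @param pre_config [preprocess_config()] for augmentation ranges.
#' @return List of \code{list(x, p, truth, view)} training pairs.
#' @export
prepare_samples <- function(samples, sigma = 4, invert_contrast = FALSE,
                            augment_n = 0L,
                            pre_config = preprocess_config()) {
  out <- list()
  for (s in samples) {
    img <- s$image; lms <- s$landmarks
    variants <- list(list(image = img, landmarks = lms))
    if (augment_n > 0L)
      for (k in seq_len(augment_n))
        variants <- c(variants, list(augment(img, lms, pre_config)[1:2]))
    for (v in variants) {
      x <- normalize_intensity(v$image$pixels)
      if (invert_contrast) x <- 1 - x
      p <- encode_heatmap(v$landmarks, dim(x), sigma)
      out[[length(out) + 1L]] <-
        list(x = x, p = p, truth = v$landmarks, view = lms$view,
             patient_id = s$patient_id, id = s$id,
             spacing = v$image$spacing)
    }
  }
  out
}
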