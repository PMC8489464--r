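#' U-Net model configuration
#'
#' Describes the encoder--decoder backbone used for heatmap landmark
#' detection.  The network is organised as resolution levels: at each
#' level the encoder and the decoder branch each apply
#' \code{blocks_per_level} convolution blocks (3x3 convolution, instance
#' normalisation, ReLU), downsampling halves the resolution and doubles
#' the channel count, and skip connections concatenate encoder features
#' into the decoder at the same resolution.  A final 1x1 convolution
#' emits one raw score channel per class (background + one per
#' landmark).
#'
#' @param n_levels Number of resolution levels (>= 2).
#' @param blocks_per_level Convolution blocks in the encoder branch at
#'   each level.
#' @param decoder_blocks Convolution blocks in the decoder branch at
#'   each level (the first always consumes the skip concatenation).
#' @param base_channels Channels at the finest level; doubled per level.
#' @param in_channels Input image channels (grayscale: 1).
#' @param out_channels Output classes; background + number of landmarks.
#' @param input_size Integer vector (rows, cols); both must be divisible
#'   by \code{2^(n_levels - 1)}.
#' @return An object of class \code{model_config}.
#' @export
model_config <- function(n_levels = 4L, blocks_per_level = 2L,
                         decoder_blocks = 1L, base_channels = 16L,
                         in_channels = 1L, out_channels = 4L,
                         input_size = c(96L, 96L)) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("n_levels must be >= 2")
  if (blocks_per_level < 1L || decoder_blocks < 1L)
    stop("need at least one block per branch")
  input_size <- as.integer(rep(input_size, length.out = 2L))
  div <- 2L^(n_levels - 1L)
  if (any(input_size %% div != 0L))
    stop("input_size must be divisible by 2^(n_levels - 1) = ", div)
  structure(list(n_levels = n_levels,
                 blocks_per_level = as.integer(blocks_per_level),
                 decoder_blocks = as.integer(decoder_blocks),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 input_size = input_size),
            class = "model_config")
}

# op codes shared with the C++ engine
.OP_CONVBLOCK <- 1L; .OP_POOL <- 2L; .OP_UPCAT <- 3L; .OP_CONV1 <- 4L

#' @keywords internal
unet_layout <- function(config) {
  L <- config$n_levels
  B <- config$blocks_per_level
  ch <- config$base_channels * 2L^(0:(L - 1L))
  rows <- list()
  cin <- config$in_channels
  for (l in seq_len(L)) {
    for (b in seq_len(B)) {
      rows[[length(rows) + 1L]] <- c(.OP_CONVBLOCK, cin, ch[l])
      cin <- ch[l]
    }
    if (l < L) rows[[length(rows) + 1L]] <- c(.OP_POOL, ch[l], ch[l])
  }
  for (l in rev(seq_len(L - 1L))) {
    # cin column records the skip channel count for the split in backward
    rows[[length(rows) + 1L]] <- c(.OP_UPCAT, ch[l], ch[l] + cin)
    cin <- ch[l] + cin
    for (b in seq_len(config$decoder_blocks)) {
      rows[[length(rows) + 1L]] <- c(.OP_CONVBLOCK, cin, ch[l])
      cin <- ch[l]
    }
  }
  rows[[length(rows) + 1L]] <- c(.OP_CONV1, cin, config$out_channels)
  do.call(rbind, rows)
}

#' Build an untrained U-Net
#'
#' Allocates and initialises the weight set for the configured backbone.
#' Convolution kernels use He-normal initialisation
#' (sd = sqrt(2 / fan_in)), biases start at zero and instance-norm
#' scale/shift at one/zero.
#'
#' @param config A [model_config()].
#' @return A list with elements \code{config}, \code{plan} and
#'   \code{weights} (named flat list of arrays).
#' @export
build_unet <- function(config = model_config()) {
  plan <- unet_layout(config)
  weights <- list()
  for (i in seq_len(nrow(plan))) {
    op <- plan[i, 1L]; cin <- plan[i, 2L]; cout <- plan[i, 3L]
    if (op == .OP_CONVBLOCK) {
      sd <- sqrt(2 / (9 * cin))
      weights[[sprintf("conv%02d.W", i)]] <-
        array(stats::rnorm(9 * cin * cout, sd = sd), dim = c(3, 3, cin, cout))
      weights[[sprintf("conv%02d.b", i)]] <- numeric(cout)
      weights[[sprintf("conv%02d.gamma", i)]] <- rep(1, cout)
      weights[[sprintf("conv%02d.beta", i)]] <- numeric(cout)
    } else if (op == .OP_CONV1) {
      sd <- sqrt(2 / cin)
      weights[[sprintf("conv%02d.W", i)]] <-
        matrix(stats::rnorm(cin * cout, sd = sd), nrow = cout, ncol = cin)
      weights[[sprintf("conv%02d.b", i)]] <- numeric(cout)
    }
  }
  structure(list(config = config, plan = plan, weights = weights),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("U-Net: %d levels (%d enc + %d dec blocks/level), base %d channels\n",
              cfg$n_levels, cfg$blocks_per_level, cfg$decoder_blocks,
              cfg$base_channels))
  cat(sprintf("  input %dx%dx%d -> scores %dx%dx%d, %s parameters\n",
              cfg$input_size[1], cfg$input_size[2], cfg$in_channels,
              cfg$input_size[1], cfg$input_size[2], cfg$out_channels,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param net A network from [build_unet()].
#' @export
n_parameters <- function(net) {
  sum(vapply(net$weights, length, integer(1)))
}

#' Forward pass: raw per-pixel scores
#'
#' @param net A network from [build_unet()].
#' @param x Input batch: array (H, W, n) or a single H x W matrix.
#' @return Array (H, W, out_channels, n) of raw scores.
#' @export
unet_forward <- function(net, x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  res <- .unet_step_cpp(net$weights, x, dim(x), NULL, integer(4),
                        net$plan, FALSE, FALSE)
  res$scores
}

#' Loss + gradient step evaluation
#'
#' Runs forward, evaluates the combined KL + soft-Dice loss against the
#' target heatmaps, and backpropagates.  Loss values are means over the
#' batch.
#'
#' @param net network; @param x input array (H, W, n);
#' @param p_truth target heatmap array (H, W, C, n).
#' @param want_grads compute weight gradients;
#' @param want_input_grad also return d(loss)/d(input) (saliency).
#' @keywords internal
unet_step <- function(net, x, p_truth, want_grads = TRUE,
                      want_input_grad = FALSE) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(p_truth)) == 3L)
    p_truth <- array(p_truth, dim = c(dim(p_truth), 1L))
  .unet_step_cpp(net$weights, x, dim(x), p_truth, dim(p_truth),
                 net$plan, want_grads, want_input_grad)
}

#' Per-pixel softmax over channels
#'
#' Converts raw network scores into per-pixel class probabilities.
#'
#' @param scores Array (H, W, C) or (H, W, C, n) of raw scores.
#' @return Array of the same shape; channel values at each pixel sum to 1.
#' @export
softmax_probs <- function(scores) {
  d <- dim(scores)
  if (length(d) == 4L) {
    for (i in seq_len(d[4L]))
      scores[, , , i] <- softmax_probs(array(scores[, , , i], d[1:3]))
    return(scores)
  }
  stopifnot(length(d) == 3L)
  m <- apply(scores, c(1, 2), max)
  e <- exp(scores - as.vector(m))
  s <- apply(e, c(1, 2), sum)
  e / as.vector(s)
}
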