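#' Kullback-Leibler divergence between heatmap distributions
#'
#' Mean over pixels of \eqn{\sum_c p_c \log(p_c / q_c)} with the
#' conventions \eqn{0 \log(0/q) = 0} and \eqn{q} floored at 1e-12.
#'
#' @param truth Array (H, W, C): ground-truth per-pixel distribution.
#' @param pred Array (H, W, C): predicted per-pixel distribution.
#' @return Nonnegative scalar.
#' @export
kl_loss <- function(truth, pred) {
  if (!identical(dim(truth), dim(pred))) stop("shape mismatch")
  q <- pmax(pred, 1e-12)
  term <- ifelse(truth > 0, truth * (log(truth) - log(q)), 0)
  sum(term) / prod(dim(truth)[1:2])
}

#' Soft-Dice loss term over landmark channels
#'
#' For each landmark channel (background excluded) the soft Dice ratio
#' \eqn{2 \sum p q / (\sum p + \sum q + \epsilon)} measures overlap of
#' the two probability maps; the loss term is one minus the mean ratio,
#' so identical maps give 0 and disjoint supports give 1.
#'
#' @inheritParams kl_loss
#' @param eps Stabiliser in the denominator (default 1e-8).
#' @return Scalar in [0, 1].
#' @export
soft_dice_term <- function(truth, pred, eps = 1e-8) {
  if (!identical(dim(truth), dim(pred))) stop("shape mismatch")
  C <- dim(truth)[3]
  dice <- vapply(2:C, function(k) {
    p <- truth[, , k]; q <- pred[, , k]
    2 * sum(p * q) / (sum(p) + sum(q) + eps)
  }, numeric(1))
  1 - mean(dice)
}

#' Combined training loss: KL divergence + soft-Dice term
#'
#' @inheritParams kl_loss
#' @return A \code{loss_value}: list with \code{kl_term},
#'   \code{dice_term} and \code{total} (their sum).
#' @export
combined_loss <- function(truth, pred) {
  kl <- kl_loss(truth, pred)
  dc <- soft_dice_term(truth, pred)
  structure(list(kl_term = kl, dice_term = dc, total = kl + dc),
            class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("loss: %.6f  (KL %.6f + dice %.6f)\n",
              x$total, x$kl_term, x$dice_term))
  invisible(x)
}

#' Gradient of the combined loss with respect to raw scores
#'
#' Reference implementation of the backward rule used in training:
#' the KL part contributes \eqn{(q - p) / N_{pix}} directly, the dice
#' part is propagated through the per-pixel softmax Jacobian.
#'
#' @param truth Array (H, W, C) target distribution.
#' @param scores Array (H, W, C) raw network scores.
#' @param eps Soft-dice denominator stabiliser.
#' @return Array (H, W, C): d(combined loss)/d(scores).
#' @export
loss_score_gradient <- function(truth, scores, eps = 1e-8) {
  if (!identical(dim(truth), dim(scores))) stop("shape mismatch")
  d <- dim(truth)
  HW <- d[1] * d[2]; C <- d[3]; L <- C - 1L
  q <- softmax_probs(scores)
  dq <- array(0, d)
  for (k in 2:C) {
    p <- truth[, , k]; qq <- q[, , k]
    a <- sum(p * qq); b <- sum(p) + sum(qq) + eps
    dq[, , k] <- -2 / (L * b) * p + 2 * a / (L * b^2)
  }
  dot <- apply(dq * q, c(1, 2), sum)
  q * (dq - as.vector(dot)) + (q - truth) / HW
}
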