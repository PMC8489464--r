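# small helper: random distributions over C channels on an n x n grid
random_probs <- function(n, C = 4) {
  a <- array(runif(n * n * C), c(n, n, C))
  a / as.vector(apply(a, c(1, 2), sum))
}

test_that("KL loss identities hold", {
  set.seed(2)
  p <- random_probs(16)
  expect_equal(kl_loss(p, p), 0, tolerance = 1e-12)

  # one-hot background truth against a uniform 4-channel prediction:
  # every pixel contributes log 4
  onehot <- array(0, c(16, 16, 4)); onehot[, , 1] <- 1
  unif <- array(1 / 4, c(16, 16, 4))
  expect_equal(kl_loss(onehot, unif), log(4), tolerance = 1e-12)

  # nonnegativity over random pairs (Gibbs inequality)
  for (i in 1:20) expect_gte(kl_loss(random_probs(8), random_probs(8)), 0)
  expect_error(kl_loss(p, random_probs(8)), "shape")
})

test_that("soft-dice term spans identical (0) to disjoint (1) supports", {
  onehot <- array(0, c(16, 16, 4))
  onehot[, , 2][5, 5] <- 1; onehot[, , 3][9, 9] <- 1
  onehot[, , 4][12, 3] <- 1
  onehot[, , 1] <- 1 - apply(onehot[, , 2:4], c(1, 2), sum)
  expect_equal(soft_dice_term(onehot, onehot), 0, tolerance = 1e-6)

  moved <- onehot * 0
  moved[, , 2][6, 6] <- 1; moved[, , 3][10, 10] <- 1
  moved[, , 4][13, 4] <- 1
  moved[, , 1] <- 1 - apply(moved[, , 2:4], c(1, 2), sum)
  expect_equal(soft_dice_term(onehot, moved), 1, tolerance = 1e-6)

  # p = q = uniform 0.5 on every landmark channel: dice = 0.5
  half <- array(0.5, c(8, 8, 4))
  expect_equal(soft_dice_term(half, half), 0.5, tolerance = 1e-9)
})

test_that("combined loss decomposes and vanishes on one-hot self-prediction", {
  onehot <- array(0, c(12, 12, 4))
  onehot[, , 2][4, 4] <- 1
  onehot[, , 3][8, 8] <- 1
  onehot[, , 4][2, 9] <- 1
  onehot[, , 1] <- 1 - apply(onehot[, , 2:4], c(1, 2), sum)
  lv <- combined_loss(onehot, onehot)
  expect_equal(lv$total, lv$kl_term + lv$dice_term)
  expect_equal(lv$total, 0, tolerance = 1e-6)

  set.seed(3)
  p <- random_probs(10); q <- random_probs(10)
  lv2 <- combined_loss(p, q)
  expect_gte(lv2$total, lv2$kl_term)
  expect_gte(lv2$total, lv2$dice_term)
})

test_that("smoothed self-prediction has exactly zero KL and the analytic dice slack", {
  lms <- random_landmark_set("SAX", shape = c(32, 32), margin = 8)
  p <- encode_heatmap(lms, c(32, 32), sigma = 3)
  lv <- combined_loss(p, p)
  expect_identical(lv$kl_term, 0)
  dice_self <- mean(vapply(2:4, function(k)
    2 * sum(p[, , k]^2) / (2 * sum(p[, , k]) + 1e-8), numeric(1)))
  expect_equal(lv$dice_term, 1 - dice_self, tolerance = 1e-12)
})

test_that("analytic score gradient matches central finite differences on an 8x8 case", {
  set.seed(4)
  truth <- random_probs(8)
  scores <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  g <- loss_score_gradient(truth, scores)
  loss_of <- function(s) {
    lv <- combined_loss(truth, softmax_probs(s))
    lv$total
  }
  h <- 1e-5
  idx <- rbind(c(1, 1, 1), c(3, 5, 2), c(8, 8, 4), c(2, 7, 3), c(5, 5, 1))
  for (i in seq_len(nrow(idx))) {
    sp <- scores; sp[idx[i, 1], idx[i, 2], idx[i, 3]] <- sp[idx[i, 1], idx[i, 2], idx[i, 3]] + h
    sm <- scores; sm[idx[i, 1], idx[i, 2], idx[i, 3]] <- sm[idx[i, 1], idx[i, 2], idx[i, 3]] - h
    fd <- (loss_of(sp) - loss_of(sm)) / (2 * h)
    expect_equal(g[idx[i, 1], idx[i, 2], idx[i, 3]], fd, tolerance = 1e-3)
  }
})

test_that("the C++ training-step loss agrees with the R reference", {
  set.seed(6)
  cfg <- tiny_model(32)
  net <- build_unet(cfg)
  x <- matrix(runif(32 * 32), 32)
  lms <- random_landmark_set("SAX", shape = c(32, 32), margin = 8)
  p <- encode_heatmap(lms, c(32, 32), sigma = 3)
  r <- cardiomark:::unet_step(net, x, p, want_grads = FALSE)
  sc <- array(r$scores, c(32, 32, 4))
  ref <- combined_loss(p, softmax_probs(sc))
  expect_equal(r$kl, ref$kl_term, tolerance = 1e-4)
  expect_equal(r$dice, ref$dice_term, tolerance = 1e-4)
  expect_equal(r$total, ref$total, tolerance = 1e-4)
})

test_that("C++ weight gradients match finite differences on a tiny net", {
  set.seed(7)
  cfg <- model_config(n_levels = 2L, blocks_per_level = 1L,
                      decoder_blocks = 1L, base_channels = 2L,
                      input_size = c(8L, 8L))
  net <- build_unet(cfg)
  x <- matrix(runif(64), 8)
  p <- random_probs(8)
  r <- cardiomark:::unet_step(net, x, p, want_grads = TRUE)
  loss_at <- function(w) {
    n2 <- net; n2$weights <- w
    cardiomark:::unet_step(n2, x, p, want_grads = FALSE)$total
  }
  h <- 1e-3
  # probe a few parameters across layers (conv kernel, bias, IN gamma)
  probes <- list(c(1L, 1L), c(2L, 1L), c(3L, 1L),
                 c(length(net$weights) - 1L, 2L),
                 c(5L, 1L))
  for (pr in probes) {
    wi <- pr[1]; ei <- pr[2]
    wp <- net$weights; wp[[wi]][ei] <- wp[[wi]][ei] + h
    wm <- net$weights; wm[[wi]][ei] <- wm[[wi]][ei] - h
    fd <- (loss_at(wp) - loss_at(wm)) / (2 * h)
    an <- r$grads[[wi]][ei]
    # single-precision forward: relative check with an absolute floor
    expect_lt(abs(an - fd), max(5e-2 * abs(fd), 5e-3))
  }
})
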